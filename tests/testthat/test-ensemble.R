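two_class_space <- function() {
  # G1 = {a, b}, G2 = {b, c}
  corpus <- corpus_from_edges(c("d1", "d1", "d2", "d2"), c("a", "b", "b", "c"))
  ls <- build_label_space(corpus, min_targets = 0, others_size = 0,
                          nontarget_size = 0, seed = 1)
  ann <- ann_from_table(c("a", "b", "b", "c"),
                        c("GO:0000001", "GO:0000001", "GO:0000002", "GO:0000002"),
                        rep("MF", 4))
  vocab <- build_vocabulary(ann, c("a", "b", "c"))
  feats <- vectorize_genes(ann, vocab, c("a", "b", "c"))
  list(ls = ls, feats = feats)
}

test_that("conflict removal keeps the positive class intact", {
  s <- two_class_space()
  sp <- binary_split(s$ls, s$feats, 1)
  expect_equal(sp$positive_genes, c("a", "b"))
  expect_equal(sp$negative_genes, "c")  # b removed from the negatives
  sp2 <- binary_split(s$ls, s$feats, 2)
  expect_equal(sp2$positive_genes, c("b", "c"))
  expect_equal(sp2$negative_genes, "a")
})

test_that("a negative with a feature vector identical to a positive's is removed", {
  corpus <- corpus_from_edges(c("d1", "d2"), c("a", "z"))
  ls <- build_label_space(corpus, min_targets = 0, others_size = 0,
                          nontarget_size = 0, seed = 1)
  # distinct genes a and z share the same single GO term
  ann <- ann_from_table(c("a", "z"), c("GO:0000001", "GO:0000001"), c("MF", "MF"))
  feats <- vectorize_genes(ann, build_vocabulary(ann, c("a", "z")), c("a", "z"))
  sp <- binary_split(ls, feats, 1, compare_vectors = TRUE)
  expect_equal(sp$negative_genes, character(0))
  sp_id <- binary_split(ls, feats, 1, compare_vectors = FALSE)
  expect_equal(sp_id$negative_genes, "z")
})

test_that("splits of a random multi-class space match brute-force set arithmetic", {
  study <- planted_study(seed = 19, p_signal = 0.8, p_noise = 0.1,
                         n_drugs = 5, n_genes = 60, n_background = 0)
  ls <- study$label_space
  feats <- study$features
  sig <- apply(as.matrix(feats$x), 1, paste, collapse = "")
  for (i in seq_len(ls$N)) {
    if (length(ls$gene_sets[[i]]) == 0) next
    sp <- binary_split(ls, feats, i)
    pos <- sort(ls$gene_sets[[i]])
    neg <- setdiff(sort(unique(unlist(ls$gene_sets))), pos)
    neg <- neg[!(sig[neg] %in% sig[pos])]
    expect_equal(sp$positive_genes, pos)
    expect_equal(sp$negative_genes, neg)
  }
})

test_that("the ensemble assigns one model per class and ignores fitting order", {
  s <- two_class_space()
  fit <- suppressWarnings(brdti(s$ls, s$feats, C = 1, skip_empty = TRUE))
  expect_length(fit$models, 4)  # 2 drugs + 2 empty sentinels (skipped)
  expect_equal(fit$models[[1]]$label_index, 1L)
  expect_equal(fit$models[[2]]$label_index, 2L)
  expect_null(fit$models[[3]])
  expect_null(fit$models[[4]])

  # permuting class order permutes the models but not the per-label fits
  ls_perm <- s$ls
  perm <- c(2L, 1L, 3L, 4L)
  ls_perm$labels <- s$ls$labels[perm]
  ls_perm$gene_sets <- s$ls$gene_sets[perm]
  fit_perm <- suppressWarnings(brdti(ls_perm, s$feats, C = 1, skip_empty = TRUE))
  expect_identical(fit$models[[1]]$weights, fit_perm$models[[2]]$weights)
  expect_identical(fit$models[[2]]$weights, fit_perm$models[[1]]$weights)
})

test_that("empty classes error unless skipping is requested", {
  corpus <- corpus_from_edges(c("d1", "d2", "d2", "d3", "d3"),
                              c("a", "b", "c", "d", "e"))
  ls <- build_label_space(corpus, min_targets = 0, others_size = 0,
                          nontarget_size = 0, seed = 1)
  genes <- letters[1:5]
  ann <- ann_from_table(genes, sprintf("GO:000000%d", 1:5), rep("MF", 5))
  feats <- vectorize_genes(ann, build_vocabulary(ann, genes), genes)
  ls_empty <- ls
  ls_empty$gene_sets[[which(ls$labels == "d1")]] <- character(0)
  expect_error(brdti(ls_empty, feats, C = 1), "empty positive set")
  suppressWarnings(
    expect_warning(fit <- brdti(ls_empty, feats, C = 1, skip_empty = TRUE), "skipped"))
  i_d1 <- which(ls$labels == "d1")
  i_d2 <- which(ls$labels == "d2")
  expect_null(fit$models[[i_d1]])
  expect_false(is.null(fit$models[[i_d2]]))
})

test_that("prediction applies the strict f(g) > 0 rule", {
  s <- two_class_space()
  fit <- suppressWarnings(brdti(s$ls, s$feats, C = 1, skip_empty = TRUE))
  # zero weights: p = 0.5 exactly, never predicted
  fit0 <- fit
  for (i in seq_along(fit0$models)) {
    if (is.null(fit0$models[[i]])) next
    fit0$models[[i]]$weights[] <- 0
  }
  pred0 <- predict(fit0, s$feats)
  expect_true(all(lengths(pred0) == 0))
  # positively aligned weights predict the label with p > 0.5
  fit1 <- fit0
  fit1$models[[1]]$weights[] <- c(1, 0, 0)  # GO:0000001 + intercept 0
  pred1 <- predict(fit1, s$feats)
  expect_true("1" %in% names(pred1[["a"]]))
  expect_gt(pred1[["a"]][["1"]], 0.5)
})

test_that("predicted label sets equal a brute-force per-class sign test", {
  study <- planted_study(seed = 23, p_signal = 0.9, p_noise = 0.05)
  fit <- suppressWarnings(brdti(study$label_space, study$features, C = 1, skip_empty = TRUE))
  genes <- sample(rownames(study$features$x), 10)
  sub <- brdti:::features_subset(study$features, genes)
  pred <- predict(fit, sub)
  W <- coef(fit)
  X <- as.matrix(sub$x)
  for (r in seq_along(genes)) {
    expected <- integer(0)
    for (i in seq_len(study$label_space$N)) {
      if (any(is.na(W[, i]))) next
      f_i <- sum(X[r, ] * W[seq_len(ncol(X)), i]) + W[nrow(W), i]
      if (f_i > 0) expected <- c(expected, i)
    }
    expect_equal(sort(as.integer(names(pred[[r]]))), sort(expected))
  }
})

test_that("serialization round-trips and refits are byte-identical", {
  study <- planted_study(seed = 29, n_drugs = 3, n_genes = 40, n_background = 6)
  fit <- suppressWarnings(brdti(study$label_space, study$features, C = 1, skip_empty = TRUE))
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  write_brdti(fit, f1)
  back <- read_brdti(f1)
  expect_equal(predict(back, study$features, type = "prob"),
               predict(fit, study$features, type = "prob"))
  fit2 <- suppressWarnings(brdti(study$label_space, study$features, C = 1, skip_empty = TRUE))
  write_brdti(fit2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)), readBin(f2, "raw", file.size(f2)))
})

test_that("a vocabulary mismatch between model and features is detected", {
  study <- planted_study(seed = 29, n_drugs = 3, n_genes = 40, n_background = 6)
  fit <- suppressWarnings(brdti(study$label_space, study$features, C = 1, skip_empty = TRUE))
  # rebuild the vocabulary from a subset of genes -> different hash
  vocab2 <- build_vocabulary(study$sim$annotations, study$universe[1:10])
  feats2 <- suppressWarnings(
    vectorize_genes(study$sim$annotations, vocab2, label_space_genes(study$label_space)))
  expect_error(predict(fit, feats2), "hash")
})
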