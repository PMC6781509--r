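# Trained study with one true edge withheld from training, so a known
# repurposing signal is planted: the withheld (drug, gene) pair should
# reappear as a confident novel association.
withheld_study <- function(seed = 43) {
  sim <- synth_corpus(synth_spec(n_drugs = 4, n_genes = 80, vocab_size = 60,
                                 signature_size = 5, p_signal = 1, p_noise = 0,
                                 labels_per_gene = c(1, 2),
                                 n_background_genes = 12, seed = seed))
  # withhold the first single-label gene's edge from the training corpus
  single <- names(sim$truth$gene_labelsets)[lengths(sim$truth$gene_labelsets) == 1]
  gene <- single[[1]]
  drug <- sim$truth$gene_labelsets[[gene]]
  d <- rep(corpus_drugs(sim$corpus), lengths(sim$corpus$drug_to_genes))
  g <- unlist(sim$corpus$drug_to_genes, use.names = FALSE)
  keep <- !(d == drug & g == gene)
  f <- tempfile(fileext = ".tsv")
  writeLines(paste(d[keep], g[keep], sep = "\t"), f)
  corpus <- read_interactions(f, format = "simple_tsv")
  universe <- well_studied_genes(sim$annotations)
  ls <- build_label_space(corpus, min_targets = 0, others_size = 0,
                          nontarget_size = 6, gene_universe = universe, seed = seed)
  vocab <- build_vocabulary(sim$annotations, universe)
  feats <- vectorize_genes(sim$annotations, vocab, universe)
  fit <- suppressWarnings(brdti(ls, feats, C = 1, skip_empty = TRUE))
  list(sim = sim, corpus = corpus, ls = ls, feats = feats, fit = fit,
       withheld = list(drug = drug, gene = gene))
}

test_that("a withheld true edge is recovered as a novel association", {
  st <- withheld_study()
  assoc <- extract_novel(st$fit, st$feats, st$corpus)
  hit <- assoc[assoc$gene_id == st$withheld$gene &
               assoc$drug_label == st$withheld$drug, ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$status, "novel")
  expect_gt(hit$probability, 0.5)
  # predictions matching training edges are flagged known
  known <- assoc[assoc$status == "known", ]
  expect_gt(nrow(known), 0)
  for (r in sample(nrow(known), min(20, nrow(known)))) {
    expect_true(has_interaction(st$corpus, known$drug_label[r], known$gene_id[r]))
  }
})

test_that("sentinel classes are suppressed from association output", {
  st <- withheld_study()
  assoc <- extract_novel(st$fit, st$feats, st$corpus)
  expect_false(any(assoc$drug_label %in% c("others", "non-target")))
  # background genes predicted only as non-target yield no rows
  prob <- predict(st$fit, st$feats, type = "prob")
  nt <- st$ls$nontarget_index
  only_nt <- rownames(prob)[!is.na(prob[, nt]) & prob[, nt] > 0.5 &
                            rowSums(prob[, -nt, drop = FALSE] > 0.5, na.rm = TRUE) == 0]
  expect_false(any(only_nt %in% assoc$gene_id))
})

test_that("known + novel counts conserve the thresholded prediction total", {
  st <- withheld_study()
  assoc <- extract_novel(st$fit, st$feats, st$corpus)
  prob <- predict(st$fit, st$feats, type = "prob")
  sent <- c(st$ls$others_index, st$ls$nontarget_index)
  total <- sum(prob[, -sent, drop = FALSE] > 0.5, na.rm = TRUE)
  expect_equal(nrow(assoc), total)
  expect_equal(sum(assoc$status == "known") + sum(assoc$status == "novel"), total)
})

test_that("repurposed gene lists are per-drug, novel-only, probability-sorted", {
  st <- withheld_study()
  assoc <- extract_novel(st$fit, st$feats, st$corpus)
  for (d in attr(assoc, "drugs")) {
    rg <- repurposed_genes(assoc, d)
    manual <- assoc[assoc$drug_label == d & assoc$status == "novel", ]
    expect_equal(nrow(rg), nrow(manual))
    if (nrow(rg) > 1) expect_true(all(diff(rg$probability) <= 0))
  }
  expect_error(repurposed_genes(assoc, "no-such-drug"), "unknown drug")
})

test_that("phenotype support mode distinguishes all-gene from any-gene coverage", {
  assoc <- data.frame(
    gene_id = c("g1", "g2", "g3"),
    drug_label = c("dA", "dA", "dA"),
    probability = c(0.9, 0.8, 0.7),
    status = c("novel", "novel", "known"),
    stringsAsFactors = FALSE)
  # ph1 carried by g1+g2 (both novel-predicted) -> all
  # ph2 carried by g2+g3 (g3 only known-predicted) -> any
  map <- list(g1 = "OMIM:600001", g2 = c("OMIM:600001", "OMIM:600002"),
              g3 = "OMIM:600002")
  links <- drug_phenotype_links(assoc, map)
  expect_equal(links$support_mode[links$phenotype_id == "OMIM:600001"], "all")
  expect_equal(links$support_mode[links$phenotype_id == "OMIM:600002"], "any")
  expect_equal(links$n_supporting_genes, c(2L, 1L))
})

test_that("phenotype linking is idempotent, order-independent, and matches a brute-force join", {
  st <- withheld_study()
  assoc <- extract_novel(st$fit, st$feats, st$corpus)
  map <- synth_phenotypes(st$sim$truth, n_phenotypes = 10, genes_per_phenotype = 6,
                          seed = 3)
  links <- drug_phenotype_links(assoc, map)
  shuffled <- assoc[sample(nrow(assoc)), ]
  attr(shuffled, "drugs") <- attr(assoc, "drugs")
  expect_equal(drug_phenotype_links(shuffled, map), links)
  expect_equal(drug_phenotype_links(assoc, map), links)

  # brute-force join over novel rows
  novel <- assoc[assoc$status == "novel", ]
  universe <- unique(assoc$gene_id)
  expected <- 0L
  for (d in unique(novel$drug_label)) {
    dg <- novel$gene_id[novel$drug_label == d]
    phs <- unique(unlist(map[dg]))
    expected <- expected + length(phs)
  }
  expect_equal(nrow(links), expected)
  for (r in seq_len(nrow(links))) {
    carriers <- universe[vapply(universe, function(g) {
      links$phenotype_id[r] %in% (map[[g]] %||% character(0))
    }, logical(1))]
    supp <- strsplit(links$supporting_genes[r], ";")[[1]]
    dg <- novel$gene_id[novel$drug_label == links$drug_label[r]]
    expect_setequal(supp, intersect(dg, carriers))
    expect_equal(links$support_mode[r], if (all(carriers %in% supp)) "all" else "any")
  }
})

test_that("gene-phenotype maps round-trip through TSV", {
  map <- list(g1 = c("OMIM:600001", "OMIM:600002"), g3 = "OMIM:600009")
  f <- tempfile(fileext = ".tsv")
  write_gene_phenotypes(map, f)
  expect_identical(read_gene_phenotypes(f), map)
})
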