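# Fixture builders and independent oracles shared across the suite.
# Oracles are written as plain, explicit arithmetic -- loops over sets
# and indicators, or a general-purpose optimizer -- so they share no
# code path with the implementation they check.

`%||%` <- function(a, b) if (is.null(a)) b else a

ann_from_table <- function(gene, term, aspect) {
  f <- tempfile(fileext = ".tsv")
  writeLines(paste(gene, term, aspect, sep = "\t"), f)
  read_annotations(f, format = "simple_tsv")
}

corpus_from_edges <- function(drug, gene) {
  f <- tempfile(fileext = ".tsv")
  writeLines(paste(drug, gene, sep = "\t"), f)
  read_interactions(f, format = "simple_tsv")
}

# Random true/predicted label-set pairs; true sets always non-empty.
random_pairs <- function(n, n_labels, seed) {
  set.seed(seed)
  true <- lapply(seq_len(n), function(i) sort(sample(n_labels, sample(n_labels, 1))))
  pred <- lapply(seq_len(n), function(i) {
    sz <- sample(0:n_labels, 1)
    if (sz == 0) integer(0) else sort(sample(n_labels, sz))
  })
  label_set_pairs(sprintf("g%04d", seq_len(n)), true, pred)
}

# Brute-force per-instance metrics by direct set arithmetic.
oracle_instance <- function(L, Lp) {
  inter <- 0
  for (a in L) if (a %in% Lp) inter <- inter + 1
  extra <- 0
  for (b in Lp) if (!(b %in% L)) extra <- extra + 1
  uni <- length(unique(c(L, Lp)))
  c(hit = inter / length(L),
    novel = if (length(Lp) == 0) 0 else extra / length(Lp),
    jaccard = if (uni == 0) 1 else inter / uni)
}

# Brute-force F-measures from explicit 0/1 indicator matrices.
oracle_f_measures <- function(pairs, N) {
  l <- length(pairs$gene_id)
  Y <- matrix(0L, l, N)
  Yp <- matrix(0L, l, N)
  for (i in seq_len(l)) {
    for (j in pairs$true[[i]]) Y[i, j] <- 1L
    for (j in pairs$predicted[[i]]) Yp[i, j] <- 1L
  }
  per <- numeric(N)
  num_tot <- 0; den_tot <- 0
  for (j in seq_len(N)) {
    num <- sum(Yp[, j] * Y[, j])
    den <- sum(Yp[, j]) + sum(Y[, j])
    per[j] <- if (den > 0) 2 * num / den else 0
    num_tot <- num_tot + num
    den_tot <- den_tot + den
  }
  list(per_label_f = per, macro_f = mean(per),
       micro_f = if (den_tot > 0) 2 * num_tot / den_tot else 0)
}

# Independent minimizer of the primal objective via a general-purpose
# quasi-Newton optimizer; returns the achieved objective value.
oracle_objective_min <- function(X, y, C, intercept = TRUE) {
  Xa <- if (intercept) cbind(as.matrix(X), 1) else as.matrix(X)
  obj <- function(w) {
    z <- as.numeric(Xa %*% w) * y
    0.5 * sum(w^2) + C * sum(log(1 + exp(-pmin(z, 700))))
  }
  gr <- function(w) {
    z <- as.numeric(Xa %*% w) * y
    s <- 1 / (1 + exp(pmin(z, 700)))
    w - C * as.numeric(t(Xa) %*% (y * s))
  }
  fit <- stats::optim(numeric(ncol(Xa)), obj, gr, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-15))
  fit$value
}

# Small planted study reused by several files: clean signal, background
# genes for a non-target class.
planted_study <- function(seed = 3, p_signal = 1, p_noise = 0,
                          n_drugs = 4, n_genes = 80, n_background = 12) {
  sim <- synth_corpus(synth_spec(n_drugs = n_drugs, n_genes = n_genes,
                                 vocab_size = 60, signature_size = 5,
                                 p_signal = p_signal, p_noise = p_noise,
                                 labels_per_gene = c(1, 2),
                                 n_background_genes = n_background, seed = seed))
  universe <- well_studied_genes(sim$annotations)
  ls <- build_label_space(sim$corpus, min_targets = 0, others_size = 0,
                          nontarget_size = min(6, n_background),
                          gene_universe = universe, seed = seed)
  vocab <- build_vocabulary(sim$annotations, universe)
  feats <- vectorize_genes(sim$annotations, vocab, label_space_genes(ls))
  list(sim = sim, label_space = ls, vocab = vocab, features = feats,
       universe = universe)
}
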