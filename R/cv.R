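# Stratified multi-label k-fold cross-validation and selection of the
# penalty parameter C over the standard power-of-two grid.

#' The power-of-two penalty grid
#'
#' `2^c(-11, -9, -7, -5, -3, 0, 3, 5, 7, 9, 11, 13, 15, 17)` -- the
#' grid C is chosen from during tuning.
#' @export
c_grid <- function() 2^c(-11, -9, -7, -5, -3, 0, 3, 5, 7, 9, 11, 13, 15, 17)

#' Cross-validate a binary-relevance DTI model
#'
#' Splits the class genes into k stratified multi-label folds, trains
#' the ensemble on k-1 folds, predicts the held-out genes, and pools
#' the resulting label-set pairs over all folds into one metrics
#' report. A class whose positive set is empty overall is dropped with
#' a message before folding; a class emptied by a particular training
#' split is excluded from that fold's ensemble with a warning.
#'
#' @param label_space A `label_space`.
#' @param features A `go_features` covering every class gene.
#' @param k Fold count (default 5).
#' @param C Penalty parameter.
#' @param seed Seed driving fold assignment.
#' @param xi Numeric aggregate thresholds (the symbolic 1/|L| is always
#'   added).
#' @param tol,intercept,compare_vectors Passed through to the fitter.
#' @return A `brdti_cv`: the `brdti_metrics` fields plus `folds`, `k`,
#'   `C`, `seed`, `pairs`, and `skipped` (classes dropped per fold).
#' @export
cv_brdti <- function(label_space, features, k = 5L, C = 1, seed = 1L,
                     xi = seq(0.1, 1, by = 0.1), tol = 1e-6, intercept = TRUE,
                     compare_vectors = TRUE) {
  stopifnot(inherits(label_space, "label_space"), inherits(features, "go_features"))
  empty_global <- which(lengths(label_space$gene_sets) == 0L)
  if (length(empty_global) > 0) {
    message("dropping ", length(empty_global), " class(es) with no genes: ",
            paste(label_space$labels[empty_global], collapse = ", "))
  }
  genes <- label_space_genes(label_space)
  labelsets <- label_space_labelsets(label_space)
  folds <- stratify_folds(genes, labelsets, k = k, seed = seed)

  gene_ids <- character(0); truth <- list(); pred <- list()
  skipped <- vector("list", k)
  for (f in seq_len(k)) {
    train <- names(folds$fold)[folds$fold != f]
    test <- names(folds$fold)[folds$fold == f]
    sub_sets <- lapply(label_space$gene_sets, function(g) intersect(g, train))
    keep <- which(lengths(sub_sets) > 0L)
    dropped <- setdiff(seq_len(label_space$N), keep)
    fold_dropped <- setdiff(dropped, empty_global)
    if (length(fold_dropped) > 0) {
      warning("fold ", f, ": class(es) with no training positives excluded: ",
              paste(label_space$labels[fold_dropped], collapse = ", "), call. = FALSE)
    }
    skipped[[f]] <- dropped
    sub_space <- structure(list(labels = label_space$labels[keep],
                                gene_sets = sub_sets[keep],
                                others_index = NA_integer_, nontarget_index = NA_integer_,
                                N = length(keep)),
                           class = "label_space")
    fit <- brdti(sub_space, features_subset(features, train), C = C, tol = tol,
                 intercept = intercept, compare_vectors = compare_vectors,
                 skip_empty = TRUE)
    prob <- predict(fit, features_subset(features, test), type = "prob")
    for (r in seq_along(test)) {
      g <- test[[r]]
      p <- prob[r, ]
      sel <- which(!is.na(p) & p > 0.5)
      gene_ids <- c(gene_ids, g)
      truth <- c(truth, list(labelsets[[g]]))
      pred <- c(pred, list(keep[sel]))  # back to original class indices
    }
  }
  pairs <- label_set_pairs(gene_ids, truth, pred)
  rep <- metrics_report(pairs, N = label_space$N, xi = xi)
  out <- unclass(rep)
  out$folds <- folds
  out$k <- as.integer(k)
  out$C <- C
  out$seed <- as.integer(seed)
  out$pairs <- pairs
  out$skipped <- skipped
  class(out) <- c("brdti_cv", "brdti_metrics")
  out
}

#' @export
print.brdti_cv <- function(x, ...) {
  cat("Stratified multi-label ", x$k, "-fold cross-validation (C = ", format(x$C),
      ", seed ", x$seed, ")\n", sep = "")
  NextMethod()
}

#' Plot per-label F-measures of a cross-validation run
#'
#' @param x A `brdti_cv` (or any `brdti_metrics`).
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.brdti_cv <- function(x, ...) {
  graphics::barplot(x$per_label_f, names.arg = seq_along(x$per_label_f),
                    xlab = "class index", ylab = "F-measure",
                    main = "Per-label F-measure", ...)
  invisible(x)
}

#' Select the penalty parameter over a grid
#'
#' Runs [cv_brdti()] for each candidate C (identical folds: the fold
#' assignment depends only on the genes, label sets, k and seed) and
#' returns the C with the best one-hit rate, the HitRate aggregate at
#' the symbolic threshold 1/|L|. Ties go to the larger C.
#'
#' @param label_space,features,k,seed,... As in [cv_brdti()].
#' @param grid Candidate C values (default [c_grid()]).
#' @return A `brdti_tune`: list with `best_c`, `table` (per-C one-hit
#'   rates), and `reports` (per-C `brdti_cv` objects, named by C).
#' @export
tune_c <- function(label_space, features, grid = c_grid(), k = 5L, seed = 1L, ...) {
  stopifnot(length(grid) > 0, all(grid > 0))
  grid <- sort(unique(as.numeric(grid)))
  reports <- lapply(grid, function(C) cv_brdti(label_space, features, k = k, C = C,
                                               seed = seed, ...))
  names(reports) <- vapply(grid, format, character(1))
  one_hit <- vapply(reports, aggregate_value, numeric(1), metric = "hit",
                    threshold = "1/|L|")
  # best one-hit rate; ties broken toward larger C (grid is ascending)
  best <- max(one_hit)
  best_c <- grid[max(which(one_hit == best))]
  structure(list(best_c = best_c,
                 table = data.frame(C = grid, log2_C = log2(grid),
                                    one_hit_rate = unname(one_hit)),
                 reports = reports, k = as.integer(k), seed = as.integer(seed)),
            class = "brdti_tune")
}

#' @export
print.brdti_tune <- function(x, ...) {
  cat("Penalty selection over ", nrow(x$table), " grid values (", x$k,
      "-fold CV, seed ", x$seed, ")\n", sep = "")
  print(x$table, row.names = FALSE)
  cat("best C =", format(x$best_c), sprintf("(2^%g)\n", log2(x$best_c)))
  invisible(x)
}
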