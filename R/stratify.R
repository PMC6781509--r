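# Iterative stratification for multi-label k-fold cross-validation.
#
# Classic stratified k-fold preserves per-class proportions but assumes
# one label per example; with label sets the class subsets overlap, so
# proportions are maintained greedily instead: desired per-fold example
# counts (real-valued, count/k) are kept per label and per fold, the
# label with the fewest remaining unassigned examples is processed
# first (rare labels are the hardest to spread), each of its genes goes
# to the fold that still wants the most examples of that label, and the
# desired counts of *all* the gene's labels are decremented. Folds stay
# disjoint and near-equal-sized while each approximates the global
# label distribution.

#' Stratified multi-label fold assignment
#'
#' @param genes Character vector of instance ids (sorted internally, so
#'   input order never affects the result).
#' @param labelsets Named list mapping every gene to an integer vector
#'   of class indices (may be empty for label-free genes, which are
#'   placed last into the emptiest folds).
#' @param k Number of folds (>= 2, <= number of genes).
#' @param seed Integer seed; only tie-breaks beyond the desired-count
#'   rules consume randomness.
#' @param slack Warn if max - min fold size exceeds this (default 2;
#'   label structure can force folds slightly apart).
#' @return A `fold_assignment`: list with `k` and `fold`, a named
#'   integer vector in 1..k covering every gene.
#' @export
stratify_folds <- function(genes, labelsets, k, seed = 1L, slack = 2L) {
  genes <- sort(unique(as.character(genes)))
  stopifnot(is_count(k, min = 2L))
  if (k > length(genes)) stop("k (", k, ") exceeds the number of genes (", length(genes), ")",
                              call. = FALSE)
  labelsets <- lapply(genes, function(g) sort(unique(as.integer(labelsets[[g]]))))
  names(labelsets) <- genes
  labs <- sort(unique(unlist(labelsets)))
  n <- length(genes)

  fold <- integer(n)
  names(fold) <- genes
  desired_total <- rep(n / k, k)
  desired_label <- matrix(0, nrow = length(labs), ncol = k,
                          dimnames = list(as.character(labs), NULL))
  if (length(labs) > 0) {
    cnt <- table(factor(unlist(labelsets), levels = labs))
    desired_label[] <- as.numeric(cnt) / k
  }
  gene_labels <- labelsets  # by sorted gene

  with_seed(seed, {
    unassigned <- rep(TRUE, n)
    names(unassigned) <- genes
    assign_gene <- function(g, f) {
      fold[[g]] <<- f
      unassigned[[g]] <<- FALSE
      for (l in as.character(gene_labels[[g]])) {
        desired_label[l, f] <<- max(0, desired_label[l, f] - 1)
      }
      desired_total[f] <<- max(0, desired_total[f] - 1)
    }
    pick_fold <- function(want) {
      cand <- which(want == max(want))
      if (length(cand) > 1L) {
        tot <- desired_total[cand]
        cand <- cand[tot == max(tot)]
      }
      if (length(cand) > 1L) cand <- cand[sample.int(length(cand), 1L)] else cand
    }
    repeat {
      remaining <- vapply(as.character(labs), function(l) {
        sum(vapply(which(unassigned), function(ix) {
          as.integer(l) %in% gene_labels[[ix]]
        }, logical(1)))
      }, numeric(1))
      active <- remaining >= 1
      if (!length(remaining) || !any(active)) break
      # fewest remaining examples first; ties -> lowest class index
      lab <- as.character(labs)[active][which.min(remaining[active])]
      todo <- names(which(unassigned))
      todo <- todo[vapply(todo, function(g) as.integer(lab) %in% gene_labels[[g]], logical(1))]
      for (g in todo) assign_gene(g, pick_fold(desired_label[lab, ]))
    }
    for (g in names(which(unassigned))) assign_gene(g, pick_fold(desired_total))
  })

  sizes <- tabulate(fold, nbins = k)
  if (max(sizes) - min(sizes) > slack) {
    warning("fold sizes differ by ", max(sizes) - min(sizes), " (slack ", slack, ")")
  }
  structure(list(k = as.integer(k), fold = fold), class = "fold_assignment")
}

#' @export
print.fold_assignment <- function(x, ...) {
  cat("Fold assignment: ", length(x$fold), " genes in ", x$k, " folds (sizes ",
      paste(tabulate(x$fold, x$k), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Export fold assignments as TSV
#' @param folds A `fold_assignment`.
#' @param path Output path.
#' @export
write_folds <- function(folds, path) {
  stopifnot(inherits(folds, "fold_assignment"))
  utils::write.table(data.frame(gene_id = names(folds$fold), fold = unname(folds$fold)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-label balance of a fold partition
#'
#' For each label and fold, the absolute deviation of the fold's count
#' from the ideal count/k, relative to the label's total count. The
#' mean over labels and folds is a single imbalance score (lower is
#' better); uniform random partitions score visibly worse than the
#' iterative stratifier on multi-label data.
#'
#' @param folds A `fold_assignment` (or a bare named integer vector).
#' @param labelsets Named list gene -> integer class indices.
#' @param k Fold count (taken from `folds` when it is a
#'   `fold_assignment`).
#' @return List with `per_label` deviation matrix and `score`.
#' @export
fold_balance <- function(folds, labelsets, k = NULL) {
  if (inherits(folds, "fold_assignment")) {
    k <- folds$k
    fold <- folds$fold
  } else {
    stopifnot(!is.null(k))
    fold <- folds
  }
  genes <- names(fold)
  labs <- sort(unique(unlist(labelsets[genes])))
  dev <- matrix(NA_real_, nrow = length(labs), ncol = k,
                dimnames = list(as.character(labs), NULL))
  for (li in seq_along(labs)) {
    carriers <- genes[vapply(genes, function(g) labs[[li]] %in% labelsets[[g]], logical(1))]
    nl <- length(carriers)
    cnt <- tabulate(fold[carriers], nbins = k)
    dev[li, ] <- abs(cnt - nl / k) / nl
  }
  list(per_label = dev, score = mean(dev))
}
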