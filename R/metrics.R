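# Multi-label evaluation metrics.
#
# Per instance i with true label set L and predicted label set L':
#   HitRate(i)   = |L intersect L'| / |L|
#   NovelRate(i) = |L' - L| / |L'|          (0 when L' is empty)
#   Jaccard(i)   = |L intersect L'| / |L union L'|   (1 when both empty)
# Aggregates report, for a threshold xi, the fraction of instances
# whose per-instance value is >= xi; the symbolic threshold "1/|L|"
# compares each instance against its own 1/|L_i| (the "at least one
# correct drug" reading). Per-label F-measures come from indicator
# sums; macro-F is their unweighted mean and micro-F pools the sums
# over labels. DTI recall is the pooled fraction of known
# (gene, drug) interactions recovered.

#' Construct a set of true/predicted label-set pairs
#'
#' @param gene_id Character vector of instance identifiers.
#' @param true,predicted Lists (parallel to `gene_id`) of integer class
#'   indices.
#' @return A `label_set_pairs` object.
#' @export
label_set_pairs <- function(gene_id, true, predicted) {
  stopifnot(length(gene_id) == length(true), length(true) == length(predicted))
  structure(list(gene_id = as.character(gene_id),
                 true = lapply(true, function(v) sort(unique(as.integer(v)))),
                 predicted = lapply(predicted, function(v) sort(unique(as.integer(v))))),
            class = "label_set_pairs")
}

#' @export
length.label_set_pairs <- function(x) length(x$gene_id)

#' @export
print.label_set_pairs <- function(x, ...) {
  cat("Label-set pairs: ", length(x), " instances\n", sep = "")
  invisible(x)
}

#' Per-instance hit, novel, and Jaccard rates
#'
#' @param true Integer vector, the true label set (must be non-empty).
#' @param predicted Integer vector, the predicted label set.
#' @return Named numeric vector `c(hit, novel, jaccard)`.
#' @export
instance_metrics <- function(true, predicted) {
  true <- unique(as.integer(true))
  predicted <- unique(as.integer(predicted))
  if (length(true) == 0L) stop("true label set must be non-empty", call. = FALSE)
  inter <- length(intersect(true, predicted))
  hit <- inter / length(true)
  novel <- if (length(predicted) == 0L) 0 else length(setdiff(predicted, true)) / length(predicted)
  jaccard <- inter / length(union(true, predicted))
  c(hit = hit, novel = novel, jaccard = jaccard)
}

# Matrix of per-instance metrics for a pair set.
pair_metrics <- function(pairs) {
  stopifnot(inherits(pairs, "label_set_pairs"))
  t(vapply(seq_along(pairs$true),
           function(i) instance_metrics(pairs$true[[i]], pairs$predicted[[i]]),
           numeric(3)))
}

#' Thresholded aggregate of a per-instance metric
#'
#' @param pairs A `label_set_pairs` (non-empty).
#' @param metric `"hit"`, `"novel"`, or `"jaccard"`.
#' @param xi Numeric threshold in (0, 1\], or the string `"1/|L|"` for
#'   the symbolic per-instance threshold 1/|L_i|.
#' @return Fraction of instances whose metric is `>= xi`.
#' @export
threshold_aggregate <- function(pairs, metric = c("hit", "novel", "jaccard"), xi = 1) {
  metric <- match.arg(metric)
  stopifnot(inherits(pairs, "label_set_pairs"))
  if (length(pairs) == 0L) stop("empty pair list", call. = FALSE)
  vals <- pair_metrics(pairs)[, metric]
  if (identical(xi, "1/|L|")) {
    thr <- 1 / lengths(pairs$true)
  } else {
    stopifnot(is.numeric(xi), length(xi) == 1L, xi > 0, xi <= 1)
    thr <- rep(xi, length(vals))
  }
  mean(vals >= thr)
}

#' Per-label, macro-averaged, and micro-averaged F-measures
#'
#' Per-label F_j = 2 * sum_i y'_ji y_ji / (sum_i y'_ji + sum_i y_ji)
#' where y and y' are the true/predicted label indicators; a label with
#' zero denominator (never true and never predicted) gets F = 0 and is
#' counted in `n_zero_denominator`. Macro-F is the unweighted mean over
#' the N labels; micro-F pools the numerator and denominator sums over
#' labels first.
#'
#' @param pairs A `label_set_pairs`.
#' @param N Number of class labels (>= every referenced index).
#' @return List with `per_label_f` (length N), `macro_f`, `micro_f`,
#'   `n_zero_denominator`.
#' @export
label_f_measures <- function(pairs, N) {
  stopifnot(inherits(pairs, "label_set_pairs"), is_count(N, min = 1L))
  maxref <- suppressWarnings(max(0L, unlist(pairs$true), unlist(pairs$predicted)))
  if (maxref > N) stop("N (", N, ") smaller than a referenced label index (", maxref, ")",
                       call. = FALSE)
  tp <- numeric(N); npred <- numeric(N); ntrue <- numeric(N)
  for (i in seq_along(pairs$true)) {
    L <- pairs$true[[i]]; Lp <- pairs$predicted[[i]]
    ntrue[L] <- ntrue[L] + 1
    npred[Lp] <- npred[Lp] + 1
    b <- intersect(L, Lp)
    tp[b] <- tp[b] + 1
  }
  denom <- npred + ntrue
  per_label <- ifelse(denom > 0, 2 * tp / denom, 0)
  list(per_label_f = per_label,
       macro_f = mean(per_label),
       micro_f = if (sum(denom) > 0) 2 * sum(tp) / sum(denom) else 0,
       n_zero_denominator = sum(denom == 0))
}

#' Pooled recall of known drug-target interactions
#'
#' sum_i |L_i intersect L'_i| / sum_i |L_i|: the fraction of known
#' (gene, drug) interactions recovered across all instances.
#'
#' @param pairs A `label_set_pairs` (non-empty, with at least one
#'   non-empty true set).
#' @export
dti_recall <- function(pairs) {
  stopifnot(inherits(pairs, "label_set_pairs"))
  if (length(pairs) == 0L) stop("empty pair list", call. = FALSE)
  tot <- sum(lengths(pairs$true))
  if (tot == 0L) stop("all true label sets are empty", call. = FALSE)
  hits <- sum(vapply(seq_along(pairs$true), function(i) {
    length(intersect(pairs$true[[i]], pairs$predicted[[i]]))
  }, numeric(1)))
  hits / tot
}

#' Full metrics report for a set of label-set pairs
#'
#' @param pairs A `label_set_pairs`.
#' @param N Number of class labels.
#' @param xi Numeric thresholds for the aggregates; the symbolic
#'   threshold `"1/|L|"` is always included.
#' @return A `brdti_metrics` object: `per_instance` data frame,
#'   `aggregates` data frame (metric, xi, value; xi `"1/|L|"` for the
#'   symbolic row), `per_label_f`, `macro_f`, `micro_f`,
#'   `n_zero_denominator`, `dti_recall`, `n`.
#' @export
metrics_report <- function(pairs, N, xi = seq(0.1, 1, by = 0.1)) {
  stopifnot(inherits(pairs, "label_set_pairs"))
  if (length(pairs) == 0L) stop("empty pair list", call. = FALSE)
  pm <- pair_metrics(pairs)
  per_instance <- data.frame(gene_id = pairs$gene_id,
                             hit_rate = pm[, "hit"],
                             novel_rate = pm[, "novel"],
                             jaccard = pm[, "jaccard"],
                             stringsAsFactors = FALSE)
  xis <- c(as.list(xi), list("1/|L|"))
  agg <- do.call(rbind, lapply(c("hit", "novel", "jaccard"), function(m) {
    do.call(rbind, lapply(xis, function(x0) {
      data.frame(metric = m,
                 xi = if (is.character(x0)) x0 else format(x0),
                 value = threshold_aggregate(pairs, m, x0),
                 stringsAsFactors = FALSE)
    }))
  }))
  fm <- label_f_measures(pairs, N)
  structure(list(per_instance = per_instance, aggregates = agg,
                 per_label_f = fm$per_label_f, macro_f = fm$macro_f,
                 micro_f = fm$micro_f, n_zero_denominator = fm$n_zero_denominator,
                 dti_recall = dti_recall(pairs), n = length(pairs), N = N),
            class = "brdti_metrics")
}

# Look an aggregate up by metric + xi ("1/|L|" allowed).
#' @rdname metrics_report
#' @param report A `brdti_metrics`.
#' @param metric,threshold Row selector for `aggregate_value`.
#' @export
aggregate_value <- function(report, metric, threshold = "1/|L|") {
  stopifnot(inherits(report, "brdti_metrics"))
  key <- if (is.character(threshold)) threshold else format(threshold)
  row <- report$aggregates[report$aggregates$metric == metric & report$aggregates$xi == key, ]
  if (nrow(row) != 1L) stop("no aggregate for metric=", metric, " xi=", key, call. = FALSE)
  row$value
}

#' @export
print.brdti_metrics <- function(x, ...) {
  cat("Multi-label metrics over ", x$n, " instances (", x$N, " classes)\n", sep = "")
  one <- aggregate_value(x, "hit", "1/|L|")
  all <- aggregate_value(x, "hit", 1)
  cat(sprintf("  HitRate: %.2f%% (xi = 1/|L|), %.2f%% (xi = 1)\n", 100 * one, 100 * all))
  cat(sprintf("  NovelRate: %.2f%% (xi = 1/|L|), %.2f%% (xi = 1)\n",
              100 * aggregate_value(x, "novel", "1/|L|"), 100 * aggregate_value(x, "novel", 1)))
  cat(sprintf("  Jaccard: %.2f%% (xi = 1)\n", 100 * aggregate_value(x, "jaccard", 1)))
  cat(sprintf("  macro-F: %.4f   micro-F: %.4f   DTI recall: %.2f%%\n",
              x$macro_f, x$micro_f, 100 * x$dti_recall))
  invisible(x)
}

#' Serialize a metrics report to JSON / per-instance TSV
#'
#' @param report A `brdti_metrics`.
#' @param path Output path.
#' @export
write_metrics <- function(report, path) {
  stopifnot(inherits(report, "brdti_metrics"))
  payload <- list(container = "brdti-metrics", version = 1L,
                  n = report$n, N = report$N,
                  aggregates = report$aggregates,
                  per_label_f = report$per_label_f,
                  macro_f = report$macro_f, micro_f = report$micro_f,
                  n_zero_denominator = report$n_zero_denominator,
                  dti_recall = report$dti_recall)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}

#' @rdname write_metrics
#' @export
write_per_instance <- function(report, path) {
  stopifnot(inherits(report, "brdti_metrics"))
  utils::write.table(report$per_instance, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
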