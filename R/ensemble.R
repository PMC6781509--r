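# Binary-relevance ensemble: one l2-regularized logistic model per
# class label. For class i the positives are its gene set G_i and the
# negatives are the genes of all other classes, union(G_j) - G_i --
# every training example comes from an observed interaction, not from
# random pair sampling. A negative that collides with a positive (same
# gene id, or an identical feature vector) is removed so the small
# positive class stays intact.

#' Binary-relevance split for one class
#'
#' @param label_space A `label_space`.
#' @param features A `go_features` covering every class gene.
#' @param i Class index in 1..N.
#' @param compare_vectors When `TRUE` (default) a negative gene whose
#'   feature vector is identical to any positive's is also removed;
#'   when `FALSE` only gene-id collisions (set difference) apply.
#' @return A `binary_split`: list with `label_index`,
#'   `positive_genes`, `negative_genes` (both sorted).
#' @export
binary_split <- function(label_space, features, i, compare_vectors = TRUE) {
  stopifnot(inherits(label_space, "label_space"), inherits(features, "go_features"),
            is_count(i, min = 1L), i <= label_space$N)
  pos <- sort(label_space$gene_sets[[i]])
  if (length(pos) == 0L) {
    stop("class ", i, " (", label_space$labels[[i]], ") has an empty positive set",
         call. = FALSE)
  }
  neg <- sort(setdiff(unique(unlist(label_space$gene_sets, use.names = FALSE)), pos))
  if (compare_vectors && length(neg) > 0L) {
    sig <- feature_signatures(features, c(pos, neg))
    neg <- neg[!(sig[neg] %in% sig[pos])]
  }
  structure(list(label_index = as.integer(i), positive_genes = pos, negative_genes = neg),
            class = "binary_split")
}

# Row signature strings for exact feature-vector comparison.
feature_signatures <- function(features, genes) {
  x <- features$x[genes, , drop = FALSE]
  xt <- methods::as(methods::as(Matrix::t(x), "CsparseMatrix"), "generalMatrix")
  # column g of xt holds gene g's vector; encode its nonzero pattern
  starts <- xt@p[-length(xt@p)] + 1L
  ends <- xt@p[-1L]
  sig <- vapply(seq_along(genes), function(k) {
    if (ends[k] < starts[k]) "" else paste(xt@i[starts[k]:ends[k]], collapse = ",")
  }, character(1))
  names(sig) <- genes
  sig
}

#' Fit a binary-relevance multi-label drug-target model
#'
#' The main fitting function: trains one independent l2-regularized
#' logistic model per class in the label space (drug classes plus the
#' "others" and "non-target" sentinels) on the binary GO feature
#' matrix. Classes are fit in index order, but the models are
#' independent, so fitting order cannot change the result.
#'
#' @param label_space A `label_space` from [build_label_space()].
#' @param features A `go_features` from [vectorize_genes()] whose rows
#'   cover every class gene.
#' @param C Penalty parameter shared by all per-class models
#'   (default 1; see [tune_c()] for grid selection).
#' @param tol,intercept,compare_vectors Passed to [fit_logistic()] /
#'   [binary_split()].
#' @param skip_empty When `TRUE`, classes with an empty positive set
#'   (or with only one response class after conflict removal) are
#'   dropped with a warning instead of raising an error; used by
#'   cross-validation where a fold can empty a small class.
#' @return A `brdti` object: list with `models` (per class index; `NULL`
#'   for skipped classes), `label_space`, `vocabulary`, `C`, `call`.
#' @seealso [predict.brdti()], [cv_brdti()], [extract_novel()]
#' @examples
#' sim <- synth_corpus(synth_spec(n_drugs = 3, n_genes = 60, vocab_size = 40,
#'                                signature_size = 4, seed = 1))
#' ls <- build_label_space(sim$corpus, min_targets = 0, others_size = 0,
#'                         nontarget_size = 0, seed = 1)
#' vocab <- build_vocabulary(sim$annotations, corpus_genes(sim$corpus))
#' feats <- vectorize_genes(sim$annotations, vocab, label_space_genes(ls))
#' fit <- brdti(ls, feats, C = 1, skip_empty = TRUE)
#' fit
#' @export
brdti <- function(label_space, features, C = 1, tol = 1e-6, intercept = TRUE,
                  compare_vectors = TRUE, skip_empty = FALSE) {
  stopifnot(inherits(label_space, "label_space"), inherits(features, "go_features"))
  genes_needed <- label_space_genes(label_space)
  if (!all(genes_needed %in% rownames(features$x))) {
    stop("features do not cover every class gene", call. = FALSE)
  }
  models <- vector("list", label_space$N)
  for (i in seq_len(label_space$N)) {
    fit <- tryCatch({
      sp <- binary_split(label_space, features, i, compare_vectors = compare_vectors)
      if (length(sp$negative_genes) == 0L) {
        stop("class ", i, " has no negatives after conflict removal", call. = FALSE)
      }
      rows <- c(sp$positive_genes, sp$negative_genes)
      y <- c(rep(1, length(sp$positive_genes)), rep(-1, length(sp$negative_genes)))
      m <- fit_logistic(features$x[rows, , drop = FALSE], y, C = C, tol = tol,
                        intercept = intercept)
      m$label_index <- i
      m$n_pos <- length(sp$positive_genes)
      m$n_neg <- length(sp$negative_genes)
      m
    }, error = function(e) {
      if (skip_empty) {
        warning("class ", i, " (", label_space$labels[[i]], ") skipped: ",
                conditionMessage(e), call. = FALSE)
        NULL
      } else {
        stop("class ", i, " (", label_space$labels[[i]], "): ",
             conditionMessage(e), call. = FALSE)
      }
    })
    models[i] <- list(fit)  # keep NULL slots for skipped classes
  }
  structure(list(models = models, label_space = label_space,
                 vocabulary = features$vocabulary, C = C,
                 intercept = intercept, call = match.call()),
            class = "brdti")
}

#' @export
print.brdti <- function(x, ...) {
  fitted <- sum(!vapply(x$models, is.null, logical(1)))
  cat("Binary-relevance multi-label DTI model\n")
  cat("  classes: ", x$label_space$N, " (", fitted, " fitted)",
      "   features: ", length(x$vocabulary$terms),
      "   C = ", format(x$C), "\n", sep = "")
  invisible(x)
}

#' @export
summary.brdti <- function(object, ...) {
  ms <- object$models
  fitted <- !vapply(ms, is.null, logical(1))
  tab <- data.frame(
    label_index = seq_along(ms),
    label = object$label_space$labels,
    n_pos = vapply(ms, function(m) if (is.null(m)) NA_integer_ else m$n_pos, integer(1)),
    n_neg = vapply(ms, function(m) if (is.null(m)) NA_integer_ else m$n_neg, integer(1)),
    objective = vapply(ms, function(m) if (is.null(m)) NA_real_ else m$objective, numeric(1)),
    converged = vapply(ms, function(m) if (is.null(m)) NA else m$converged, logical(1)),
    stringsAsFactors = FALSE
  )
  structure(list(table = tab, C = object$C, n_features = length(object$vocabulary$terms),
                 n_fitted = sum(fitted)),
            class = "summary.brdti")
}

#' @export
print.summary.brdti <- function(x, ...) {
  cat("Binary-relevance ensemble: ", nrow(x$table), " classes (", x$n_fitted,
      " fitted), ", x$n_features, " GO-term features, C = ", format(x$C), "\n\n", sep = "")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' @export
coef.brdti <- function(object, ...) {
  p <- length(object$vocabulary$terms) + as.integer(object$intercept)
  out <- matrix(NA_real_, nrow = p, ncol = object$label_space$N,
                dimnames = list(c(object$vocabulary$terms,
                                  if (object$intercept) "(Intercept)"),
                                object$label_space$labels))
  for (i in seq_along(object$models)) {
    m <- object$models[[i]]
    if (!is.null(m)) out[, i] <- m$weights
  }
  out
}

#' Predict drug label sets for genes
#'
#' For each gene the ensemble evaluates every per-class decision value
#' f_i(g) = w_i'x; the predicted label set is \{i : f_i(g) > 0\},
#' equivalently posterior probability strictly above 0.5 (a decision
#' value of exactly 0 is negative). The feature matrix must carry the
#' vocabulary hash the model was trained with.
#'
#' @param object A fitted `brdti` model.
#' @param features A `go_features` with the same vocabulary (hash
#'   checked), or a numeric matrix with one column per vocabulary term
#'   (no hash check possible, accepted as-is).
#' @param type `"labels"` (default) returns a list, one element per
#'   gene, of named probability vectors over the predicted classes
#'   (names = class index, attribute `"label"` = class labels);
#'   `"prob"` the full gene x class probability matrix; `"link"` the
#'   decision-value matrix. Skipped classes yield `NA` columns and are
#'   never predicted.
#' @param threshold Probability cutoff for `type = "labels"`
#'   (strict `>`; default 0.5, the f_i(g) > 0 rule).
#' @param ... Unused.
#' @export
predict.brdti <- function(object, features, type = c("labels", "prob", "link"),
                          threshold = 0.5, ...) {
  type <- match.arg(type)
  if (inherits(features, "go_features")) {
    if (features$vocabulary$hash != object$vocabulary$hash) {
      stop("feature vocabulary hash does not match the model's; re-vectorize the genes ",
           "with the model's vocabulary (model ", object$vocabulary$hash, ", features ",
           features$vocabulary$hash, ")", call. = FALSE)
    }
    x <- features$x
  } else {
    x <- features
    if (ncol(x) != length(object$vocabulary$terms)) {
      stop("feature matrix has ", ncol(x), " columns; vocabulary has ",
           length(object$vocabulary$terms), call. = FALSE)
    }
  }
  link <- matrix(NA_real_, nrow = nrow(x), ncol = object$label_space$N,
                 dimnames = list(rownames(x), object$label_space$labels))
  for (i in seq_along(object$models)) {
    m <- object$models[[i]]
    if (!is.null(m)) link[, i] <- logit_link(m, x)
  }
  if (type == "link") return(link)
  prob <- plogis(link)
  if (type == "prob") return(prob)
  out <- lapply(seq_len(nrow(prob)), function(r) {
    p <- prob[r, ]
    sel <- which(!is.na(p) & p > threshold)
    v <- p[sel]
    names(v) <- as.character(sel)
    attr(v, "label") <- object$label_space$labels[sel]
    v
  })
  names(out) <- rownames(x)
  out
}

#' Serialize / restore a fitted ensemble
#'
#' A versioned JSON container holding the per-class weights, C, the
#' label space, and the vocabulary with its content hash; written with
#' full numeric precision so identical fits serialize byte-identically
#' across runs and platforms.
#'
#' @param model A `brdti` object.
#' @param path Output (input) path.
#' @return `write_brdti` the path, invisibly; `read_brdti` the model.
#' @export
write_brdti <- function(model, path) {
  stopifnot(inherits(model, "brdti"))
  payload <- list(
    container = "brdti-model",
    version = 1L,
    C = model$C,
    intercept = model$intercept,
    label_space = label_space_to_list(model$label_space),
    vocabulary = list(terms = model$vocabulary$terms, hash = model$vocabulary$hash),
    models = lapply(model$models, function(m) {
      if (is.null(m)) return(NULL)
      list(label_index = m$label_index, weights = unname(m$weights), C = m$C,
           n_pos = m$n_pos, n_neg = m$n_neg, objective = m$objective,
           converged = m$converged, intercept = m$intercept)
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = FALSE)
  invisible(path)
}

#' @rdname write_brdti
#' @export
read_brdti <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                                 simplifyMatrix = FALSE)
  if (!identical(payload$container, "brdti-model")) {
    stop("not a brdti model container: ", path, call. = FALSE)
  }
  ls <- label_space_from_list(payload$label_space)
  vocab <- structure(list(terms = as.character(payload$vocabulary$terms),
                          hash = payload$vocabulary$hash),
                     class = "go_vocabulary")
  wnames <- c(vocab$terms, if (isTRUE(payload$intercept)) "(Intercept)")
  if (!is.list(payload$models)) {
    # a run of nulls simplifies to an atomic NA vector
    payload$models <- vector("list", length(payload$models))
  }
  models <- lapply(payload$models, function(m) {
    if (is.null(m) || (!is.list(m) && all(is.na(m)))) return(NULL)
    w <- as.numeric(m$weights)
    names(w) <- wnames
    structure(list(weights = w, C = m$C, objective = m$objective, trace = numeric(0),
                   gradient_norm = NA_real_, iterations = NA_integer_,
                   converged = isTRUE(m$converged), intercept = isTRUE(m$intercept),
                   label_index = as.integer(m$label_index),
                   n_pos = as.integer(m$n_pos), n_neg = as.integer(m$n_neg)),
              class = "brdti_logit")
  })
  structure(list(models = models, label_space = ls, vocabulary = vocab,
                 C = payload$C, intercept = isTRUE(payload$intercept),
                 call = NULL),
            class = "brdti")
}
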