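# The l2-regularized logistic base classifier.
#
# For training pairs (x_i, y_i), y_i in {-1,+1}, the model minimizes
#
#   f(w) = (1/2) w'w + C * sum_i log(1 + exp(-y_i w'x_i))
#
# over the weight vector w (an intercept is appended as a constant
# feature and regularized with the rest, the liblinear convention).
# The primal is smooth and strongly convex, so a damped Newton method
# with Armijo backtracking converges in a handful of iterations at the
# feature dimensions binary GO vectors produce; the solver stops when
# the primal gradient norm drops below `tol`.

#' Fit an l2-regularized logistic model
#'
#' @param x Numeric matrix or `Matrix::dgCMatrix`, rows = training
#'   examples. Binary GO features in this package, but any finite
#'   numeric features are accepted.
#' @param y Labels in \{-1, +1\} (or a logical vector, `TRUE` = +1);
#'   both classes must be present.
#' @param C Positive penalty parameter weighting the logistic loss
#'   against the ridge term. Larger C fits the data harder.
#' @param tol Convergence tolerance on the primal gradient norm.
#' @param intercept Append a regularized constant feature (default
#'   `TRUE`).
#' @param max_iter Newton iteration cap.
#' @return A `brdti_logit`: list with `weights` (named, intercept slot
#'   last as `"(Intercept)"` when present), `C`, `objective`, `trace`
#'   (objective value per iteration, non-increasing), `gradient_norm`,
#'   `iterations`, `converged`, `intercept`.
#' @examples
#' x <- matrix(c(1, -1), ncol = 1)
#' m <- fit_logistic(x, c(1, -1), C = 1)
#' sign(x %*% m$weights[1])
#' @export
fit_logistic <- function(x, y, C = 1, tol = 1e-6, intercept = TRUE,
                         max_iter = 200L) {
  if (is.logical(y)) y <- ifelse(y, 1, -1)
  y <- as.numeric(y)
  stopifnot(is.numeric(C), length(C) == 1L, C > 0, tol > 0)
  if (!all(y %in% c(-1, 1))) stop("y must be coded -1/+1", call. = FALSE)
  if (length(unique(y)) < 2L) stop("both classes must be present in y", call. = FALSE)
  X <- methods::as(methods::as(x, "CsparseMatrix"), "generalMatrix")
  if (!methods::is(X, "dMatrix")) X <- X * 1  # pattern/logical -> numeric
  if (nrow(X) != length(y)) stop("nrow(x) must equal length(y)", call. = FALSE)
  if (any(!is.finite(X@x))) stop("non-finite feature values", call. = FALSE)
  feat_names <- colnames(X) %||% paste0("V", seq_len(ncol(X)))
  if (intercept) {
    X <- cbind(X, Matrix::Matrix(1, nrow(X), 1, sparse = TRUE))
    feat_names <- c(feat_names, "(Intercept)")
  }
  p <- ncol(X)
  w <- numeric(p)
  Ip <- diag(p)

  objective <- function(w) {
    z <- as.numeric(X %*% w) * y
    0.5 * sum(w^2) + C * sum(log1pexp(-z))
  }

  trace <- numeric(0)
  f <- objective(w)
  gn <- Inf
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    z <- as.numeric(X %*% w) * y
    s <- plogis(-z)                       # sigma(-y w'x)
    g <- w - C * as.numeric(Matrix::crossprod(X, y * s))
    gn <- sqrt(sum(g^2))
    trace <- c(trace, f)
    if (gn <= tol) { converged <- TRUE; break }
    d <- s * (1 - s)
    H <- Ip + C * as.matrix(Matrix::crossprod(X, X * d))
    step <- solve(H, g)
    # Armijo backtracking on the Newton direction
    t <- 1
    gTs <- sum(g * step)
    repeat {
      f_new <- objective(w - t * step)
      if (f_new <= f - 1e-4 * t * gTs || t < 2^-30) break
      t <- t / 2
    }
    w <- w - t * step
    f <- f_new
    iter <- iter + 1L
  }
  if (!converged) {
    # final gradient check after the last step
    z <- as.numeric(X %*% w) * y
    g <- w - C * as.numeric(Matrix::crossprod(X, y * plogis(-z)))
    gn <- sqrt(sum(g^2))
    converged <- gn <= tol
    trace <- c(trace, objective(w))
    if (!converged) warning("fit_logistic: gradient norm ", format(gn),
                            " above tol after ", max_iter, " iterations")
  }
  names(w) <- feat_names
  structure(list(weights = w, C = C, objective = objective(w), trace = trace,
                 gradient_norm = gn, iterations = iter, converged = converged,
                 intercept = intercept),
            class = "brdti_logit")
}

#' @export
print.brdti_logit <- function(x, ...) {
  cat("l2-regularized logistic model: ", length(x$weights), " weights, C = ",
      format(x$C), ", objective = ", format(x$objective), "\n", sep = "")
  invisible(x)
}

# P(y = +1 | x) for a fitted model on a feature matrix (no intercept
# column; appended here when the model has one).
logit_prob <- function(model, x) {
  plogis(logit_link(model, x))
}

# Decision value w'x (intercept included).
logit_link <- function(model, x) {
  w <- model$weights
  if (model$intercept) {
    b <- w[length(w)]
    w <- w[-length(w)]
    as.numeric(x %*% w) + b
  } else {
    as.numeric(x %*% w)
  }
}
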