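# Elastic net regression backend (glmnet) with the replicate-based alpha
# tuning: cross-validation fold assignment is itself a noticeable source of
# variability at these sample sizes, so each candidate alpha is scored by
# the median across replicate cv.glmnet runs of the MAE at lambda.min.

enr_replicate_mae <- function(X, y, alpha, weights = NULL, nfolds = 10,
                              seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  args <- list(x = X, y = y, alpha = alpha, nfolds = nfolds, keep = TRUE)
  if (nrow(X) < 3 * nfolds) args$grouped <- FALSE  # what glmnet would force
  if (!is.null(weights)) args$weights <- weights
  cvfit <- do.call(glmnet::cv.glmnet, args)
  k <- match(cvfit$lambda.min, cvfit$lambda)
  prev <- cvfit$fit.preval[, k]  # cross-validated predictions at lambda.min
  median(abs(prev - y))
}

#' Tune the elastic net mixing parameter alpha
#'
#' For each candidate alpha, runs `n_reps` replicate 10-fold cross-validated
#' elastic-net fits (fold assignments redrawn each replicate), records the
#' median absolute error of the cross-validated predictions at the
#' deviance-minimising penalty (`lambda.min`), and minimises the median
#' replicate MAE over alpha with a bounded scalar optimiser. Replicate
#' seeds are shared across alphas (common random numbers), so the
#' objective is deterministic given `seed`.
#'
#' @param X numeric matrix, samples x sites.
#' @param y numeric response.
#' @param weights optional observation weights.
#' @param alpha_range search bounds (published bounds 1e-4 to 0.5).
#' @param n_reps replicate cv.glmnet runs per alpha (published scale 1000).
#' @param nfolds cross-validation folds.
#' @param tol optimiser tolerance on alpha.
#' @param seed master seed.
#' @return the selected alpha.
#' @export
tune_enr_alpha <- function(X, y, weights = NULL, alpha_range = c(1e-4, 0.5),
                           n_reps = 1000, nfolds = 10, tol = 0.01,
                           seed = 1L) {
  stopifnot(n_reps >= 1, length(alpha_range) == 2)
  if (nrow(X) < nfolds) stop("fewer samples than cross-validation folds")
  rep_seeds <- vapply(seq_len(n_reps), function(i) derive_seed(seed, i),
                      integer(1))
  obj <- function(alpha) {
    maes <- vapply(rep_seeds, function(s)
      enr_replicate_mae(X, y, alpha, weights, nfolds, s), numeric(1))
    median(maes)
  }
  if (diff(alpha_range) < .Machine$double.eps) return(alpha_range[1])
  optimize(obj, interval = alpha_range, tol = tol)$minimum
}

#' Fit an elastic net age model
#'
#' Runs one more cross-validation at the chosen alpha to pick `lambda.min`,
#' then refits on the full data.
#'
#' @inheritParams tune_enr_alpha
#' @param alpha the mixing parameter (e.g. from [tune_enr_alpha()]).
#' @return an `enr_model` with the glmnet fit and chosen (alpha, lambda).
#' @export
enr_fit <- function(X, y, alpha, weights = NULL, nfolds = 10, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  args <- list(x = X, y = y, alpha = alpha, nfolds = min(nfolds, nrow(X)))
  if (nrow(X) < 3 * args$nfolds) args$grouped <- FALSE
  if (!is.null(weights)) args$weights <- weights
  cvfit <- do.call(glmnet::cv.glmnet, args)
  structure(list(fit = cvfit$glmnet.fit, lambda = cvfit$lambda.min,
                 alpha = alpha), class = "enr_model")
}

#' @export
predict.enr_model <- function(object, newdata, ...) {
  as.vector(predict(object$fit, newx = as.matrix(newdata),
                    s = object$lambda))
}
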