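# R-level interface to the compiled regression random forest, plus the
# (sampsize, mtry) grid tuning with a median-smoothed out-of-bag error
# surface standing in for by-eye selection.

#' Fit a regression random forest
#'
#' Bootstrap-aggregated CART regression trees with `mtry` randomly drawn
#' candidate sites per node. Out-of-bag (OOB) predictions are accumulated
#' during fitting. Sample weights, when supplied, weight the bootstrap
#' sampling probabilities.
#'
#' @param X numeric matrix, samples x sites.
#' @param y numeric response (ages, possibly log-transformed).
#' @param ntree number of trees (published default 10000; desk-scale tests use
#'   a few hundred).
#' @param mtry candidate sites per split (default `max(1, floor(p / 3))`).
#' @param sampsize bootstrap sample size per tree (default `n`).
#' @param weights optional per-sample sampling weights.
#' @param nodesize minimum node size before splitting stops (default 5).
#' @param seed integer seed for the forest's RNG.
#' @return an `rf_model` with the trees, OOB predictions and OOB MSE.
#' @export
rf_fit <- function(X, y, ntree = 500, mtry = NULL, sampsize = NULL,
                   weights = NULL, nodesize = 5, seed = 1L) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), all(is.finite(X)), all(is.finite(y)))
  if (is.null(mtry)) mtry <- max(1L, floor(ncol(X) / 3))
  if (is.null(sampsize)) sampsize <- nrow(X)
  if (is.null(weights)) weights <- numeric(0)
  fit <- rf_fit_cpp(X, as.numeric(y), as.integer(ntree), as.integer(mtry),
                    as.integer(sampsize), as.numeric(weights),
                    as.integer(nodesize), as.integer(seed))
  oob <- fit$oob_pred
  structure(list(trees = fit$trees, inbag = fit$inbag, oob_pred = oob,
                 oob_count = fit$oob_count,
                 oob_mse = mean((oob - y)^2, na.rm = TRUE),
                 mtry = mtry, sampsize = sampsize, ntree = ntree,
                 nodesize = nodesize, seed = seed,
                 X = X, y = as.numeric(y)),
            class = "rf_model")
}

#' @export
predict.rf_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  rf_predict_cpp(object$trees, newdata)
}

#' Permutation importance of a fitted forest
#'
#' Mean increase in per-tree out-of-bag MSE when each site's OOB values are
#' shuffled.
#'
#' @param fit an `rf_model`.
#' @param seed RNG seed for the shuffles.
#' @return numeric vector of importances, one per site.
#' @export
rf_importance <- function(fit, seed = 1L) {
  stopifnot(inherits(fit, "rf_model"))
  imp <- rf_importance_cpp(fit$trees, fit$inbag, fit$X, fit$y,
                           as.integer(seed))
  setNames(imp, colnames(fit$X))
}

# 3x3 median smoothing of the OOB error surface: a deterministic surrogate
# for picking the grid optimum from a visual inspection of the noisy
# error distribution.
median_filter_2d <- function(m) {
  out <- m
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    ri <- max(1, i - 1):min(nrow(m), i + 1)
    rj <- max(1, j - 1):min(ncol(m), j + 1)
    out[i, j] <- stats::median(m[ri, rj])
  }
  out
}

#' Tune a random forest over the (sampsize, mtry) grid
#'
#' Builds forests over `sampsize` in 0.3n..0.7n and `mtry` in 0.1s..0.5s
#' (integer grids, optionally thinned to at most `grid_n` points per axis
#' for desk-scale runs), smooths the OOB-MSE surface with a 3x3 median
#' filter, and returns the grid minimum.
#'
#' @inheritParams rf_fit
#' @param ntree trees per candidate forest.
#' @param grid_n maximum grid points per axis (NULL = full integer grid).
#' @return list with `sampsize`, `mtry`, the raw and smoothed MSE surfaces.
#' @export
rf_tune <- function(X, y, weights = NULL, ntree = 500, grid_n = NULL,
                    seed = 1L) {
  n <- nrow(X); s <- ncol(X)
  ss <- seq.int(max(2L, floor(0.3 * n)), max(2L, floor(0.7 * n)))
  mt <- seq.int(max(1L, floor(0.1 * s)), max(1L, floor(0.5 * s)))
  thin <- function(v, k) if (!is.null(k) && length(v) > k)
    unique(round(seq(min(v), max(v), length.out = k))) else v
  ss <- thin(ss, grid_n); mt <- thin(mt, grid_n)
  mse <- matrix(NA_real_, length(ss), length(mt),
                dimnames = list(ss, mt))
  cnt <- 0L
  for (i in seq_along(ss)) for (j in seq_along(mt)) {
    cnt <- cnt + 1L
    f <- rf_fit(X, y, ntree = ntree, mtry = mt[j], sampsize = ss[i],
                weights = weights, seed = derive_seed(seed, cnt))
    mse[i, j] <- f$oob_mse
  }
  sm <- median_filter_2d(mse)
  k <- which(sm == min(sm), arr.ind = TRUE)[1, ]
  list(sampsize = ss[k[1]], mtry = mt[k[2]], mse = mse, smoothed = sm)
}
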