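# Stepwise CpG site selection preceding clock training: elastic-net
# inclusion frequency across replicate cross-validated fits, or
# random-forest permutation importance with a response-permutation null.

#' Select CpG sites by elastic-net inclusion frequency
#'
#' Runs `n_reps` replicate elastic-net fits, each with its own 10-fold
#' cross-validation split, records which sites have a nonzero coefficient
#' at the deviance-minimising penalty, and selects sites included in at
#' least `freq_threshold` of the replicates (published scale: 1000 replicates,
#' threshold 0.5).
#'
#' @param X numeric matrix, samples x sites (the site-selection sample
#'   subset).
#' @param y response (ages, transformed or not).
#' @param weights optional CR weights.
#' @param n_reps replicate fits.
#' @param freq_threshold inclusion-frequency threshold in \[0, 1\].
#' @param alpha elastic-net mixing parameter; NULL tunes it once on this
#'   sample set via [tune_enr_alpha()] with `tune_reps` replicates.
#' @param tune_reps replicates for the alpha tuning when `alpha` is NULL.
#' @param nfolds cross-validation folds.
#' @param seed master seed.
#' @return a `site_selection` result: per-site frequency, the selected site
#'   ids, the threshold and alpha used.
#' @export
select_sites_enr <- function(X, y, weights = NULL, n_reps = 1000,
                             freq_threshold = 0.5, alpha = NULL,
                             tune_reps = 25, nfolds = 10, seed = 1L) {
  stopifnot(n_reps >= 1, freq_threshold >= 0, freq_threshold <= 1)
  X <- as.matrix(X)
  if (is.null(alpha))
    alpha <- tune_enr_alpha(X, y, weights, n_reps = tune_reps,
                            nfolds = nfolds, seed = derive_seed(seed, 0L))
  hits <- numeric(ncol(X))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  for (r in seq_len(n_reps)) {
    set.seed(derive_seed(seed, r))
    args <- list(x = X, y = y, alpha = alpha, nfolds = min(nfolds, nrow(X)))
    if (nrow(X) < 3 * args$nfolds) args$grouped <- FALSE
    if (!is.null(weights)) args$weights <- weights
    cvfit <- do.call(glmnet::cv.glmnet, args)
    cf <- as.matrix(coef(cvfit, s = "lambda.min"))[-1, 1]  # drop intercept
    hits <- hits + (cf != 0)
  }
  freq <- hits / n_reps
  # a site never included in any replicate is never selected, even at a
  # vacuous threshold of zero
  sel <- colnames(X)[freq >= freq_threshold & freq > 0]
  if (!length(sel))
    warning("no site reached the ENR inclusion-frequency threshold")
  structure(list(method = "ENR", score = setNames(freq, colnames(X)),
                 selected = sel, threshold = freq_threshold,
                 alpha = alpha, n_reps = n_reps),
            class = "site_selection")
}

#' Select CpG sites by random-forest permutation importance
#'
#' Fits a random forest, scores each site by the increase in out-of-bag MSE
#' when its values are permuted, and derives per-site p-values from a null
#' distribution of the same score under `n_perm` refits with the response
#' permuted. `p = (1 + #\{null >= observed\}) / (1 + n_perm)`; sites with
#' `p < p_threshold` are selected (published scale: 1000 permutations, p < 0.05).
#'
#' @inheritParams select_sites_enr
#' @param n_perm response-permutation refits for the null.
#' @param p_threshold selection threshold on the permutation p-value.
#' @param ntree trees per forest.
#' @param mtry,sampsize forest settings (defaults `p/3` and `n`).
#' @return a `site_selection` result with importances and p-values.
#' @export
select_sites_rfr <- function(X, y, weights = NULL, n_perm = 1000,
                             p_threshold = 0.05, ntree = 500, mtry = NULL,
                             sampsize = NULL, seed = 1L) {
  stopifnot(n_perm >= 1)
  X <- as.matrix(X)
  fit <- rf_fit(X, y, ntree = ntree, mtry = mtry, sampsize = sampsize,
                weights = weights, seed = derive_seed(seed, 0L))
  obs <- rf_importance(fit, seed = derive_seed(seed, 1L))
  null <- matrix(NA_real_, n_perm, ncol(X))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  for (b in seq_len(n_perm)) {
    set.seed(derive_seed(seed, 2L * b))
    yp <- sample(y)
    pf <- rf_fit(X, yp, ntree = ntree, mtry = mtry, sampsize = sampsize,
                 weights = weights, seed = derive_seed(seed, 2L * b + 1L))
    null[b, ] <- rf_importance(pf, seed = derive_seed(seed, 2L * b + 1L))
  }
  pval <- vapply(seq_len(ncol(X)), function(j)
    (1 + sum(null[, j] >= obs[j])) / (1 + n_perm), numeric(1))
  names(pval) <- colnames(X)
  sel <- colnames(X)[pval < p_threshold]
  structure(list(method = "RFR", score = obs, p_value = pval,
                 selected = sel, threshold = p_threshold, n_perm = n_perm),
            class = "site_selection")
}

#' @export
print.site_selection <- function(x, ...) {
  cat(sprintf("site_selection (%s): %d of %d sites selected (threshold %s)\n",
              x$method, length(x$selected), length(x$score),
              format(x$threshold)))
  invisible(x)
}

#' Write a site-selection result as TSV for audit
#'
#' @param sel a `site_selection`.
#' @param path output path.
#' @export
write_site_selection <- function(sel, path) {
  df <- data.frame(site_id = names(sel$score), score = as.numeric(sel$score))
  if (!is.null(sel$p_value)) df$p_value <- as.numeric(sel$p_value)
  df$selected <- df$site_id %in% sel$selected
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
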