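# One training/prediction contract over the four regression backends
# (elastic net, random forest, support vector, generalised additive), with
# the optional log-age transform and prediction clamping to plausible ages.

.METHODS <- c("ENR", "RFR", "SVM", "GAM")
.TRANSFORMS <- c("none", "log")
.SITE_SEL <- c("all", "ENR", "RFR")
.SUBSETS <- c("All", "CR3+", "CR4+")

#' Tuning settings for clock training
#'
#' Published-scale defaults with a `"desk"` profile that thins every grid and
#' replicate count so a full config can be trained in seconds during tests.
#'
#' @param profile `"study"` (defaults at the published scale) or `"desk"`.
#' @param ... overrides of individual settings.
#' @return a `clock_tuning` list.
#' @export
clock_tuning <- function(profile = c("study", "desk"), ...) {
  profile <- match.arg(profile)
  t <- list(
    enr_alpha = NULL,                # NULL = tune; or a fixed value
    enr_alpha_range = c(1e-4, 0.5),
    enr_reps = 1000,                 # replicate cv.glmnet runs per alpha
    enr_nfolds = 10,
    enr_alpha_tol = 0.01,
    rfr_ntree = 10000,
    rfr_grid_n = NULL,               # NULL = full integer grids
    svm_step = 0.1,                  # log10 grid spacing
    svm_cost_range = c(-4, 5),
    svm_gamma_range = c(-5, 4),
    svm_nfolds = 10,
    svm_epsilon = 0.1,
    gam_k = 3,
    gam_k_max = 10,
    select_reps = 1000,              # ENR site-selection replicates
    select_freq = 0.5,
    select_nperm = 1000,             # RFR permutation count
    select_p = 0.05,
    clamp = c(0, 80))
  if (profile == "desk") {
    t$enr_reps <- 25; t$enr_alpha_tol <- 0.05
    t$rfr_ntree <- 500; t$rfr_grid_n <- 4
    t$svm_step <- 1
    t$select_reps <- 100; t$select_nperm <- 100
  }
  ov <- list(...)
  bad <- setdiff(names(ov), names(t))
  if (length(bad)) stop("unknown tuning settings: ", paste(bad, collapse = ", "))
  t[names(ov)] <- ov
  structure(t, class = "clock_tuning")
}

#' A point in the clock design grid
#'
#' @param method training backend: `"ENR"`, `"RFR"`, `"SVM"` or `"GAM"`.
#' @param age_transform `"none"` or `"log"` (train on ln age, exponentiate
#'   predictions).
#' @param site_selection `"all"` (no selection), `"ENR"` (inclusion
#'   frequency) or `"RFR"` (permutation importance).
#' @param site_selection_samples sample subset used for site selection.
#' @param training_samples sample subset used to train the final model.
#' @param weighted weight samples by their CR value. SVM has no weighting
#'   mechanism, so `weighted = TRUE` only affects its site-selection stage.
#' @param tuning a [clock_tuning()] object.
#' @return a `clock_config`.
#' @export
clock_config <- function(method = "ENR", age_transform = "none",
                         site_selection = "all",
                         site_selection_samples = "All",
                         training_samples = "All", weighted = FALSE,
                         tuning = clock_tuning("desk")) {
  method <- match.arg(method, .METHODS)
  age_transform <- match.arg(age_transform, .TRANSFORMS)
  site_selection <- match.arg(site_selection, .SITE_SEL)
  site_selection_samples <- match.arg(site_selection_samples, .SUBSETS)
  training_samples <- match.arg(training_samples, .SUBSETS)
  stopifnot(is.logical(weighted), inherits(tuning, "clock_tuning"))
  structure(list(method = method, age_transform = age_transform,
                 site_selection = site_selection,
                 site_selection_samples = site_selection_samples,
                 training_samples = training_samples, weighted = weighted,
                 tuning = tuning),
            class = "clock_config")
}

#' @export
print.clock_config <- function(x, ...) {
  cat(sprintf(
    "clock_config: %s / transform=%s / sites=%s(%s) / train=%s / weighted=%s\n",
    x$method, x$age_transform, x$site_selection, x$site_selection_samples,
    x$training_samples, x$weighted))
  invisible(x)
}

config_label <- function(cfg) {
  paste(cfg$method, cfg$age_transform, cfg$site_selection,
        cfg$site_selection_samples, cfg$training_samples,
        if (cfg$weighted) "wt" else "unwt", sep = "/")
}

#' Tune the hyperparameters of a clock configuration
#'
#' Performed once per configuration on its full training subset; leave-one-
#' out refits then hold the result fixed.
#'
#' @param config a [clock_config()].
#' @param X training matrix (already restricted to the selected sites and
#'   training subset).
#' @param y response on the model scale (log-transformed if configured).
#' @param weights optional CR weights.
#' @param seed integer seed.
#' @return a named list of hyperparameters for the backend.
#' @export
tune_clock <- function(config, X, y, weights = NULL, seed = 1L) {
  t <- config$tuning
  switch(config$method,
    ENR = {
      alpha <- t$enr_alpha
      if (is.null(alpha))
        alpha <- tune_enr_alpha(X, y, weights, t$enr_alpha_range,
                                n_reps = t$enr_reps, nfolds = t$enr_nfolds,
                                tol = t$enr_alpha_tol,
                                seed = derive_seed(seed, 1L))
      list(alpha = alpha)
    },
    RFR = {
      tu <- rf_tune(X, y, weights, ntree = min(t$rfr_ntree, 500),
                    grid_n = t$rfr_grid_n, seed = derive_seed(seed, 2L))
      list(sampsize = tu$sampsize, mtry = tu$mtry)
    },
    SVM = {
      tu <- svr_tune(X, y, cost_range = t$svm_cost_range,
                     gamma_range = t$svm_gamma_range, step = t$svm_step,
                     nfolds = t$svm_nfolds, epsilon = t$svm_epsilon,
                     seed = derive_seed(seed, 3L))
      list(cost = tu$cost, gamma = tu$gamma)
    },
    GAM = list(k = t$gam_k))
}

#' Train a clock
#'
#' Applies the configured age transform, fits the configured backend with
#' the given (or freshly tuned) hyperparameters, and returns a predictor.
#'
#' @param config a [clock_config()].
#' @param X numeric matrix, training samples x selected sites.
#' @param ages training ages in years (transformed internally if the config
#'   says so; must be positive for the log transform).
#' @param weights optional CR weights (ignored by SVM).
#' @param hyper optional pre-tuned hyperparameters (from [tune_clock()]);
#'   tuned here when NULL.
#' @param seed integer seed.
#' @return a `trained_clock`.
#' @export
train_clock <- function(config, X, ages, weights = NULL, hyper = NULL,
                        seed = 1L) {
  stopifnot(inherits(config, "clock_config"))
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("training matrix contains non-finite values")
  if (config$age_transform == "log" && any(ages <= 0))
    stop("log transform requires strictly positive ages")
  y <- if (config$age_transform == "log") log(ages) else ages
  if (config$method == "SVM") weights <- NULL
  if (is.null(hyper)) hyper <- tune_clock(config, X, y, weights, seed)
  t <- config$tuning
  fit <- switch(config$method,
    ENR = enr_fit(X, y, alpha = hyper$alpha, weights = weights,
                  nfolds = t$enr_nfolds, seed = derive_seed(seed, 11L)),
    RFR = rf_fit(X, y, ntree = t$rfr_ntree, mtry = hyper$mtry,
                 sampsize = hyper$sampsize, weights = weights,
                 seed = derive_seed(seed, 12L)),
    SVM = svr_fit(X, y, cost = hyper$cost, gamma = hyper$gamma,
                  epsilon = t$svm_epsilon),
    GAM = gam_fit(X, y, weights = weights, k = hyper$k,
                  k_max = t$gam_k_max))
  structure(list(config = config, fit = fit, hyper = hyper,
                 sites = colnames(X), transform = config$age_transform,
                 clamp = t$clamp),
            class = "trained_clock")
}

#' Predict ages from a trained clock
#'
#' Back-transforms (exponentiates under the log transform) and clamps
#' predictions to the plausible-age interval (default 0 to 80 years;
#' the species' oldest observed individual was 65).
#'
#' @param object a `trained_clock`.
#' @param newdata methylation matrix covering the clock's site set.
#' @param ... unused.
#' @return numeric vector of predicted ages in years.
#' @export
predict.trained_clock <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  miss <- setdiff(object$sites, colnames(newdata))
  if (length(miss))
    stop("newdata is missing clock sites: ", paste(miss, collapse = ", "))
  nd <- newdata[, object$sites, drop = FALSE]
  p <- predict(object$fit, nd)
  if (object$transform == "log") p <- exp(p)
  pmin(pmax(p, object$clamp[1]), object$clamp[2])
}

#' Out-of-bag predictions of a trained random-forest clock
#'
#' @param clock a `trained_clock` with method RFR.
#' @return back-transformed, clamped OOB predicted ages.
#' @export
oob_predictions <- function(clock) {
  stopifnot(inherits(clock, "trained_clock"),
            clock$config$method == "RFR")
  p <- clock$fit$oob_pred
  if (any(is.na(p)))
    stop("some samples were never out-of-bag; grow more trees")
  if (clock$transform == "log") p <- exp(p)
  pmin(pmax(p, clock$clamp[1]), clock$clamp[2])
}

#' Save / load a trained clock
#'
#' A trained clock reloaded in a new session predicts identically.
#'
#' @param clock a `trained_clock`.
#' @param path file path.
#' @return `load_clock` returns the restored clock.
#' @export
save_clock <- function(clock, path) {
  stopifnot(inherits(clock, "trained_clock"))
  saveRDS(list(format = "methclock_clock_v1", clock = clock), path)
  invisible(path)
}

#' @rdname save_clock
#' @export
load_clock <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "methclock_clock_v1"))
    stop("not a methclock clock archive")
  obj$clock
}
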