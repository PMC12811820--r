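# Design-grid enumeration and evaluation: every combination of backend,
# age transform, site-selection route, training subset and CR weighting is
# trained and scored by leave-one-out cross-validation (out-of-bag for
# random forests), with accuracy metrics summarised over the
# high-confidence (CR 4-5) samples only.

#' Row indices of a confidence-rating subset
#'
#' @param records age records.
#' @param subset `"All"`, `"CR3+"` or `"CR4+"`.
#' @return integer indices into `records`.
#' @export
cr_subset <- function(records, subset) {
  switch(subset,
         "All" = seq_len(nrow(records)),
         "CR3+" = which(records$cr >= 3),
         "CR4+" = which(records$cr >= 4),
         stop("unknown sample subset: ", subset))
}

#' Enumerate the clock design grid
#'
#' Cartesian product of method x transform x (no selection + selection
#' method x selection samples) x training subset x weighting, in a stable
#' order, minus combinations rejected by `exclude`.
#'
#' @param methods,transforms,selection_methods,selection_samples,
#'   training_samples,weighted allowed values per axis.
#' @param tuning shared [clock_tuning()] for every config.
#' @param exclude optional predicate `function(config) TRUE` to drop a
#'   combination.
#' @return list of `clock_config` objects.
#' @export
enumerate_configs <- function(methods = .METHODS,
                              transforms = .TRANSFORMS,
                              selection_methods = c("ENR", "RFR"),
                              selection_samples = .SUBSETS,
                              training_samples = .SUBSETS,
                              weighted = c(FALSE, TRUE),
                              tuning = clock_tuning("desk"),
                              exclude = NULL) {
  axes <- list(methods, transforms, selection_methods, selection_samples,
               training_samples, weighted)
  if (any(vapply(axes, length, 1L) == 0))
    stop("every grid axis needs at least one value")
  site_opts <- rbind(
    data.frame(sel = "all", sel_samples = "All"),  # selection samples moot
    expand.grid(sel = selection_methods, sel_samples = selection_samples,
                stringsAsFactors = FALSE))
  grid <- expand.grid(method = methods, transform = transforms,
                      site_opt = seq_len(nrow(site_opts)),
                      train = training_samples, wt = weighted,
                      stringsAsFactors = FALSE)
  configs <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    clock_config(method = g$method, age_transform = g$transform,
                 site_selection = site_opts$sel[g$site_opt],
                 site_selection_samples = site_opts$sel_samples[g$site_opt],
                 training_samples = g$train, weighted = g$wt,
                 tuning = tuning)
  })
  if (!is.null(exclude))
    configs <- Filter(function(cfg) !isTRUE(exclude(cfg)), configs)
  configs
}

# Accuracy metrics over a set of predictions. MAE is the *median* absolute
# error (median deviance); residual = predicted - age_best; bins are by
# age_best: [0, 10), [10, 25), [25, Inf).
compute_metrics <- function(pred, records) {
  stopifnot(length(pred) == nrow(records))
  resid <- pred - records$age_best
  dev <- abs(resid)
  bin <- cut(records$age_best, c(-Inf, 10, 25, Inf),
             labels = c("0-9", "10-24", "25+"), right = FALSE)
  per_bin <- function(f, v) vapply(levels(bin), function(b) {
    i <- bin == b
    if (any(i)) f(v[i]) else NA_real_
  }, numeric(1))
  list(pred = pred, residual = resid, deviance = dev,
       mae = median(dev),
       mae_bin = per_bin(median, dev),
       mean_resid_bin = per_bin(mean, resid),
       corr = if (nrow(records) >= 3 && sd(pred) > 0)
         cor(records$age_best, pred) else NA_real_,
       n = nrow(records))
}

#' Leave-one-out evaluation of a clock configuration
#'
#' Hyperparameters are tuned once on the full training subset and held
#' fixed across folds; each training-subset sample is then predicted by a
#' model refit without it. Samples outside the training subset (e.g. CR2
#' when training on CR4+) are predicted by the full-subset fit and reported
#' separately. Accuracy metrics are computed only over CR4+ samples.
#'
#' @param config a [clock_config()] with method other than RFR.
#' @param X methylation matrix (samples x sites, already restricted to the
#'   clock's site set), rownames = sample ids.
#' @param records age records aligned to `rownames(X)`.
#' @param seed integer seed.
#' @param refit_hook optional `function()` called once per LOO refit
#'   (instrumentation).
#' @return an `evaluation` with metrics over CR4+ samples, the per-sample
#'   LOO predictions, and out-of-subset predictions.
#' @export
evaluate_loo <- function(config, X, records, seed = 1L, refit_hook = NULL) {
  stopifnot(config$method != "RFR")
  records <- records[match(rownames(X), records$sample_id), ]
  tr <- cr_subset(records, config$training_samples)
  if (length(tr) < 3) stop("fewer than 3 training samples")
  w <- if (config$weighted) records$cr[tr] else NULL
  Xtr <- X[tr, , drop = FALSE]
  ytr <- records$age_best[tr]
  yfit <- if (config$age_transform == "log") log(ytr) else ytr
  hyper <- tune_clock(config, Xtr, yfit,
                      if (config$method == "SVM") NULL else w, seed = seed)

  loo <- rep(NA_real_, length(tr))
  for (k in seq_along(tr)) {
    if (!is.null(refit_hook)) refit_hook()
    fit <- train_clock(config, Xtr[-k, , drop = FALSE], ytr[-k],
                       weights = w[-k], hyper = hyper,
                       seed = derive_seed(seed, 100L + k))
    loo[k] <- predict(fit, Xtr[k, , drop = FALSE])
  }
  full <- train_clock(config, Xtr, ytr, weights = w, hyper = hyper,
                      seed = derive_seed(seed, 99L))
  out <- setdiff(seq_len(nrow(X)), tr)
  out_pred <- if (length(out))
    setNames(predict(full, X[out, , drop = FALSE]),
             records$sample_id[out]) else numeric(0)

  cr4 <- which(records$cr[tr] >= 4)
  metrics <- compute_metrics(loo[cr4], records[tr[cr4], , drop = FALSE])
  structure(c(metrics,
              list(config = config, hyper = hyper, clock = full,
                   loo_pred = setNames(loo, records$sample_id[tr]),
                   out_of_subset_pred = out_pred,
                   eval_samples = records$sample_id[tr[cr4]])),
            class = "evaluation")
}

#' Out-of-bag evaluation of a random-forest clock configuration
#'
#' A single forest is fit on the training subset; each sample's prediction
#' comes from the trees in which it was out-of-bag. Metric definitions are
#' identical to [evaluate_loo()].
#'
#' @inheritParams evaluate_loo
#' @return an `evaluation`.
#' @export
evaluate_oob <- function(config, X, records, seed = 1L) {
  stopifnot(config$method == "RFR")
  records <- records[match(rownames(X), records$sample_id), ]
  tr <- cr_subset(records, config$training_samples)
  if (length(tr) < 3) stop("fewer than 3 training samples")
  w <- if (config$weighted) records$cr[tr] else NULL
  Xtr <- X[tr, , drop = FALSE]
  ytr <- records$age_best[tr]
  yfit <- if (config$age_transform == "log") log(ytr) else ytr
  hyper <- tune_clock(config, Xtr, yfit, w, seed = seed)
  clock <- train_clock(config, Xtr, ytr, weights = w, hyper = hyper,
                       seed = derive_seed(seed, 99L))
  oob <- oob_predictions(clock)
  out <- setdiff(seq_len(nrow(X)), tr)
  out_pred <- if (length(out))
    setNames(predict(clock, X[out, , drop = FALSE]),
             records$sample_id[out]) else numeric(0)
  cr4 <- which(records$cr[tr] >= 4)
  metrics <- compute_metrics(oob[cr4], records[tr[cr4], , drop = FALSE])
  structure(c(metrics,
              list(config = config, hyper = hyper, clock = clock,
                   loo_pred = setNames(oob, records$sample_id[tr]),
                   out_of_subset_pred = out_pred,
                   eval_samples = records$sample_id[tr[cr4]])),
            class = "evaluation")
}

#' Evaluate one configuration end to end
#'
#' Runs the configured site-selection stage on its sample subset, restricts
#' the matrix to the selected sites, and dispatches to [evaluate_loo()] or
#' [evaluate_oob()].
#'
#' @param config a [clock_config()].
#' @param X full methylation matrix (samples x all sites).
#' @param records age records for the rows of `X`.
#' @param seed integer seed.
#' @return an `evaluation`, with the selection result attached.
#' @export
evaluate_config <- function(config, X, records, seed = 1L) {
  records <- records[match(rownames(X), records$sample_id), ]
  t <- config$tuning
  sel <- NULL
  sites <- colnames(X)
  if (config$site_selection != "all") {
    ss <- cr_subset(records, config$site_selection_samples)
    Xs <- X[ss, , drop = FALSE]
    ys <- records$age_best[ss]
    if (config$age_transform == "log") ys <- log(ys)
    ws <- if (config$weighted) records$cr[ss] else NULL
    sel <- if (config$site_selection == "ENR")
      select_sites_enr(Xs, ys, ws, n_reps = t$select_reps,
                       freq_threshold = t$select_freq,
                       seed = derive_seed(seed, 7L))
    else
      select_sites_rfr(Xs, ys, ws, n_perm = t$select_nperm,
                       p_threshold = t$select_p,
                       ntree = min(t$rfr_ntree, 500),
                       seed = derive_seed(seed, 8L))
    sites <- sel$selected
    if (length(sites) < 2)
      stop("site selection kept fewer than 2 sites for config ",
           config_label(config))
  }
  Xr <- X[, sites, drop = FALSE]
  ev <- if (config$method == "RFR")
    evaluate_oob(config, Xr, records, seed = seed)
  else evaluate_loo(config, Xr, records, seed = seed)
  ev$selection <- sel
  ev
}

#' Rank evaluated models
#'
#' Ascending by overall MAE on CR4+ samples, ties broken by correlation
#' (descending) then input order, mirroring the results-table convention.
#'
#' @param evals list of `evaluation` objects.
#' @return a data.frame, one row per model, best first, with a `rank`
#'   column and the defining design choices.
#' @export
rank_models <- function(evals) {
  stopifnot(length(evals) >= 1)
  df <- do.call(rbind, lapply(evals, function(e) {
    cfg <- e$config
    data.frame(method = cfg$method, training_samples = cfg$training_samples,
               weighted = cfg$weighted, age_transform = cfg$age_transform,
               site_selection = cfg$site_selection,
               site_selection_samples = cfg$site_selection_samples,
               n_sites = length(e$clock$sites),
               corr = e$corr, mae = e$mae,
               mae_0_9 = e$mae_bin[["0-9"]],
               mae_10_24 = e$mae_bin[["10-24"]],
               mae_25plus = e$mae_bin[["25+"]],
               resid_0_9 = e$mean_resid_bin[["0-9"]],
               resid_10_24 = e$mean_resid_bin[["10-24"]],
               resid_25plus = e$mean_resid_bin[["25+"]],
               stringsAsFactors = FALSE)
  }))
  ord <- order(df$mae, -df$corr, seq_len(nrow(df)))
  df <- df[ord, , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df[, c("rank", setdiff(names(df), "rank"))]
}

#' Search a list of configurations
#'
#' @param configs list of [clock_config()] objects (e.g. from
#'   [enumerate_configs()]).
#' @param X full methylation matrix.
#' @param records age records.
#' @param seed master seed; each config gets a derived seed.
#' @param verbose print progress.
#' @return list with the ranked table (`table`) and all `evaluations`.
#' @export
search_models <- function(configs, X, records, seed = 1L, verbose = FALSE) {
  evals <- vector("list", length(configs))
  for (i in seq_along(configs)) {
    if (verbose)
      message(sprintf("[%d/%d] %s", i, length(configs),
                      config_label(configs[[i]])))
    evals[[i]] <- evaluate_config(configs[[i]], X, records,
                                  seed = derive_seed(seed, i))
  }
  list(table = rank_models(evals), evaluations = evals)
}
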