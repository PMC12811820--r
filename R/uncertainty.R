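# Resampling engine: propagate catalogue-age and binomial methylation
# uncertainty through repeated model refits into per-sample predicted-age
# distributions, 95% highest-density intervals, coverage and
# longitudinal-pair ordinality.

#' Highest density interval of a set of draws
#'
#' The shortest contiguous interval containing `ceiling(mass * n)` of the
#' sorted draws, found by sliding-window minimisation; ties go to the
#' left-most (lowest) window.
#'
#' @param draws numeric vector of at least 2 finite draws.
#' @param mass interval mass (default 0.95).
#' @return numeric `c(lower, upper)`.
#' @export
hdi <- function(draws, mass = 0.95) {
  draws <- draws[is.finite(draws)]
  n <- length(draws)
  stopifnot(n >= 2, mass > 0, mass <= 1)
  s <- sort(draws)
  m <- ceiling(mass * n)
  if (m >= n) return(c(lower = s[1], upper = s[n]))
  widths <- s[(m):n] - s[seq_len(n - m + 1)]
  i <- which.min(widths)  # which.min takes the first (lowest) on ties
  c(lower = s[i], upper = s[i + m - 1])
}

#' Draw one resampling replicate of ages and methylation
#'
#' Ages: one draw per sample from its confidence-weighted skew-normal
#' prior. Methylation: for every retained cell, a binomial redraw
#' `n* ~ Binom(K_m, n_m / K_m)`; the redrawn proportion is pushed through
#' the conversion-efficiency correction (with the sample's fixed P_v) and
#' the logit exactly as in the point pipeline, including the per-locus
#' half-lowest substitution computed within the replicate.
#'
#' @param mm a `meth_matrix` (from [qc_filter()]), raw counts retained.
#' @param priors named list of `age_prior` objects covering the samples.
#' @return list with `ages` (named vector) and `M` (replicate logit
#'   methylation matrix).
#' @export
resample_replicate <- function(mm, priors) {
  stopifnot(inherits(mm, "meth_matrix"))
  ids <- rownames(mm$M)
  ages <- vapply(ids, function(s) sample_age(priors[[s]], 1), numeric(1))
  K <- mm$K_m
  n <- mm$n_m
  ok <- which(is.finite(K) & K > 0)
  nstar <- n
  nstar[ok] <- rbinom(length(ok), size = K[ok], prob = n[ok] / K[ok])
  P <- nstar / K
  pv <- mm$samples$conversion_efficiency[
    match(ids, mm$samples$sample_id)]
  locus_of <- mm$sites$locus[match(colnames(K), mm$sites$site_id)]
  M <- P
  M[ok] <- logit_methylation(correct_methylation(
    P[ok], pv[(ok - 1) %% nrow(K) + 1], locus_of[(ok - 1) %/% nrow(K) + 1]))
  list(ages = ages, M = M)
}

#' Run the full resampling analysis
#'
#' Trains the point-estimate clock (tuning its hyperparameters once), then
#' for each replicate: draws ages and methylation via
#' [resample_replicate()], refits the clock on the replicate's training
#' subset with the point-estimate hyperparameters, predicts every sample
#' from the replicate methylation, and clamps to the plausible-age bounds.
#' Replicate fit failures are dropped with a warning; more than 5%
#' failures abort the run.
#'
#' @param config a [clock_config()]. Site selection must already be
#'   resolved: `X` is the matrix over the clock's final site set.
#' @param mm a `meth_matrix` restricted (columns) to the clock's sites.
#' @param records age records for the samples.
#' @param priors fitted age priors (default: fitted from `records`).
#' @param n_reps replicates (published scale 1000; tests use 100-200).
#' @param seed master seed; the run is fully reproducible from it.
#' @param hyper optional pre-tuned hyperparameters; tuned here when NULL.
#' @return a `resampling_result`: the draw matrix (samples x replicates),
#'   per-sample `prediction_distribution` summaries, and the point clock.
#' @export
run_resampling <- function(config, mm, records, priors = NULL,
                           n_reps = 1000, seed = 1L, hyper = NULL) {
  stopifnot(n_reps >= 2, inherits(mm, "meth_matrix"))
  records <- records[match(rownames(mm$M), records$sample_id), ]
  if (is.null(priors)) priors <- fit_age_priors(records)
  tr <- cr_subset(records, config$training_samples)
  w <- if (config$weighted) records$cr[tr] else NULL

  ytr <- records$age_best[tr]
  yfit <- if (config$age_transform == "log") log(ytr) else ytr
  Xtr <- mm$M[tr, , drop = FALSE]
  if (is.null(hyper))
    hyper <- tune_clock(config, Xtr, yfit,
                        if (config$method == "SVM") NULL else w, seed = seed)
  point_clock <- train_clock(config, Xtr, ytr, weights = w, hyper = hyper,
                             seed = derive_seed(seed, 1L))

  ids <- rownames(mm$M)
  draws <- matrix(NA_real_, length(ids), n_reps,
                  dimnames = list(ids, NULL))
  failures <- 0L
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  for (r in seq_len(n_reps)) {
    set.seed(derive_seed(seed, 1000L + r))
    rep <- resample_replicate(mm, priors)
    ages_r <- rep$ages[tr]
    if (config$age_transform == "log") ages_r <- pmax(ages_r, 1e-3)
    p <- tryCatch({
      fit <- train_clock(config, rep$M[tr, , drop = FALSE], ages_r,
                         weights = w, hyper = hyper,
                         seed = derive_seed(seed, 2000L + r))
      predict(fit, rep$M)
    }, error = function(e) NULL)
    if (is.null(p)) {
      failures <- failures + 1L
      warning("replicate ", r, " model fit failed; replicate dropped")
    } else draws[, r] <- p
  }
  if (failures > 0.05 * n_reps)
    stop("more than 5% of resampling replicates failed (", failures,
         " of ", n_reps, ")")
  draws <- draws[, colSums(is.na(draws)) == 0, drop = FALSE]

  dists <- lapply(ids, function(s) {
    d <- draws[s, ]
    h <- hdi(d, 0.95)
    ab <- records$age_best[records$sample_id == s]
    structure(list(sample_id = s, draws = d, hdi = h,
                   median = median(d), mode = draw_mode(d),
                   age_best = ab,
                   age_best_in_hdi = ab >= h[1] && ab <= h[2]),
              class = "prediction_distribution")
  })
  names(dists) <- ids
  structure(list(draws = draws, distributions = dists,
                 point_clock = point_clock, config = config,
                 records = records, n_failed = failures),
            class = "resampling_result")
}

# mode of a draw vector via a kernel density estimate
draw_mode <- function(d) {
  if (length(unique(d)) == 1) return(d[1])
  dens <- stats::density(d)
  dens$x[which.max(dens$y)]
}

#' Proportion of samples whose Age_best falls inside its 95% HDI
#'
#' @param result a `resampling_result` (or list of
#'   `prediction_distribution`).
#' @param records optional age records; defaults to those in `result`.
#' @param cr_min restrict to samples with CR at least this (the headline
#'   coverage in the study is over CR4+ samples); default 2 keeps all.
#' @return the coverage proportion.
#' @export
hdi_coverage <- function(result, records = NULL, cr_min = 2) {
  dists <- if (inherits(result, "resampling_result"))
    result$distributions else result
  if (is.null(records) && inherits(result, "resampling_result"))
    records <- result$records
  ids <- vapply(dists, function(d) d$sample_id, character(1))
  keep <- ids %in% records$sample_id[records$cr >= cr_min]
  flags <- vapply(dists[keep], function(d) d$age_best_in_hdi, logical(1))
  mean(flags)
}

#' Longitudinal pair ordinality from resampling draws
#'
#' For each pair of samples from the same individual, computes the
#' per-replicate difference (later-collected minus earlier-collected
#' predicted age) and the proportion of replicates in which it is
#' positive. Zero differences count as incorrect (conservative tie rule).
#'
#' @param result a `resampling_result`.
#' @param records optional age records with `individual_id` and
#'   `collection_date`; defaults to those in `result`.
#' @return a data.frame with one row per pair: ids, true age gap in years
#'   (from collection dates), proportion of replicates correctly ordered
#'   and the `correct` flag (proportion > 0.5).
#' @export
pair_ordinality <- function(result, records = NULL) {
  stopifnot(inherits(result, "resampling_result"))
  if (is.null(records)) records <- result$records
  records <- records[records$sample_id %in% rownames(result$draws), ]
  pairs <- split(records, records$individual_id)
  pairs <- Filter(function(p) nrow(p) == 2 &&
                    length(unique(p$collection_date)) == 2, pairs)
  if (!length(pairs))
    return(data.frame(individual_id = character(0),
                      earlier = character(0), later = character(0),
                      true_gap = numeric(0), prop_correct = numeric(0),
                      correct = logical(0)))
  do.call(rbind, lapply(pairs, function(p) {
    p <- p[order(p$collection_date), ]
    d_late <- result$draws[p$sample_id[2], ]
    d_early <- result$draws[p$sample_id[1], ]
    diff <- d_late - d_early
    prop <- mean(diff > 0)
    data.frame(individual_id = p$individual_id[1],
               earlier = p$sample_id[1], later = p$sample_id[2],
               true_gap = as.numeric(p$collection_date[2] -
                                       p$collection_date[1]) / 365.25,
               prop_correct = prop, correct = prop > 0.5,
               row.names = NULL)
  }))
}

#' @export
print.resampling_result <- function(x, ...) {
  cat("resampling_result:", nrow(x$draws), "samples x", ncol(x$draws),
      "replicates (", x$n_failed, "failed )\n")
  cat(sprintf("  Age_best in 95%% HDI: %.2f of samples\n", hdi_coverage(x)))
  invisible(x)
}

#' Plot a per-sample predicted-age distribution
#'
#' Histogram of the replicate predicted-age draws with the 95% HDI bounds
#' as solid lines, Age_best as a dashed line, and (optionally) the
#' sample's catalogue age-prior density overlaid.
#'
#' @param x a `prediction_distribution`.
#' @param prior optional `age_prior` for the same sample.
#' @param ... passed to [graphics::hist()].
#' @export
plot.prediction_distribution <- function(x, prior = NULL, ...) {
  h <- graphics::hist(x$draws, breaks = 30, plot = FALSE)
  graphics::plot(h, freq = FALSE, main = x$sample_id,
                 xlab = "predicted age (years)",
                 col = "grey80", border = "grey60", ...)
  graphics::abline(v = x$hdi, lwd = 2)
  graphics::abline(v = x$age_best, lty = 2, col = "grey40")
  if (!is.null(prior)) {
    ages <- seq(max(0, min(x$draws) - 5), max(x$draws) + 5, length.out = 200)
    graphics::lines(ages, age_density(ages, prior), col = "grey40")
  }
  invisible(x)
}

#' Write per-sample resampling summaries (and optionally draws) as TSV
#'
#' @param result a `resampling_result`.
#' @param dir output directory.
#' @param draws also write the full draw matrix.
#' @export
write_resampling <- function(result, dir, draws = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sm <- do.call(rbind, lapply(result$distributions, function(d)
    data.frame(sample_id = d$sample_id, median = d$median, mode = d$mode,
               hdi_lower = d$hdi[1], hdi_upper = d$hdi[2],
               age_best = d$age_best,
               age_best_in_hdi = d$age_best_in_hdi)))
  p1 <- file.path(dir, "prediction_summaries.tsv")
  write.table(sm, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- p1
  po <- pair_ordinality(result)
  if (nrow(po)) {
    p2 <- file.path(dir, "pair_ordinality.tsv")
    write.table(po, p2, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p2)
  }
  if (draws) {
    p3 <- file.path(dir, "prediction_draws.tsv")
    write.table(data.frame(sample_id = rownames(result$draws),
                           result$draws, check.names = FALSE),
                p3, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p3)
  }
  invisible(paths)
}
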