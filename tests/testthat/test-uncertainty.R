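# HDI computation, replicate resampling of ages and methylation, coverage
# and longitudinal-pair ordinality.

test_that("HDI handles constants, outliers and uniform draws", {
  expect_equal(unname(hdi(rep(3.2, 10))), c(3.2, 3.2))
  # nine 1s and one 100 at mass 0.9: the window of 9 sorted draws is (1, 1)
  expect_equal(unname(hdi(c(rep(1, 9), 100), mass = 0.9)), c(1, 1))
  set.seed(1)
  h <- hdi(runif(10000))
  expect_lt(abs((h[2] - h[1]) - 0.95), 0.02)
  expect_error(hdi(1), "n >= 2")
})

test_that("sliding-window HDI equals the exhaustive-window oracle", {
  set.seed(2)
  for (i in 1:25) {
    n <- sample(5:200, 1)
    draws <- switch(1 + i %% 3,
                    rnorm(n), rexp(n), c(rnorm(n %/% 2), rnorm(n - n %/% 2, 8)))
    mass <- sample(c(0.5, 0.8, 0.95), 1)
    expect_equal(unname(hdi(draws, mass)), hdi_oracle(draws, mass))
  }
})

test_that("binomial redraws reproduce the point estimates in expectation", {
  x <- small_cohort()
  mm <- x$mm
  priors <- fit_age_priors(x$records)
  set.seed(3)
  rep1 <- resample_replicate(mm, priors)
  expect_equal(dim(rep1$M), dim(mm$M))
  expect_true(all(is.finite(rep1$M)))
  expect_length(rep1$ages, nrow(mm$M))
  # high-coverage law of large numbers: replicate close to point value
  K <- mm$K_m; P <- mm$P_m
  reps <- replicate(40, {
    r <- resample_replicate(mm, priors)
    r$M[1, 1]
  })
  p <- P[1, 1]
  se_logit <- sqrt(p * (1 - p) / K[1, 1]) / (p * (1 - p))  # delta method
  expect_lt(abs(mean(reps) - mm$M[1, 1]), 4 * se_logit / sqrt(40) + 0.01)
  # binomial mean oracle on a constructed cell
  set.seed(4)
  draws <- rbinom(2000, 1000, 300 / 1000) / 1000
  expect_lt(abs(mean(draws) - 0.3), 3 * sqrt(0.3 * 0.7 / 1000 / 2000) + 1e-3)
})

test_that("a zero-count cell stays at the deterministic floor", {
  tab <- rbind(
    count_row("a", "L1", 1, "CpG", C = 0, T = 1000),    # fully unmethylated
    count_row("a", "L1", 2, "CpG", C = 500, T = 500),
    count_row("b", "L1", 1, "CpG", C = 0, T = 1000),
    count_row("b", "L1", 2, "CpG", C = 480, T = 520),
    control_rows(c("a", "b"), pv = 1.0))
  mm <- qc_filter(tab, 0, 0, 0)$matrix
  priors <- fit_age_priors(toy_records(c("a", "b"), c(10, 20)))
  # n_m = 0 cells redraw to 0 every time, so they always land exactly on
  # the within-replicate half-lowest floor of their locus
  for (s in 5:7) {
    set.seed(s)
    r <- resample_replicate(mm, priors)
    floor_val <- min(inv_logit(r$M[, "L1_2"])) / 2
    expect_equal(unname(inv_logit(r$M[, "L1_1"])), rep(floor_val, 2))
  }
})

test_that("resampling is reproducible and honours degenerate inputs", {
  x <- small_cohort()
  cfg <- clock_config("SVM", tuning = clock_tuning("desk"))
  run1 <- run_resampling(cfg, x$mm, x$records, n_reps = 10, seed = 17)
  run2 <- run_resampling(cfg, x$mm, x$records, n_reps = 10, seed = 17)
  expect_identical(run1$draws, run2$draws)
  expect_true(all(run1$draws >= 0 & run1$draws <= 80))
  d <- run1$distributions[[1]]
  expect_lte(d$hdi[1], d$hdi[2])
  expect_error(run_resampling(cfg, x$mm, x$records, n_reps = 1, seed = 1))
})

test_that("point-mass priors and huge coverage collapse the HDIs", {
  # build a tiny cohort with enormous depth and near-point age priors
  spec <- synth_spec(n_individuals = 20, n_pairs = 0, cpg_per_locus = 4,
                     n_clock_sites = 8, noncpg_per_locus = 4,
                     depth_range = c(2e5, 2e5 + 1), seed = 21)
  co <- generate_cohort(spec)
  rec <- co$records
  # shrink every prior to a sliver around age_best
  rec$age_min <- pmax(0, rec$age_best - 0.02)
  rec$age_max <- rec$age_best + 0.02
  rec$cr <- 5
  cfg <- clock_config("SVM", tuning = clock_tuning("desk"))
  mm <- qc_filter(co$counts)$matrix
  # well-conditioned hyperparameters: coarse-grid tuning can land on an
  # ill-conditioned corner whose fit amplifies numerically tiny jitter
  run <- run_resampling(cfg, mm, rec, n_reps = 25, seed = 2,
                        hyper = list(cost = 10, gamma = 1 / ncol(mm$M)))
  widths <- vapply(run$distributions,
                   function(d) d$hdi[2] - d$hdi[1], numeric(1))
  expect_lt(median(widths), 1)
})

test_that("coverage counts exactly the samples whose HDI holds age_best", {
  mk_dist <- function(id, lo, hi, best) {
    structure(list(sample_id = id, draws = c(lo, hi), hdi = c(lo, hi),
                   median = (lo + hi) / 2, mode = (lo + hi) / 2,
                   age_best = best,
                   age_best_in_hdi = best >= lo && best <= hi),
              class = "prediction_distribution")
  }
  ids <- sprintf("p%02d", 1:10)
  covered <- c(rep(TRUE, 7), rep(FALSE, 3))
  dists <- lapply(seq_along(ids), function(i)
    mk_dist(ids[i], 10, 20, if (covered[i]) 15 else 40))
  rec <- toy_records(ids, rep(15, 10), cr = rep(4, 10))
  expect_equal(hdi_coverage(dists, rec), 0.7)
  all80 <- lapply(ids, function(i) mk_dist(i, 0, 80, 15))
  expect_equal(hdi_coverage(all80, rec), 1.0)
  none <- lapply(ids, function(i) mk_dist(i, 50, 60, 15))
  expect_equal(hdi_coverage(none, rec), 0.0)
})

test_that("pair ordinality applies the conservative tie rule", {
  ids <- c("e1", "l1", "e2", "l2")
  rec <- data.frame(sample_id = ids,
                    individual_id = c("A", "A", "B", "B"),
                    collection_date = as.Date(c("2010-01-01", "2015-01-01",
                                                "2010-06-01", "2012-06-01")),
                    age_best = c(10, 15, 20, 22),
                    age_min = c(5, 10, 15, 17), age_max = c(15, 20, 25, 27),
                    cr = 4)
  draws <- rbind(e1 = rnorm(100, 10), l1 = 0,
                 e2 = rnorm(100, 20), l2 = 0)
  draws["l1", ] <- draws["e1", ] + 5     # always correctly ordered
  draws["l2", ] <- draws["e2", ]         # all ties -> all incorrect
  res <- structure(list(draws = draws, records = rec),
                   class = "resampling_result")
  po <- pair_ordinality(res)
  po <- po[order(po$individual_id), ]
  expect_equal(po$prop_correct, c(1, 0))
  expect_equal(po$correct, c(TRUE, FALSE))
  expect_equal(po$true_gap, c(5, 2), tolerance = 0.01)
})

test_that("wider priors never shrink the median HDI width", {
  x <- small_cohort()
  cfg <- clock_config("SVM", tuning = clock_tuning("desk"))
  med_width <- function(rec, seed) {
    run <- run_resampling(cfg, x$mm, rec, n_reps = 15, seed = seed)
    median(vapply(run$distributions, function(d) d$hdi[2] - d$hdi[1],
                  numeric(1)))
  }
  rec_wide <- x$records
  rec_wide$age_min <- pmax(0, rec_wide$age_min - 6)
  rec_wide$age_max <- rec_wide$age_max + 6
  wins <- 0
  for (s in 1:3)
    wins <- wins + (med_width(rec_wide, s) >= med_width(x$records, s) - 0.2)
  expect_gte(wins, 2)
})
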