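# The shared training/prediction contract over the four backends: tuning,
# transforms, clamping, serialisation, and backend-specific behaviour.

desk <- clock_tuning("desk")

test_that("predictions are clamped to the plausible-age interval", {
  # a stub backend that returns whatever we like
  stub <- structure(list(out = c(-3, 95, 20)), class = "stub_fit")
  registerS3method("predict", "stub_fit",
                   function(object, newdata, ...) object$out)
  clock <- structure(list(config = clock_config("ENR", tuning = desk),
                          fit = stub, sites = "s1", transform = "none",
                          clamp = c(0, 80)), class = "trained_clock")
  X <- matrix(0, 3, 1, dimnames = list(NULL, "s1"))
  expect_equal(unname(predict(clock, X)), c(0, 80, 20))
  # missing site columns are an error naming them
  expect_error(predict(clock, matrix(0, 1, 1, dimnames = list(NULL, "zz"))),
               "s1")
})

test_that("noise-free linear signal is recovered by the elastic net", {
  set.seed(4)
  n <- 30
  M1 <- runif(n, -3, 3)
  X <- cbind(site1 = M1, site2 = rnorm(n))
  rownames(X) <- sprintf("s%02d", 1:n)
  y <- 2 * M1 + 15   # keep the noise-free responses inside the clamp range
  cfg <- clock_config("ENR", tuning = clock_tuning("desk", enr_alpha = 0.1))
  rec <- toy_records(rownames(X), y)
  ev <- evaluate_loo(cfg, X, rec, seed = 1)
  # cross-validation on a noise-free system has a flat objective, so the
  # selected penalty jitters; the bulk of predictions recover y almost
  # exactly and no point drifts far
  expect_lt(median(abs(ev$loo_pred - y)), 0.1)
  expect_lt(max(abs(ev$loo_pred - y)), 0.5)
})

test_that("the log transform round-trips on a log-linear system", {
  set.seed(5)
  n <- 30
  x <- runif(n, -2, 2)
  y <- exp(1 + 0.8 * x)           # ln y linear in x, noise-free
  X <- cbind(site1 = x, site2 = rnorm(n))
  cfg <- clock_config("ENR", age_transform = "log",
                      tuning = clock_tuning("desk", enr_alpha = 0.1))
  clock <- train_clock(cfg, X, y, hyper = list(alpha = 0.1), seed = 2)
  p <- predict(clock, X)
  expect_equal(p, y, tolerance = 0.05)
})

test_that("alpha tuning is deterministic and honours a collapsed range", {
  tr <- toy_regression(n = 30, p = 8, k = 2, noise = 1)
  a1 <- tune_enr_alpha(tr$X, tr$y, n_reps = 5, seed = 9)
  a2 <- tune_enr_alpha(tr$X, tr$y, n_reps = 5, seed = 9)
  expect_identical(a1, a2)
  expect_identical(tune_enr_alpha(tr$X, tr$y, alpha_range = c(0.3, 0.3),
                                  n_reps = 2, seed = 1), 0.3)
  expect_error(tune_enr_alpha(tr$X[1:5, ], tr$y[1:5], n_reps = 1),
               "fewer samples")
})

test_that("elastic-net sparsity is monotone in the penalty", {
  tr <- toy_regression(n = 40, p = 15, k = 3, noise = 2)
  fit <- glmnet::glmnet(tr$X, tr$y, alpha = 0.5)
  nz <- colSums(as.matrix(fit$beta) != 0)  # lambda path is decreasing
  # sparsity grows with the penalty (monotone up to single-step jitter
  # where a variable swaps in and out along the path)
  expect_lte(nz[1], nz[length(nz)])
  expect_lt(cor(log(fit$lambda), nz, method = "spearman"), -0.9)
  # near-ridge keeps everything nonzero at a mild penalty
  fit0 <- glmnet::glmnet(tr$X, tr$y, alpha = 1e-4,
                         lambda = min(fit$lambda))
  expect_equal(sum(as.matrix(fit0$beta) != 0), 15)
})

test_that("random forest reproduces constants and respects its seed", {
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, paste0("s", 1:3)))
  f <- rf_fit(X, rep(7, 20), ntree = 50, seed = 1)
  expect_equal(unname(predict(f, X)), rep(7, 20))
  expect_equal(f$oob_pred, rep(7, 20))
  y <- rnorm(20)
  f1 <- rf_fit(X, y, ntree = 50, seed = 5)
  f2 <- rf_fit(X, y, ntree = 50, seed = 5)
  expect_identical(predict(f1, X), predict(f2, X))
})

test_that("forest OOB error at the tuned grid point beats the grid median", {
  tr <- toy_regression(n = 40, p = 6, k = 2, noise = 2, seed = 3)
  tu <- rf_tune(tr$X, tr$y, ntree = 100, grid_n = 3, seed = 2)
  sm <- tu$smoothed
  expect_lte(sm[as.character(tu$sampsize), as.character(tu$mtry)],
             median(sm))
  f <- rf_fit(tr$X, tr$y, ntree = 100, mtry = tu$mtry,
              sampsize = tu$sampsize, seed = 3)
  expect_lte(f$oob_mse, median(tu$mse) * 1.5)
})

test_that("SVR fits a smooth signal and tuning picks sane parameters", {
  set.seed(8)
  n <- 50
  x <- seq(-2, 2, length.out = n)
  y <- sin(x) * 3 + 10
  X <- cbind(site1 = x, site2 = rnorm(n, 0, 0.1))
  fit <- svr_fit(X, y, cost = 10, gamma = 0.5)
  expect_lt(median(abs(predict(fit, X) - y)), 0.4)
  tu <- svr_tune(X, y, cost_range = c(-1, 3), gamma_range = c(-2, 1),
                 step = 1, nfolds = 5, seed = 1)
  expect_true(tu$cost >= 0.1 && tu$cost <= 1000)
  fit2 <- svr_fit(X, y, cost = tu$cost, gamma = tu$gamma)
  expect_lt(median(abs(predict(fit2, X) - y)), 0.5)
  # determinism: same seed, same grid choice
  tu2 <- svr_tune(X, y, cost_range = c(-1, 3), gamma_range = c(-2, 1),
                  step = 1, nfolds = 5, seed = 1)
  expect_identical(tu$cost, tu2$cost)
  expect_identical(tu$gamma, tu2$gamma)
})

test_that("GAM captures curvature that defeats a linear backend", {
  set.seed(11)
  n <- 45
  x <- runif(n, -2, 2)
  y <- 20 + 6 * x^2 + rnorm(n, 0, 0.2)  # pure quadratic
  X <- cbind(site1 = x, site2 = rnorm(n, 0, 0.3))
  rec <- toy_records(sprintf("s%02d", 1:n), y)
  rownames(X) <- rec$sample_id
  gam_cfg <- clock_config("GAM", tuning = desk)
  enr_cfg <- clock_config("ENR", tuning = clock_tuning("desk", enr_alpha = 0.1))
  ev_gam <- evaluate_loo(gam_cfg, X, rec, seed = 1)
  ev_enr <- evaluate_loo(enr_cfg, X, rec, seed = 1)
  expect_lt(ev_gam$mae * 4, ev_enr$mae)
})

test_that("GAM records the basis dimension it converged at", {
  set.seed(12)
  x <- runif(40, -2, 2)
  X <- cbind(site1 = x)
  y <- x^2
  fit <- gam_fit(X, y, k = 3)
  expect_gte(fit$k, 3)
  expect_s3_class(fit, "gam_model")
  expect_lt(median(abs(predict(fit, X) - y)), 0.3)
})

test_that("weighted fits accept CR weights where the backend supports them", {
  tr <- toy_regression(n = 30, p = 5, k = 2, noise = 1)
  w <- rep(c(2, 5), length.out = 30)
  for (m in c("ENR", "RFR", "GAM")) {
    cfg <- clock_config(m, weighted = TRUE,
                        tuning = clock_tuning("desk", enr_alpha = 0.2,
                                              rfr_ntree = 50))
    hy <- switch(m, ENR = list(alpha = 0.2),
                 RFR = list(sampsize = 20, mtry = 2), GAM = list(k = 3))
    clock <- train_clock(cfg, tr$X[, 1:3], tr$y, weights = w, hyper = hy,
                         seed = 1)
    expect_s3_class(clock, "trained_clock")
    expect_true(all(predict(clock, tr$X[, 1:3]) >= 0))
  }
})

test_that("a saved clock reloads and predicts identically", {
  tr <- toy_regression(n = 25, p = 4, k = 2, noise = 0.5)
  cfg <- clock_config("SVM", tuning = desk)
  clock <- train_clock(cfg, tr$X, tr$y, hyper = list(cost = 10, gamma = 0.3),
                       seed = 1)
  path <- withr::local_tempfile(fileext = ".rds")
  save_clock(clock, path)
  back <- load_clock(path)
  expect_identical(predict(back, tr$X), predict(clock, tr$X))
  expect_error(suppressWarnings(
    load_clock(withr::local_tempfile(fileext = ".rds"))))
})
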