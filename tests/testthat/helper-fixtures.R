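# Fixture builders shared across test files. Everything is generated in
# code; no data files.

# One count-table row.
count_row <- function(sample, locus, pos, class, A = 0, C = 0, G = 0, T = 0) {
  data.frame(sample_id = sample, locus = locus, position = pos,
             site_class = class, n_A = A, n_C = C, n_G = G, n_T = T,
             stringsAsFactors = FALSE)
}

# Control (non-CpG cytosine) rows giving every sample the same conversion
# efficiency pv at depth K.
control_rows <- function(samples, pv = 0.99, K = 1000, locus = "L1",
                         pos = 900) {
  do.call(rbind, lapply(samples, function(s)
    count_row(s, locus, pos, "nonCpG_C",
              C = round(K * (1 - pv)), T = K - round(K * (1 - pv)))))
}

# The 10-sample x 5-site QC fixture: sample s01 has median CpG depth 900
# (stage 1), site c3 has median depth 500 among the remaining samples
# (stage 2), and sample s02 has 80 reads at site c1 (stage 3).
qc_fixture <- function() {
  samples <- sprintf("s%02d", 1:10)
  depth <- matrix(2000, 10, 5, dimnames = list(samples, NULL))
  depth["s01", ] <- 900
  depth[samples != "s01", 3] <- 500
  depth["s02", 1] <- 80
  rows <- list()
  for (i in 1:10) for (j in 1:5) {
    K <- depth[i, j]
    rows[[length(rows) + 1]] <-
      count_row(samples[i], "L1", j, "CpG",
                C = round(K * 0.6), T = K - round(K * 0.6))
  }
  rbind(do.call(rbind, rows), control_rows(samples))
}

# A small, clean regression problem: n samples, p sites, k of them exactly
# linear in age, the rest pure noise. Returns list(X, y).
toy_regression <- function(n = 40, p = 10, k = 2, noise = 0, seed = 1) {
  set.seed(seed)
  age <- runif(n, 3, 40)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("s%02d", seq_len(n)),
                              sprintf("site%02d", seq_len(p))))
  for (j in seq_len(k)) X[, j] <- 0.1 * j * age + rnorm(n, 0, 0.05)
  y <- age + rnorm(n, 0, noise)
  list(X = X, y = y, age = age)
}

# Age records for a methylation matrix / vector of sample ids.
toy_records <- function(ids, ages, cr = NULL) {
  n <- length(ids)
  if (is.null(cr)) cr <- rep(4:5, length.out = n)
  data.frame(sample_id = ids, individual_id = paste0("I", seq_len(n)),
             collection_date = as.Date("2015-01-01") + seq_len(n),
             age_best = ages, age_min = pmax(0, ages - 5),
             age_max = ages + 5, cr = cr, stringsAsFactors = FALSE)
}

# A small synthetic cohort quantified end to end (cached per test file run).
small_cohort <- local({
  cache <- NULL
  function(seed = 7) {
    if (!is.null(cache) && cache$seed == seed) return(cache)
    spec <- synth_spec(n_individuals = 40, n_pairs = 6, cpg_per_locus = 6,
                       n_clock_sites = 12, noncpg_per_locus = 8,
                       depth_range = c(1500, 2500), seed = seed)
    co <- generate_cohort(spec)
    mm <- qc_filter(co$counts)$matrix
    cache <<- list(seed = seed, spec = spec, cohort = co, mm = mm,
                   records = co$records)
    cache
  }
})

# Exhaustive-window HDI oracle, independent of the package implementation:
# enumerate every contiguous window of ceiling(mass * n) sorted draws.
hdi_oracle <- function(draws, mass = 0.95) {
  s <- sort(draws)
  n <- length(s)
  m <- ceiling(mass * n)
  if (m >= n) return(c(s[1], s[n]))
  best <- c(Inf, NA, NA)
  for (i in seq_len(n - m + 1)) {
    w <- s[i + m - 1] - s[i]
    if (w < best[1]) best <- c(w, s[i], s[i + m - 1])
  }
  c(best[2], best[3])
}
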