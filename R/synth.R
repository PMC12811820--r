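# Synthetic cohort generator: read-count tables and catalogue-style age
# records with the statistical structure the framework assumes, so every
# stage is testable without any external download. Defaults mirror the
# study system: 76 individuals / 89 samples (13 longitudinal pairs), 8
# amplicons carrying ~184 CpG sites of which 47 respond log-linearly to
# age, read depths 1000-7000, conversion efficiency 0.993-0.997,
# sequencing error rate 0.02%, ages 3-40 years, and CR-structured age
# uncertainty (wider ranges at lower confidence and older age).

#' Specification of a synthetic cohort
#'
#' @param n_individuals unique animals (default 76).
#' @param n_pairs individuals sampled twice (default 13).
#' @param pair_gap_range years between a pair's two samples (default 2-13).
#' @param n_loci amplicons (default 8).
#' @param cpg_per_locus CpG sites per amplicon (default 23, ~184 total).
#' @param noncpg_per_locus non-CpG cytosine control sites per amplicon.
#' @param n_clock_sites CpG sites whose methylation drifts with age
#'   (default 47).
#' @param slope_range absolute per-year logit-scale slope of clock sites.
#' @param intercept_range logit-scale baseline methylation range.
#' @param sd_biological per-sample, per-site biological noise on the logit
#'   scale. The default 0 makes methylation a deterministic logit-linear
#'   function of age plus binomial read sampling -- the generator's stated
#'   data model; positive values add inter-individual variation for
#'   robustness experiments.
#' @param depth_range per-sample mean read depth range.
#' @param conversion_range per-sample bisulfite conversion efficiency range.
#' @param error_rate sequencing error rate (A/G reads at cytosine sites).
#' @param age_range true-age range in years.
#' @param seed master seed.
#' @return a `synth_spec`.
#' @export
synth_spec <- function(n_individuals = 76, n_pairs = 13,
                       pair_gap_range = c(2, 13), n_loci = 8,
                       cpg_per_locus = 23, noncpg_per_locus = 25,
                       n_clock_sites = 47, slope_range = c(0.02, 0.08),
                       intercept_range = c(-2.5, 2.5),
                       sd_biological = 0, depth_range = c(1000, 7000),
                       conversion_range = c(0.993, 0.997),
                       error_rate = 2e-4, age_range = c(3, 40),
                       seed = 1L) {
  spec <- as.list(environment())
  if (n_clock_sites > n_loci * cpg_per_locus)
    stop("more clock sites than total CpG sites")
  if (n_pairs > n_individuals) stop("more pairs than individuals")
  stopifnot(all(depth_range > 0), error_rate >= 0, error_rate < 1,
            all(conversion_range > 0), all(conversion_range <= 1))
  structure(spec, class = "synth_spec")
}

#' Degrade true ages into catalogue-style records
#'
#' Emulates the photo-identification catalogue's uncertainty structure:
#' Age_best is the true age plus CR-dependent noise; the plausible range
#' (Age_min, Age_max) widens as CR decreases and age increases, always
#' contains the true age (the range is defined as 100%-confidence bounds)
#' and always brackets Age_best. Older animals draw lower CRs, as longer
#' sighting histories are needed to age them confidently.
#'
#' @param true_ages numeric vector of true ages (years, >= 0).
#' @param sample_ids,individual_ids,collection_dates metadata vectors
#'   aligned with `true_ages` (defaults generated).
#' @return a validated age-record data.frame with a `true_age` column
#'   appended.
#' @export
degrade_ages <- function(true_ages, sample_ids = NULL,
                         individual_ids = NULL, collection_dates = NULL) {
  n <- length(true_ages)
  stopifnot(all(true_ages >= 0))
  if (is.null(sample_ids)) sample_ids <- sprintf("S%03d", seq_len(n))
  if (is.null(individual_ids)) individual_ids <- sprintf("I%03d", seq_len(n))
  if (is.null(collection_dates))
    collection_dates <- as.Date("2015-01-01") + seq_len(n)

  # CR drawn with age-dependent probabilities over CR 2..5
  cr_prob <- function(age) {
    if (age < 10) c(0.05, 0.20, 0.35, 0.40)
    else if (age < 25) c(0.10, 0.35, 0.35, 0.20)
    else c(0.20, 0.45, 0.33, 0.02)
  }
  cr <- vapply(true_ages, function(a)
    sample(2:5, 1, prob = cr_prob(a)), integer(1))

  noise_sd <- c(`2` = 4, `3` = 2.5, `4` = 1, `5` = 0.5)[as.character(cr)]
  base_width <- c(`2` = 16, `3` = 10, `4` = 5, `5` = 3)[as.character(cr)]

  best <- pmax(0.5, true_ages + rnorm(n, 0, noise_sd))
  width <- base_width + 0.25 * true_ages * (5 - cr) / 3 +
    abs(rnorm(n, 0, 1))
  lo_anchor <- pmin(best, true_ages)
  hi_anchor <- pmax(best, true_ages)
  age_min <- pmax(0, lo_anchor - 0.4 * width)
  age_max <- hi_anchor + 0.6 * width
  # keep the mode strictly inside the range (needed by the prior fit)
  eps <- 0.02 * (age_max - age_min)
  best <- pmin(pmax(best, age_min + eps), age_max - eps)

  data.frame(sample_id = sample_ids, individual_id = individual_ids,
             collection_date = collection_dates, age_best = best,
             age_min = age_min, age_max = age_max, cr = cr,
             true_age = true_ages, stringsAsFactors = FALSE)
}

# vectorised multinomial split of depth n into (A, G, C, T)
.split_reads <- function(n, pC_given_read, error_rate) {
  e <- error_rate
  nA <- rbinom(length(n), n, e / 2)
  nG <- rbinom(length(n), n - nA, (e / 2) / (1 - e / 2))
  rest <- n - nA - nG
  nC <- rbinom(length(n), rest, pC_given_read)
  list(n_A = nA, n_G = nG, n_C = nC, n_T = rest - nC)
}

#' Generate a synthetic cohort
#'
#' True methylation at clock sites follows
#' `p = inv_logit(intercept + slope * true_age + biological noise)`; null
#' sites drop the age term. A read at a CpG site is observed as C if the
#' genome copy is methylated, or with probability `1 - P_v` if
#' unmethylated (a bisulfite conversion failure) -- exactly the error mode
#' the conversion-efficiency correction removes, making its unbiasedness
#' testable. Non-CpG cytosine control sites are unmethylated throughout.
#' Sequencing errors turn reads into A or G at `error_rate`.
#'
#' @param spec a [synth_spec()].
#' @return list with `counts` (a site-count table), `records` (age records
#'   including the hidden `true_age`), `truth` (per-sample true ages) and
#'   `sites` (per-site truth: clock flag, intercept, slope).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)

  ## individuals and samples
  n_ind <- spec$n_individuals
  ages1 <- pmin(pmax(rgamma(n_ind, shape = 2.4, scale = 7),
                     spec$age_range[1]), spec$age_range[2])
  paired <- seq_len(spec$n_pairs)
  gaps <- runif(spec$n_pairs, spec$pair_gap_range[1], spec$pair_gap_range[2])
  ages1[paired] <- pmin(ages1[paired],
                        spec$age_range[2] - gaps - 0.5)  # room for sample 2
  ind_id <- sprintf("I%03d", seq_len(n_ind))
  sample_ind <- c(seq_len(n_ind), paired)
  true_age <- c(ages1, ages1[paired] + gaps)
  base_date <- as.Date("2010-01-01") + round(runif(n_ind, 0, 1500))
  coll_date <- c(base_date, base_date[paired] + round(gaps * 365.25))
  ord <- order(sample_ind, coll_date)
  sample_ind <- sample_ind[ord]; true_age <- true_age[ord]
  coll_date <- coll_date[ord]
  sample_id <- sprintf("S%03d", seq_along(sample_ind))

  records <- degrade_ages(true_age, sample_ids = sample_id,
                          individual_ids = ind_id[sample_ind],
                          collection_dates = coll_date)

  ## site truth
  loci <- sprintf("L%02d", seq_len(spec$n_loci))
  cpg <- expand.grid(locus = loci, k = seq_len(spec$cpg_per_locus),
                     stringsAsFactors = FALSE)
  cpg$position <- cpg$k * 10L           # spaced along the amplicon
  n_cpg <- nrow(cpg)
  is_clock <- seq_len(n_cpg) %in% sample(n_cpg, spec$n_clock_sites)
  slope <- ifelse(is_clock,
                  runif(n_cpg, spec$slope_range[1], spec$slope_range[2]) *
                    sample(c(-1, 1), n_cpg, replace = TRUE), 0)
  # keep clock sites away from saturation over the age range
  icpt <- runif(n_cpg, spec$intercept_range[1], spec$intercept_range[2]) -
    slope * mean(spec$age_range)
  sites <- data.frame(site_id = paste(cpg$locus, cpg$position, sep = "_"),
                      locus = cpg$locus, position = cpg$position,
                      is_clock = is_clock, intercept = icpt, slope = slope,
                      stringsAsFactors = FALSE)

  n_s <- length(sample_id)
  pv <- runif(n_s, spec$conversion_range[1], spec$conversion_range[2])
  depth_mean <- runif(n_s, spec$depth_range[1], spec$depth_range[2])

  ## CpG counts
  L <- outer(true_age, slope) + matrix(icpt, n_s, n_cpg, byrow = TRUE) +
    matrix(rnorm(n_s * n_cpg, 0, spec$sd_biological), n_s, n_cpg)
  p_true <- inv_logit(L)
  pvM <- matrix(pv, n_s, n_cpg)
  pC <- p_true + (1 - p_true) * (1 - pvM)   # unconverted unmethylated Cs
  depth <- matrix(round(depth_mean * runif(n_s * n_cpg, 0.7, 1.3)),
                  n_s, n_cpg)
  sp <- .split_reads(as.vector(depth), as.vector(pC), spec$error_rate)
  cpg_counts <- data.frame(
    sample_id = rep(sample_id, times = n_cpg),
    locus = rep(sites$locus, each = n_s),
    position = rep(sites$position, each = n_s),
    site_class = "CpG",
    n_A = sp$n_A, n_C = sp$n_C, n_G = sp$n_G, n_T = sp$n_T,
    stringsAsFactors = FALSE)

  ## non-CpG cytosine controls (unmethylated; C reads = conversion failures)
  ctl <- expand.grid(locus = loci, k = seq_len(spec$noncpg_per_locus),
                     stringsAsFactors = FALSE)
  ctl$position <- 1000L + ctl$k * 7L
  n_ctl <- nrow(ctl)
  depth_c <- matrix(round(rep(depth_mean, times = n_ctl) *
                            runif(n_s * n_ctl, 0.7, 1.3)), n_s, n_ctl)
  pC_ctl <- matrix(1 - pv, n_s, n_ctl)
  spc <- .split_reads(as.vector(depth_c), as.vector(pC_ctl),
                      spec$error_rate)
  ctl_counts <- data.frame(
    sample_id = rep(sample_id, times = n_ctl),
    locus = rep(ctl$locus, each = n_s),
    position = rep(ctl$position, each = n_s),
    site_class = "nonCpG_C",
    n_A = spc$n_A, n_C = spc$n_C, n_G = spc$n_G, n_T = spc$n_T,
    stringsAsFactors = FALSE)

  counts <- validate_site_counts(rbind(cpg_counts, ctl_counts))
  list(counts = counts, records = records,
       truth = data.frame(sample_id = sample_id, true_age = true_age,
                          conversion_efficiency = pv,
                          stringsAsFactors = FALSE),
       sites = sites)
}

#' Write a synthetic cohort to disk in the pipeline's input formats
#'
#' @param cohort output of [generate_cohort()].
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p1 <- file.path(dir, "site_counts.tsv")
  write.table(cohort$counts, p1, sep = "\t", quote = FALSE,
              row.names = FALSE)
  p2 <- file.path(dir, "age_records.tsv")
  write.table(cohort$records[, c("sample_id", "individual_id",
                                 "collection_date", "age_best", "age_min",
                                 "age_max", "cr")],
              p2, sep = "\t", quote = FALSE, row.names = FALSE)
  p3 <- file.path(dir, "truth.tsv")
  write.table(merge(cohort$truth,
                    cohort$records[, c("sample_id", "cr")]),
              p3, sep = "\t", quote = FALSE, row.names = FALSE)
  p4 <- file.path(dir, "site_truth.tsv")
  write.table(cohort$sites, p4, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(p1, p2, p3, p4))
}
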