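# Confidence-weighted skew-normal age probability distributions built from
# photo-identification catalogue age estimates (Age_best, Age_min, Age_max
# and an ordinal confidence rating CR in 2..5).

#' Read catalogue age records
#'
#' Delimited text (TSV/CSV by extension) with header `sample_id`,
#' `individual_id`, `collection_date` (ISO 8601), `age_best`, `age_min`,
#' `age_max`, `cr`.
#'
#' @param path path to the age metadata file.
#' @return validated data.frame of age records.
#' @export
read_age_records <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  validate_age_records(read.delim(path, sep = sep, stringsAsFactors = FALSE))
}

#' Validate catalogue age records
#'
#' @param records data.frame of age records.
#' @return the records, with `collection_date` parsed to `Date`.
#' @export
validate_age_records <- function(records) {
  need <- c("sample_id", "individual_id", "collection_date",
            "age_best", "age_min", "age_max", "cr")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("age records are missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(records$sample_id)) stop("duplicate sample_id")
  with(records, {
    if (any(age_min < 0) || any(age_best < 0)) stop("ages must be >= 0")
    if (any(age_max <= age_min)) stop("age_max must exceed age_min")
    if (any(age_best < age_min | age_best > age_max))
      stop("age_best must lie within [age_min, age_max]")
  })
  if (any(!records$cr %in% 2:5))
    stop("confidence ratings must be in {2, 3, 4, 5}")
  records$collection_date <- as.Date(records$collection_date)
  records
}

#' Skew-normal to Uniform mixture weight for a confidence rating
#'
#' Higher catalogue confidence puts more weight on the fitted skew-normal
#' and less on the flat Uniform(Age_min, Age_max) component: weights are
#' 0.2, 0.55, 0.75 and 1.0 for CR 2, 3, 4 and 5. No weight is defined for
#' CR 1 (very low confidence); such samples are rejected.
#'
#' @param cr integer confidence rating(s) in 2..5.
#' @return numeric vector of skew-normal component weights.
#' @export
mixture_weight <- function(cr) {
  w <- c(`2` = 0.2, `3` = 0.55, `4` = 0.75, `5` = 1.0)
  if (any(!cr %in% 2:5))
    stop("confidence rating must be in {2, 3, 4, 5}; no weight is defined ",
         "for CR = 1")
  unname(w[as.character(cr)])
}

# Standard-scale summaries used by the fitter: mode and the 2.5%/97.5%
# quantiles of SN(0, 1, alpha).
.sn_std <- function(alpha) {
  c(mode = sn_mode(0, 1, alpha),
    lo = qsn(0.025, 0, 1, alpha),
    hi = qsn(0.975, 0, 1, alpha))
}

#' Fit a skew-normal to catalogue age constraints
#'
#' Finds (location, scale, shape) such that the distribution's mode equals
#' `age_best` and its 0.025 and 0.975 quantiles equal `age_min` and
#' `age_max`. Because mode and quantiles are location-scale equivariant,
#' the problem reduces to a one-dimensional root search on the shape: the
#' relative position `(age_best - age_min) / (age_max - age_min)` pins down
#' the shape, after which location and scale follow linearly. Symmetric
#' inputs give shape 0 (a Normal); `age_best` nearer `age_min` forces
#' positive (right) skew.
#'
#' @param age_best,age_min,age_max catalogue ages in years,
#'   `age_min <= age_best <= age_max`, `age_min < age_max`.
#' @param tol required absolute accuracy (years / probability), default 1e-3.
#' @return list with `location`, `scale`, `shape`.
#' @export
fit_skew_normal <- function(age_best, age_min, age_max, tol = 1e-3) {
  if (age_min >= age_max) stop("age_min must be strictly below age_max")
  rng <- age_max - age_min
  # mode cannot sit exactly on an extreme quantile: nudge inward
  eps <- 1e-6 * rng
  b <- min(max(age_best, age_min + eps), age_max - eps)
  r <- (b - age_min) / rng

  g <- function(alpha) {
    s <- .sn_std(alpha)
    (s["mode"] - s["lo"]) / (s["hi"] - s["lo"]) - r
  }
  if (abs(r - 0.5) < 1e-10) {
    alpha <- 0
  } else {
    # g is decreasing in alpha; bracket then root-find. |alpha| = 200 puts
    # the mode slightly outside the [q025, q975] span, so every nudged
    # boundary case stays inside the bracket.
    lim <- 200
    glo <- g(-lim); ghi <- g(lim)
    if (!(glo > 0 && ghi < 0) && !(glo < 0 && ghi > 0))
      stop("cannot fit a skew-normal: age_best too close to age_min or ",
           "age_max (relative position ", signif(r, 4), ")")
    alpha <- uniroot(g, lower = -lim, upper = lim, tol = 1e-9)$root
  }
  s <- .sn_std(alpha)
  omega <- rng / (s["hi"] - s["lo"])
  xi <- age_min - omega * s["lo"]
  fit <- list(location = unname(xi), scale = unname(omega), shape = alpha)
  # verify the constraints actually hold
  m <- sn_mode(fit$location, fit$scale, fit$shape)
  e <- c(abs(m - b),
         abs(psn(age_min, fit$location, fit$scale, fit$shape) - 0.025),
         abs(psn(age_max, fit$location, fit$scale, fit$shape) - 0.975))
  if (any(e > tol))
    stop(sprintf(
      "skew-normal fit did not meet tolerance for (%.3g, %.3g, %.3g): %s",
      age_best, age_min, age_max, paste(signif(e, 3), collapse = ", ")))
  fit
}

#' Build confidence-weighted age priors for a set of records
#'
#' @param records validated age records (see [read_age_records()]).
#' @param tol fit tolerance passed to [fit_skew_normal()].
#' @return a named list of `age_prior` objects (one per sample), each with
#'   the skew-normal parameters, the CR mixture weight and the
#'   (Age_min, Age_max) support of the Uniform component.
#' @export
fit_age_priors <- function(records, tol = 1e-3) {
  records <- validate_age_records(records)
  out <- lapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    fit <- tryCatch(
      fit_skew_normal(r$age_best, r$age_min, r$age_max, tol = tol),
      error = function(e) stop("sample ", r$sample_id, ": ",
                               conditionMessage(e), call. = FALSE))
    structure(list(sample_id = r$sample_id,
                   location = fit$location, scale = fit$scale,
                   shape = fit$shape, weight = mixture_weight(r$cr),
                   age_min = r$age_min, age_max = r$age_max,
                   age_best = r$age_best, cr = r$cr),
              class = "age_prior")
  })
  names(out) <- records$sample_id
  out
}

#' Scaled likelihood of an age under a confidence-weighted prior
#'
#' `w * SkewNormal(age) + (1 - w) * Uniform(age; age_min, age_max)`. The
#' skew-normal component is not truncated to the catalogue range: the range
#' endpoints are its 2.5%/97.5% quantiles, so 5% of its mass lies outside
#' by construction.
#'
#' @param age numeric vector of ages (years).
#' @param prior an `age_prior`.
#' @return numeric vector of mixture densities.
#' @export
age_density <- function(age, prior) {
  stopifnot(inherits(prior, "age_prior"))
  sn <- dsn(age, prior$location, prior$scale, prior$shape)
  un <- ifelse(age >= prior$age_min & age <= prior$age_max,
               1 / (prior$age_max - prior$age_min), 0)
  prior$weight * sn + (1 - prior$weight) * un
}

#' Draw ages from a confidence-weighted prior
#'
#' Chooses the skew-normal component with probability `w` and the Uniform
#' with `1 - w`, then draws from it. Negative draws (possible from the
#' skew-normal tail) are rejected and redrawn; draws outside
#' (age_min, age_max) are kept.
#'
#' @param prior an `age_prior`.
#' @param n number of draws.
#' @return numeric vector of `n` non-negative age draws.
#' @export
sample_age <- function(prior, n = 1) {
  stopifnot(inherits(prior, "age_prior"), n >= 0)
  out <- numeric(0)
  while (length(out) < n) {
    m <- n - length(out)
    comp <- runif(m) < prior$weight
    x <- numeric(m)
    if (any(comp))
      x[comp] <- rsn(sum(comp), prior$location, prior$scale, prior$shape)
    if (any(!comp))
      x[!comp] <- runif(sum(!comp), prior$age_min, prior$age_max)
    out <- c(out, x[x >= 0])
  }
  out
}

#' @export
print.age_prior <- function(x, ...) {
  cat(sprintf(
    "age_prior %s: SN(loc=%.3f, scale=%.3f, shape=%.3f), w=%.2f (CR %d), range [%.4g, %.4g]\n",
    x$sample_id, x$location, x$scale, x$shape, x$weight, x$cr,
    x$age_min, x$age_max))
  invisible(x)
}

#' Serialise / restore fitted age priors
#'
#' One TSV row per sample holding the three skew-normal parameters, the
#' mixture weight and the catalogue fields, so fitted priors can be reused
#' across runs without re-solving.
#'
#' @param priors named list of `age_prior` objects.
#' @param path output (input) TSV path.
#' @return `write_age_priors` the path, invisibly; `read_age_priors` the
#'   restored list.
#' @export
write_age_priors <- function(priors, path) {
  df <- do.call(rbind, lapply(priors, function(p)
    data.frame(sample_id = p$sample_id, location = p$location,
               scale = p$scale, shape = p$shape, weight = p$weight,
               age_min = p$age_min, age_max = p$age_max,
               age_best = p$age_best, cr = p$cr)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_age_priors
#' @export
read_age_priors <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i) {
    r <- as.list(df[i, ])
    structure(r, class = "age_prior")
  })
  names(out) <- df$sample_id
  out
}
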