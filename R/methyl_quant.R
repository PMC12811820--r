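# Methylation quantification from per-site nucleotide read counts:
# corrected coverage, bisulfite conversion efficiency, sequencing error rate,
# conversion-corrected methylation on the logit scale, and sequential QC
# filtering of samples and CpG sites.

.SITE_CLASSES <- c("CpG", "nonCpG_C")

#' Read a per-site nucleotide count table
#'
#' Expects delimited text (TSV or CSV, auto-detected from the file
#' extension) with columns `sample_id`, `locus`, `position`, `site_class`,
#' `n_A`, `n_C`, `n_G`, `n_T`. Positions are 0-based within the amplicon
#' reference; `site_class` is `"CpG"` or `"nonCpG_C"`.
#'
#' @param path path to the count table.
#' @return a validated data.frame of site counts.
#' @export
read_site_counts <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  validate_site_counts(df)
}

#' Validate a site-count table
#'
#' Checks column presence, count non-negativity, key uniqueness and that
#' `site_class` is constant per (locus, position) across samples.
#'
#' @param counts data.frame of per-site counts.
#' @return the table, invisibly passed through (with integer counts).
#' @export
validate_site_counts <- function(counts) {
  need <- c("sample_id", "locus", "position", "site_class",
            "n_A", "n_C", "n_G", "n_T")
  miss <- setdiff(need, names(counts))
  if (length(miss))
    stop("count table is missing columns: ", paste(miss, collapse = ", "))
  bad <- which(!counts$site_class %in% .SITE_CLASSES)
  if (length(bad))
    stop("invalid site_class at rows: ", paste(head(bad, 5), collapse = ", "))
  cnt <- as.matrix(counts[, c("n_A", "n_C", "n_G", "n_T")])
  if (any(!is.finite(cnt)) || any(cnt < 0))
    stop("nucleotide counts must be finite and non-negative")
  if (any(counts$position < 0)) stop("positions must be >= 0")
  key <- paste(counts$sample_id, counts$locus, counts$position)
  if (anyDuplicated(key))
    stop("duplicate (sample, locus, position) keys in count table")
  site <- paste(counts$locus, counts$position)
  cls <- tapply(counts$site_class, site, function(x) length(unique(x)))
  if (any(cls > 1))
    stop("site_class differs across samples for some (locus, position)")
  counts
}

#' Corrected coverage at a cytosine site
#'
#' Reads carrying A or G at a cytosine site are treated as sequencing errors
#' and discarded, so the corrected coverage is the total read count minus
#' the A and G reads, i.e. the C + T reads.
#'
#' @param n_A,n_C,n_G,n_T non-negative read counts (vectorised).
#' @return integer vector of corrected coverages.
#' @export
corrected_coverage <- function(n_A, n_C, n_G, n_T) {
  stopifnot(all(n_A >= 0), all(n_C >= 0), all(n_G >= 0), all(n_T >= 0))
  as.integer((n_A + n_C + n_G + n_T) - (n_A + n_G))
}

#' Per-sample bisulfite conversion efficiency
#'
#' Non-CpG cytosines are assumed unmethylated, so every such read should be
#' converted to T. The conversion efficiency P_v of a sample is the total T
#' count over all its non-CpG cytosine sites divided by the summed corrected
#' coverage at those sites, pooling all loci.
#'
#' @param counts a site-count table (see [read_site_counts()]).
#' @return named numeric vector of P_v, one entry per sample.
#' @export
conversion_efficiency <- function(counts) {
  ctrl <- counts[counts$site_class == "nonCpG_C", , drop = FALSE]
  samples <- unique(counts$sample_id)
  k <- corrected_coverage(ctrl$n_A, ctrl$n_C, ctrl$n_G, ctrl$n_T)
  kv <- tapply(k, factor(ctrl$sample_id, levels = samples), sum)
  tv <- tapply(ctrl$n_T, factor(ctrl$sample_id, levels = samples), sum)
  bad <- is.na(kv) | kv == 0
  if (any(bad))
    stop("no non-CpG cytosine coverage for sample(s): ",
         paste(samples[bad], collapse = ", "))
  setNames(as.numeric(tv / kv), samples)
}

#' Per-sample sequencing error rate
#'
#' The proportion of A and G reads among all reads mapped to cytosine sites
#' (CpG and non-CpG) for each sample.
#'
#' @inheritParams conversion_efficiency
#' @return named numeric vector of error rates per sample.
#' @export
sequencing_error_rate <- function(counts) {
  samples <- unique(counts$sample_id)
  f <- factor(counts$sample_id, levels = samples)
  err <- tapply(counts$n_A + counts$n_G, f, sum)
  tot <- tapply(counts$n_A + counts$n_C + counts$n_G + counts$n_T, f, sum)
  if (any(is.na(tot)) || any(tot == 0))
    stop("zero total reads for some sample")
  setNames(as.numeric(err / tot), samples)
}

#' Conversion-efficiency-corrected methylation
#'
#' Applies `P_hat = 1 - (1 - P_m) / P_v`. Incomplete bisulfite conversion
#' leaves unmethylated cytosines unconverted, inflating the apparent
#' methylation; this rescales it down. When `P_v <= 1 - P_m` the corrected
#' value is <= 0 and is replaced by one half of the smallest strictly
#' positive corrected value observed at the same locus. Symmetrically, a
#' corrected value >= 1 (all reads methylated) would make the logit
#' infinite and is replaced by 1 minus half the smallest positive
#' `1 - P_hat` at the locus.
#'
#' @param P_m observed methylation proportions in \[0, 1\].
#' @param P_v conversion efficiency (scalar or one per element of `P_m`).
#' @param locus locus labels, one per element of `P_m`; the substitution
#'   rules pool values within locus.
#' @return corrected methylation proportions, all strictly inside (0, 1).
#' @export
correct_methylation <- function(P_m, P_v, locus) {
  stopifnot(all(P_m >= 0), all(P_m <= 1), all(P_v > 0), all(P_v <= 1))
  n <- length(P_m)
  P_v <- rep_len(P_v, n)
  locus <- rep_len(locus, n)
  raw <- 1 - (1 - P_m) / P_v
  out <- raw
  for (lc in unique(locus)) {
    idx <- which(locus == lc)
    v <- raw[idx]
    low <- which(v <= 0)
    if (length(low)) {
      pos <- v[v > 0]
      if (!length(pos))
        stop("degenerate locus '", lc,
             "': no strictly positive corrected methylation value")
      out[idx[low]] <- min(pos) / 2
    }
    high <- which(v >= 1)
    if (length(high)) {
      gaps <- 1 - v[v < 1 & v > 0]
      if (!length(gaps))
        stop("degenerate locus '", lc,
             "': no corrected methylation value below 1")
      out[idx[high]] <- 1 - min(gaps) / 2
    }
  }
  out
}

#' Logit-scale methylation
#'
#' @param P_hat corrected methylation proportions, strictly inside (0, 1).
#' @return `log(P_hat / (1 - P_hat))`.
#' @export
logit_methylation <- function(P_hat) {
  if (any(!is.finite(P_hat)) || any(P_hat <= 0) || any(P_hat >= 1))
    stop("corrected methylation must lie strictly in (0, 1) before logit")
  logit(P_hat)
}

.median_mid <- function(x) stats::median(x)  # midpoint convention for even n

#' Sequential QC filter and methylation matrix construction
#'
#' Applies the three sequential depth filters and then builds the corrected,
#' logit-scale methylation matrix:
#' \enumerate{
#'   \item drop samples whose median corrected CpG coverage is below
#'     `sample_median_threshold`;
#'   \item drop CpG sites whose median corrected coverage across the
#'     remaining samples is below `site_median_threshold`;
#'   \item drop samples with any remaining CpG site below `per_site_min`.
#' }
#' Depth throughout is the corrected coverage `K_m` (C + T reads). The stage
#' order matters: site medians are computed only over samples surviving
#' stage 1, and the filter is idempotent.
#'
#' @param counts a validated site-count table.
#' @param sample_median_threshold minimum per-sample median CpG depth
#'   (default 1000 reads).
#' @param site_median_threshold minimum per-site median depth (default 1000).
#' @param per_site_min minimum depth at every retained site (default 100).
#' @return a list with `matrix` (a `meth_matrix` object) and `report` (a
#'   `filter_report` listing removals by stage and the thresholds used).
#' @export
qc_filter <- function(counts, sample_median_threshold = 1000,
                      site_median_threshold = 1000, per_site_min = 100) {
  stopifnot(sample_median_threshold >= 0, site_median_threshold >= 0,
            per_site_min >= 0)
  counts <- validate_site_counts(counts)
  cpg <- counts[counts$site_class == "CpG", , drop = FALSE]
  if (!nrow(cpg)) stop("count table contains no CpG rows")
  cpg$K <- corrected_coverage(cpg$n_A, cpg$n_C, cpg$n_G, cpg$n_T)
  cpg$site_id <- paste(cpg$locus, cpg$position, sep = "_")

  samples <- unique(counts$sample_id)
  sites <- unique(cpg[, c("site_id", "locus", "position")])
  sites <- sites[order(sites$locus, sites$position), , drop = FALSE]

  dep <- matrix(NA_real_, length(samples), nrow(sites),
                dimnames = list(samples, sites$site_id))
  dep[cbind(match(cpg$sample_id, samples), match(cpg$site_id, sites$site_id))] <- cpg$K
  dep0 <- dep
  dep0[is.na(dep0)] <- 0   # absent rows count as zero coverage

  # stage 1: sample median CpG depth
  smed <- apply(dep0, 1, .median_mid)
  rm_samples1 <- samples[smed < sample_median_threshold]
  keep_s <- setdiff(samples, rm_samples1)

  # stage 2: site median depth over remaining samples
  if (length(keep_s)) {
    cmed <- apply(dep0[keep_s, , drop = FALSE], 2, .median_mid)
    rm_sites <- sites$site_id[cmed < site_median_threshold]
  } else rm_sites <- character(0)
  keep_c <- setdiff(sites$site_id, rm_sites)

  # stage 3: any remaining site under the per-site minimum
  if (length(keep_s) && length(keep_c)) {
    sub <- dep0[keep_s, keep_c, drop = FALSE]
    low <- apply(sub < per_site_min, 1, any)
    rm_samples3 <- keep_s[low]
  } else rm_samples3 <- character(0)
  keep_s <- setdiff(keep_s, rm_samples3)

  report <- structure(list(
    samples_removed_low_median_depth = rm_samples1,
    sites_removed_low_median_depth = rm_sites,
    samples_removed_low_site_coverage = rm_samples3,
    thresholds = c(sample_median = sample_median_threshold,
                   site_median = site_median_threshold,
                   per_site_min = per_site_min)), class = "filter_report")

  if (!length(keep_s) || !length(keep_c)) {
    warning("QC filtering removed everything; returning an empty matrix")
    return(list(matrix = empty_meth_matrix(), report = report))
  }

  keep_counts <- counts[counts$sample_id %in% keep_s, , drop = FALSE]
  pv <- conversion_efficiency(keep_counts)
  er <- sequencing_error_rate(keep_counts)

  sub <- cpg[cpg$sample_id %in% keep_s & cpg$site_id %in% keep_c, , drop = FALSE]
  sinfo <- sites[sites$site_id %in% keep_c, , drop = FALSE]
  mk <- function(v, default = NA_real_) {
    m <- matrix(default, length(keep_s), nrow(sinfo),
                dimnames = list(keep_s, sinfo$site_id))
    m[cbind(match(sub$sample_id, keep_s), match(sub$site_id, sinfo$site_id))] <- v
    m
  }
  n_m <- mk(as.numeric(sub$n_C))
  K_m <- mk(as.numeric(sub$K))
  if (any(is.na(K_m)))
    warning("some retained cells have no count row; their M is set to NA")
  P_m <- n_m / K_m
  P_m[K_m == 0] <- NA
  if (any(is.na(P_m)))
    warning("retained cells with zero corrected coverage; M set to NA there")

  locus_of <- sinfo$locus[match(colnames(P_m), sinfo$site_id)]
  ok <- which(!is.na(P_m))
  P_hat <- P_m
  P_hat[ok] <- correct_methylation(
    P_m[ok], pv[keep_s][(ok - 1) %% nrow(P_m) + 1],
    locus_of[(ok - 1) %/% nrow(P_m) + 1])
  M <- P_hat
  M[ok] <- logit_methylation(P_hat[ok])

  qc <- data.frame(sample_id = keep_s,
                   conversion_efficiency = as.numeric(pv[keep_s]),
                   sequencing_error_rate = as.numeric(er[keep_s]),
                   median_cpg_depth = apply(K_m, 1, .median_mid),
                   stringsAsFactors = FALSE)
  mm <- structure(list(M = M, P_m = P_m, P_hat = P_hat,
                       n_m = n_m, K_m = K_m,
                       sites = sinfo[, c("site_id", "locus", "position")],
                       samples = qc), class = "meth_matrix")
  list(matrix = mm, report = report)
}

empty_meth_matrix <- function() {
  z <- matrix(numeric(0), 0, 0)
  structure(list(M = z, P_m = z, P_hat = z, n_m = z, K_m = z,
                 sites = data.frame(site_id = character(0),
                                    locus = character(0),
                                    position = integer(0)),
                 samples = data.frame(sample_id = character(0),
                                      conversion_efficiency = numeric(0),
                                      sequencing_error_rate = numeric(0),
                                      median_cpg_depth = numeric(0))),
            class = "meth_matrix")
}

#' Quantify methylation from a count table
#'
#' Convenience wrapper: validates, QC-filters and builds the corrected
#' logit-scale methylation matrix with the published default thresholds.
#'
#' @inheritParams qc_filter
#' @return see [qc_filter()].
#' @export
quantify_methylation <- function(counts, sample_median_threshold = 1000,
                                 site_median_threshold = 1000,
                                 per_site_min = 100) {
  qc_filter(counts, sample_median_threshold, site_median_threshold,
            per_site_min)
}

#' @export
print.meth_matrix <- function(x, ...) {
  cat("meth_matrix:", nrow(x$M), "samples x", ncol(x$M), "CpG sites\n")
  if (nrow(x$samples)) {
    cat(sprintf("  conversion efficiency: %.4f-%.4f\n",
                min(x$samples$conversion_efficiency),
                max(x$samples$conversion_efficiency)))
    cat(sprintf("  median CpG depth: %.0f-%.0f\n",
                min(x$samples$median_cpg_depth),
                max(x$samples$median_cpg_depth)))
  }
  invisible(x)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("QC filter report (thresholds:",
      paste(names(x$thresholds), x$thresholds, sep = "=", collapse = ", "),
      ")\n")
  cat("  stage 1, samples below median-depth threshold:",
      length(x$samples_removed_low_median_depth), "\n")
  cat("  stage 2, sites below median-depth threshold:",
      length(x$sites_removed_low_median_depth), "\n")
  cat("  stage 3, samples with an under-covered site:",
      length(x$samples_removed_low_site_coverage), "\n")
  invisible(x)
}

#' Write a methylation matrix to disk
#'
#' Writes three TSVs: the wide logit-scale matrix (samples x sites), a
#' long-format table retaining the raw `n_m`/`K_m` counts needed for
#' resampling, and the per-sample QC statistics.
#'
#' @param mm a `meth_matrix`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisibly, the paths written.
#' @export
write_meth_matrix <- function(mm, dir, prefix = "methylation") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wide <- data.frame(sample_id = rownames(mm$M), mm$M, check.names = FALSE)
  p1 <- file.path(dir, paste0(prefix, "_logit.tsv"))
  write.table(wide, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  long <- data.frame(
    sample_id = rep(rownames(mm$M), times = ncol(mm$M)),
    site_id = rep(colnames(mm$M), each = nrow(mm$M)),
    n_m = as.vector(mm$n_m), K_m = as.vector(mm$K_m),
    P_m = as.vector(mm$P_m), P_hat = as.vector(mm$P_hat),
    M = as.vector(mm$M))
  p2 <- file.path(dir, paste0(prefix, "_counts.tsv"))
  write.table(long, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  p3 <- file.path(dir, paste0(prefix, "_sample_qc.tsv"))
  write.table(mm$samples, p3, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2, p3))
}
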