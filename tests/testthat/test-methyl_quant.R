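# Methylation quantification: corrected coverage, conversion efficiency,
# error rate, the conversion correction with its substitution rules, and
# the three-stage QC filter.

test_that("corrected coverage is the C + T read count", {
  expect_identical(corrected_coverage(2, 500, 1, 300), 800L)
  expect_identical(corrected_coverage(0, 10, 0, 5), 15L)
  expect_identical(corrected_coverage(3, 0, 2, 0), 0L)
  # property: equals n_C + n_T exactly for random count vectors
  set.seed(1)
  for (i in 1:20) {
    cnt <- rpois(4, 100)
    expect_identical(corrected_coverage(cnt[1], cnt[2], cnt[3], cnt[4]),
                     as.integer(cnt[2] + cnt[4]))
  }
  expect_error(corrected_coverage(-1, 0, 0, 0))
})

test_that("conversion efficiency pools non-CpG cytosines per sample", {
  tab <- rbind(
    count_row("a", "L1", 1, "nonCpG_C", T = 600),
    count_row("a", "L2", 1, "nonCpG_C", T = 400),
    count_row("b", "L1", 1, "nonCpG_C", C = 5, T = 995),
    count_row("c", "L1", 1, "nonCpG_C", C = 500, T = 500),
    count_row("a", "L1", 5, "CpG", C = 50, T = 50),
    count_row("b", "L1", 5, "CpG", C = 50, T = 50),
    count_row("c", "L1", 5, "CpG", C = 50, T = 50))
  pv <- conversion_efficiency(tab)
  expect_equal(pv[["a"]], 1.0)
  expect_equal(pv[["b"]], 0.995)
  expect_equal(pv[["c"]], 0.5)
  # a sample with no control coverage is an error
  expect_error(conversion_efficiency(count_row("z", "L1", 5, "CpG", C = 10)),
               "non-CpG")
})

test_that("sequencing error rate is the A+G fraction over all reads", {
  tab <- rbind(count_row("a", "L1", 1, "CpG", A = 1, C = 5000, G = 1, T = 4998),
               count_row("b", "L1", 1, "CpG", C = 10, T = 10),
               count_row("c", "L1", 1, "CpG", A = 7))
  er <- sequencing_error_rate(tab)
  expect_equal(er[["a"]], 2 / 10000)
  expect_equal(er[["b"]], 0)
  expect_equal(er[["c"]], 1)
})

test_that("conversion correction follows 1 - (1 - Pm)/Pv with substitutions", {
  expect_equal(correct_methylation(0.5, 1.0, "L"), 0.5)
  expect_equal(correct_methylation(0.5, 0.995, "L"), 1 - 0.5 / 0.995)
  # a cell at or below zero takes half the locus minimum positive value
  got <- correct_methylation(c(0.004, 0.0149501), c(0.995, 0.995),
                             c("L", "L"))
  # second cell: 1 - (1 - 0.0149501)/0.995 = 0.01 approx
  expect_equal(got[2], 1 - (1 - 0.0149501) / 0.995)
  expect_equal(got[1], got[2] / 2)
  # symmetric rule at the top keeps logit finite
  got <- correct_methylation(c(1, 0.9), c(0.99, 0.99), c("L", "L"))
  expect_lt(got[1], 1)
  expect_equal(got[1], 1 - (1 - got[2]) / 2)
  # a locus with no positive corrected value cannot be repaired
  expect_error(correct_methylation(0.001, 0.99, "L"), "degenerate locus")
})

test_that("the correction is the identity at Pv = 1 and monotone in Pm", {
  # identity on the open interval; the endpoint substitution rules exist
  # precisely so 0 and 1 never reach the logit
  pm <- seq(0.01, 0.99, by = 0.01)
  expect_equal(correct_methylation(pm, 1, rep("L", length(pm))), pm)
  for (pv in c(0.9, 0.993, 0.997)) {
    pm <- seq(0.05, 0.999, by = 0.001)
    ph <- 1 - (1 - pm) / pv
    keep <- ph > 0
    got <- correct_methylation(pm[keep], pv, rep("L", sum(keep)))
    expect_true(all(diff(got) > 0))          # strictly increasing
    expect_true(all(got <= pm[keep]))        # correction never inflates
    expect_true(all(got > 0 & got < 1))
  }
})

test_that("logit methylation and its inverse behave", {
  expect_equal(logit_methylation(0.5), 0)
  expect_equal(logit_methylation(0.9), log(9))
  p <- runif(50, 0.01, 0.99)
  expect_equal(inv_logit(logit_methylation(p)), p, tolerance = 1e-12)
  expect_error(logit_methylation(1))
  expect_error(logit_methylation(0))
  expect_error(logit_methylation(-0.1))
})

test_that("QC filter removes exactly the hand-computed sets, in order", {
  res <- qc_filter(qc_fixture())
  rep <- res$report
  expect_identical(rep$samples_removed_low_median_depth, "s01")
  expect_identical(rep$sites_removed_low_median_depth, "L1_3")
  expect_identical(rep$samples_removed_low_site_coverage, "s02")
  expect_identical(rownames(res$matrix$M), sprintf("s%02d", 3:10))
  expect_identical(colnames(res$matrix$M), paste0("L1_", c(1, 2, 4, 5)))
  # every retained cell finite on the logit scale
  expect_true(all(is.finite(res$matrix$M)))
})

test_that("QC filter is idempotent and vacuous at zero thresholds", {
  res0 <- qc_filter(qc_fixture(), 0, 0, 0)
  expect_length(res0$report$samples_removed_low_median_depth, 0)
  expect_length(res0$report$sites_removed_low_median_depth, 0)
  expect_length(res0$report$samples_removed_low_site_coverage, 0)
  expect_equal(nrow(res0$matrix$M), 10)

  # idempotence: refiltering the survivors changes nothing
  res1 <- qc_filter(qc_fixture())
  keep <- qc_fixture()
  keep <- keep[keep$sample_id %in% rownames(res1$matrix$M) &
                 (keep$site_class == "nonCpG_C" |
                    paste(keep$locus, keep$position, sep = "_") %in%
                      colnames(res1$matrix$M)), ]
  res2 <- qc_filter(keep)
  expect_length(unlist(res2$report[1:3]), 0)
  expect_equal(res2$matrix$M, res1$matrix$M)
})

test_that("filter stage order matters: site medians use stage-1 survivors", {
  # s1 is removed at stage 1; site c2's median crosses the threshold only
  # if s1 were (incorrectly) included
  samples <- c("s1", "s2", "s3", "s4")
  depth <- rbind(s1 = c(100, 100, 100),
                 s2 = c(2000, 1000, 2000),
                 s3 = c(2000, 1000, 2000),
                 s4 = c(2000, 900, 2000))
  rows <- list()
  for (i in seq_along(samples)) for (j in 1:3) {
    K <- depth[i, j]
    rows[[length(rows) + 1]] <- count_row(samples[i], "L1", j, "CpG",
                                          C = K / 2, T = K / 2)
  }
  tab <- rbind(do.call(rbind, rows), control_rows(samples))
  res <- qc_filter(tab, 1000, 1000, 0)
  expect_identical(res$report$samples_removed_low_median_depth, "s1")
  expect_false("L1_2" %in% res$report$sites_removed_low_median_depth)
  expect_true("L1_2" %in% colnames(res$matrix$M))
})

test_that("an empty result warns rather than crashes", {
  expect_warning(res <- qc_filter(qc_fixture(), 1e7, 0, 0), "empty")
  expect_equal(nrow(res$matrix$M), 0)
})

test_that("count-table validation catches structural errors", {
  tab <- qc_fixture()
  expect_error(validate_site_counts(tab[, -3]), "missing columns")
  dup <- rbind(tab, tab[1, ])
  expect_error(validate_site_counts(dup), "duplicate")
  bad <- tab; bad$site_class[1] <- "nonCpG_C"
  expect_error(validate_site_counts(bad), "site_class differs")
})

test_that("matrix round-trips through its TSV writer", {
  res <- qc_filter(qc_fixture())
  d <- withr::local_tempdir()
  paths <- write_meth_matrix(res$matrix, d)
  expect_true(all(file.exists(paths)))
  wide <- read.delim(paths[1], check.names = FALSE)
  expect_equal(as.matrix(wide[, -1]),
               unname(res$matrix$M), ignore_attr = TRUE, tolerance = 1e-9)
})
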