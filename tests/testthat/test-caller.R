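make_well <- function(cq) {
  structure(list(plate_id = "p1", well = "A1", sample_id = "S1",
                 reaction_id = "R1", replicate_index = 1L,
                 cq_by_marker = cq), class = "well_record")
}

test_that("within-well delta-Cq subtracts the reference", {
  w <- make_well(c(M = 24.0, STAT6 = 23.0))
  expect_equal(delta_cq(w, "M", "STAT6"), 1.0)
  w2 <- make_well(c(M = 23.0, STAT6 = 23.0))
  expect_equal(delta_cq(w2, "M", "STAT6"), 0.0)
  w3 <- make_well(c(M = NA_real_, STAT6 = 23.0))
  v <- delta_cq(w3, "M", "STAT6")
  expect_true(is.na(v))
  expect_equal(attr(v, "flag"), "ZERO_CANDIDATE")
  w4 <- make_well(c(M = 24.0, STAT6 = NA_real_))
  expect_error(delta_cq(w4, "M", "STAT6"), "REF_FAIL")
})

test_that("replicates with late reference Cq are removed", {
  d <- qc_filter(target_cq = c(24, 24.1, 23.9, 24.0),
                 ref_cq = c(23, 23.1, 32.5, 23.0))
  expect_equal(d$n_used, 3L)
  expect_true("REF_CQ_HIGH" %in% d$flags)
  expect_false(d$zero_call)

  d2 <- qc_filter(rep(24, 4), rep(33, 4))
  expect_equal(d2$n_used, 0L)
  expect_true("TOO_FEW_REPLICATES" %in% d2$flags)
})

test_that("late target with sound reference is a zero call", {
  d <- qc_filter(target_cq = rep(36, 4), ref_cq = rep(30, 4))
  expect_true(d$zero_call)
  expect_true("ZERO_CALL" %in% d$flags)
  cal <- calibrator(c(M = 2L), c(M = 0.95))
  expect_equal(call_copy_number(d, cal, "M"), 0)
  expect_equal(round_copy_number(call_copy_number(d, cal, "M")), 0L)

  # non-amplifying targets count as zero candidates too
  d2 <- qc_filter(target_cq = rep(NA_real_, 4), ref_cq = rep(28, 4))
  expect_true(d2$zero_call)
})

test_that("the 4-SD outlier rule needs leave-one-out statistics in n = 4", {
  reps <- c(1.00, 1.02, 0.98, 1.50)
  d <- qc_filter(target_cq = 23 + reps, ref_cq = rep(23, 4))
  expect_true("OUTLIER_REMOVED" %in% d$flags)
  expect_equal(d$n_used, 3L)
  expect_equal(d$mean_delta_cq, 1.00)
  # inclusive SD can never flag a single extreme point in a quadruplicate
  d2 <- qc_filter(target_cq = 23 + reps, ref_cq = rep(23, 4),
                  leave_one_out = FALSE)
  expect_equal(d2$n_used, 4L)
  expect_false("OUTLIER_REMOVED" %in% d2$flags)
})

test_that("comparative-Cq copy number follows 2^(-ddCq)", {
  cal <- calibrator(c(M = 2L), c(M = 1.0))
  ds <- function(mdcq) structure(
    list(delta_cq = mdcq, mean_delta_cq = mdcq, mean_ref_cq = 23,
         mean_target_cq = 23 + mdcq, n_used = 4L, zero_call = FALSE,
         flags = character(0)), class = "delta_cq_set")
  expect_equal(call_copy_number(ds(1.0), cal, "M"), 2.0)   # ddCq = 0
  expect_equal(call_copy_number(ds(2.0), cal, "M"), 1.0)   # ddCq = 1
  expect_equal(call_copy_number(ds(1.0 - log2(1.5)), cal, "M"), 3.0)
  expect_error(call_copy_number(ds(1), cal, "X"), "no copy number")

  # strictly decreasing in ddCq; halves per added cycle
  dd <- seq(-2, 2, by = 0.25)
  cn <- vapply(dd, function(z) call_copy_number(ds(1 + z), cal, "M"),
               numeric(1))
  expect_true(all(diff(cn) < 0))
  for (z in dd[-length(dd)])
    expect_equal(call_copy_number(ds(1 + z + 1), cal, "M"),
                 call_copy_number(ds(1 + z), cal, "M") / 2)
})

test_that("efficiency-corrected calling matches uncorrected at E = 1", {
  cal <- calibrator(c(M = 2L), c(M = 1.0), mean_ref_cq = c(M = 23.0))
  ds <- structure(list(delta_cq = 1.37, mean_delta_cq = 1.37,
                       mean_ref_cq = 22.4, mean_target_cq = 23.77,
                       n_used = 4L, zero_call = FALSE, flags = character(0)),
                  class = "delta_cq_set")
  plain <- call_copy_number(ds, cal, "M")
  same <- call_copy_number(ds, cal, "M",
                           efficiency = c(M = 1, STAT6 = 1),
                           reference_marker = "STAT6")
  expect_identical(plain, same)
  corrected <- call_copy_number(ds, cal, "M",
                                efficiency = c(M = 0.9, STAT6 = 0.95),
                                reference_marker = "STAT6")
  expect_false(identical(plain, corrected))
  # hand-computed Pfaffl form
  d_t <- (23.0 + 1.0) - 23.77
  d_r <- 23.0 - 22.4
  expect_equal(corrected, 2 * 1.9^d_t / 1.95^d_r)
})

test_that("predicted copy number rounds to nearest, ties away from zero", {
  expect_equal(round_copy_number(1.94), 2L)
  expect_equal(round_copy_number(0.12), 0L)
  expect_equal(round_copy_number(2.5), 3L)
  expect_equal(round_copy_number(c(0.5, 1.49, 3.51)), c(1L, 1L, 4L))
  expect_error(round_copy_number(-0.1))
})

test_that("cohort calibration anchors the largest delta-Cq cluster", {
  set.seed(101)
  x <- c(rnorm(70, 0.0, 0.03), rnorm(25, 1.0, 0.03), rnorm(5, -0.58, 0.03))
  cc <- cohort_calibrate(x, expected_modal_cn = 2)
  expect_equal(cc$copy_number, 2)
  expect_equal(cc$mean_delta_cq, 0.0, tolerance = 0.02)
  expect_length(cc$flags, 0L)

  expect_warning(one <- cohort_calibrate(0.4, 2), "recommended")
  expect_equal(one$mean_delta_cq, 0.4)

  # even 50/50 split: tie goes to the lower-delta-Cq (higher copy) cluster
  xx <- rep(c(0, 1), each = 40)
  tie <- cohort_calibrate(xx, expected_modal_cn = 2)
  expect_true("AMBIGUOUS_MODE" %in% tie$flags)
  expect_equal(tie$mean_delta_cq, 0)

  expect_error(cohort_calibrate(numeric(0), 2), "no delta-Cq")
})

test_that("cluster statistics report mean, n-1 SD and size per copy number", {
  calls <- data.frame(marker_id = "M",
                      calculated_cn = c(1.0, 1.1, 0.9, 2.0, 2.1, 1.9, 3.0),
                      predicted_cn = c(1L, 1L, 1L, 2L, 2L, 2L, 3L))
  cs <- cluster_stats(calls)
  expect_equal(nrow(cs), 3L)
  expect_equal(cs$mean[cs$copy_number == 1], 1.0)
  expect_equal(cs$sd[cs$copy_number == 2], sd(c(2.0, 2.1, 1.9)))
  expect_true(is.na(cs$sd[cs$copy_number == 3]))

  same <- data.frame(marker_id = "M", calculated_cn = rep(2, 5),
                     predicted_cn = rep(2L, 5))
  expect_equal(cluster_stats(same)$sd, 0)
})

test_that("confidence and z-score behave at the cluster mean and between clusters", {
  m <- confidence_metrics(2.0, 2L, cluster_mean = 2.0, cluster_sd = 0.1)
  expect_equal(m$z_score, 0)
  m2 <- confidence_metrics(2.2, 2L, cluster_mean = 2.0, cluster_sd = 0.1)
  expect_equal(m2$z_score, 2)
  # midway between well-separated adjacent clusters: posterior about half
  m3 <- confidence_metrics(1.5, 2L, cluster_mean = 2.0, cluster_sd = 0.1,
                           pooled_sd = 0.1)
  expect_equal(m3$confidence, 0.5, tolerance = 1e-6)
  m4 <- confidence_metrics(2.05, 2L, cluster_mean = 2.0, cluster_sd = 0,
                           pooled_sd = 0)
  expect_true(is.infinite(m4$z_score))
  expect_true("SD_ZERO" %in% m4$flags)
})

test_that("discrimination thresholds narrow with copy number", {
  expect_equal(discrimination_threshold(1, 6), 1 / 6)
  expect_equal(discrimination_threshold(1, 4), 0.25)
  expect_equal(discrimination_threshold(2, 6), log2(1.5) / 6)
  for (n in 1:6) for (k in c(4, 6))
    expect_equal(discrimination_threshold(n, k) * k, cn_separation(n))
  expect_true(all(diff(discrimination_threshold(1:6, 6)) < 0))
  expect_error(discrimination_threshold(0, 6))
  expect_error(discrimination_threshold(1, 5))
})

test_that("paired assays and sum rules flag discordance", {
  p <- kir_panel()
  calls <- data.frame(
    sample_id = "S1",
    marker_id = c("3DL1e4", "3DL1e9", "2DS4", "2DS4FL", "2DS4del"),
    predicted_cn = c(1L, 2L, 2L, 1L, 1L), stringsAsFactors = FALSE)
  fl <- paired_assay_check(calls, p)
  expect_true(all(c("3DL1e4", "3DL1e9") %in%
                  fl$marker_id[fl$flag == "PAIR_DISCORDANT"]))
  expect_false("RULE_VIOLATION" %in% fl$flag)   # 2 = 1 + 1 holds

  calls$predicted_cn <- c(2L, 2L, 2L, 2L, 1L)   # 2 != 2 + 1
  fl2 <- paired_assay_check(calls, p)
  expect_true("RULE_VIOLATION" %in% fl2$flag)
  expect_false("PAIR_DISCORDANT" %in% fl2$flag)
})

test_that("framework-gene rules allow consistent co-duplication", {
  ok <- c("3DL3" = 2, "3DP1" = 2, "2DL4" = 2, "3DL2" = 2,
          "3DL1" = 1, "3DS1" = 1)
  expect_equal(nrow(haplotype_rules_check(ok)), 0L)

  del <- ok; del["3DL3"] <- 1
  v <- haplotype_rules_check(del)
  expect_true("3DL3" %in% v$locus)

  dup <- c("3DL3" = 2, "3DP1" = 3, "2DL4" = 3, "3DL2" = 2,
           "3DL1" = 2, "3DS1" = 1)   # 3DL1/S1 total 3: consistent expansion
  expect_equal(nrow(haplotype_rules_check(dup)), 0L)

  bad <- dup; bad["2DL4"] <- 2
  expect_true("3DP1" %in% haplotype_rules_check(bad)$locus)
})

test_that("zero-noise simulate -> filter -> call -> round recovers 0..5 copies", {
  p <- mini_panel()
  sig <- matrix(0:5, ncol = 1)
  lib <- suppressWarnings(haplotype_library(
    paste0("h", 0:5), sig, "M", frequency = rep(1 / 6, 6)))
  truth <- structure(list(
    truth = data.frame(sample_id = paste0("cn", 0:5),
                       haplotype_1 = paste0("h", 0:5),
                       haplotype_2 = paste0("h", 0:5)),
    genotypes = matrix(0:5, ncol = 1,
                       dimnames = list(paste0("cn", 0:5), "M")),
    markers = "M", seed = 0), class = "truth_set")
  wells <- simulate_plate(truth, p, noise_model(sigma_delta_cq = 0,
                                                sigma_concentration = 0),
                          seed = 1)
  calls <- call_cohort(wells, p, calibrator_sample = "cn2",
                       calibrator_cn = c(M = 2L))
  got <- calls$predicted_cn[match(paste0("cn", 0:5), calls$sample_id)]
  expect_identical(got, 0:5)
  expect_equal(calls$calculated_cn[match(paste0("cn", 1:5),
                                         calls$sample_id)],
               1:5, tolerance = 1e-12)
})
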