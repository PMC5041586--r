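# Cohort-level calling pipeline: wells -> QC -> delta-delta-Cq calls ->
# cluster metrics -> cross-assay flags.

#' Call copy numbers for a cohort
#'
#' Runs the full calling pipeline on long-format Cq data: per sample x
#' marker replicate QC ([qc_filter()]), calibration against either a named
#' calibrator sample of known copy number or the cohort mode
#' ([cohort_calibrate()]), comparative-Cq quantification
#' ([call_copy_number()]), integer rounding, per-cluster dispersion and
#' per-sample confidence/z metrics, and the paired-assay and sum-rule
#' consistency checks.
#'
#' @param wells A `cq_data` data frame (from [read_cq_export()] or
#'   [simulate_plate()]).
#' @param panel The `qpcr_panel` describing the reactions.
#' @param calibrator_sample Sample id(s) of the control/calibrator
#'   sample(s) run on the plates. With several controls, each marker is
#'   calibrated from the first control carrying at least one copy there
#'   (no single sample carries every KIR gene).
#' @param calibrator_cn The calibrators' known copy numbers: a named
#'   integer vector (one calibrator) or a matrix with one row per
#'   calibrator sample (rownames = sample ids), columns = markers.
#' @param cohort_modes Named integer vector: expected modal copy number per
#'   marker, enabling cohort-mode calibration for markers not covered by a
#'   calibrator. Exactly one calibration source must cover each marker.
#' @param efficiency Optional named per-marker amplification efficiencies
#'   (include the reference assay); omitted = uncorrected calling.
#' @param qc_options List of overrides passed to [qc_filter()]
#'   (`ref_cq_max`, `zero_target_min`, `outlier_k`, `leave_one_out`).
#' @return A `copy_number_table` data frame: `sample_id`, `marker_id`,
#'   `calculated_cn`, `predicted_cn`, `confidence`, `z_score`, `qc_flags`
#'   (semicolon-joined), `n_replicates_used`. The cluster statistics are
#'   attached as attribute `"cluster_stats"`, the calibrator as
#'   `"calibrator"`.
#' @export
call_cohort <- function(wells, panel, calibrator_sample = NULL,
                        calibrator_cn = NULL, cohort_modes = NULL,
                        efficiency = NULL, qc_options = list()) {
  if (!is.null(calibrator_sample) && is.null(calibrator_cn))
    stop("calibrator_sample needs calibrator_cn (its known copy numbers)")
  if (is.null(calibrator_sample) && is.null(cohort_modes))
    stop("give either a calibrator sample or cohort_modes")
  if (!is.null(calibrator_sample)) {
    absent <- setdiff(calibrator_sample, wells$sample_id)
    if (length(absent) > 0L)
      stop("calibrator sample(s) not present in the data: ",
           paste(absent, collapse = ", "))
    if (is.null(dim(calibrator_cn))) {
      calibrator_cn <- matrix(calibrator_cn, nrow = 1L,
                              dimnames = list(calibrator_sample[1],
                                              names(calibrator_cn)))
    }
  }

  markers <- panel_target_markers(panel)
  ref_of <- character(0)
  for (rx in panel$reactions)
    for (m in rx$target_markers) ref_of[m] <- rx$reference_marker

  # replicate QC per sample x marker
  dsets <- list()
  for (g in split(wells, list(wells$sample_id, wells$reaction_id),
                  drop = TRUE)) {
    rx <- panel_reaction(panel, g$reaction_id[1])
    reps <- sort(unique(g$replicate_index))
    ref_cq <- g$cq[match(paste(reps, rx$reference_marker),
                         paste(g$replicate_index, g$marker_id))]
    for (m in rx$target_markers) {
      tgt_cq <- g$cq[match(paste(reps, m),
                           paste(g$replicate_index, g$marker_id))]
      dsets[[paste(g$sample_id[1], m, sep = "\r")]] <-
        do.call(qc_filter, c(list(target_cq = tgt_cq, ref_cq = ref_cq),
                             qc_options))
    }
  }
  samples <- unique(wells$sample_id)
  dset_of <- function(s, m) dsets[[paste(s, m, sep = "\r")]]

  # calibrator: explicit sample where covered, cohort mode elsewhere
  cal_dcq <- cal_ref <- stats::setNames(rep(NA_real_, length(markers)),
                                        markers)
  cal_cn <- stats::setNames(rep(NA_integer_, length(markers)), markers)
  cal_flags <- character(0)
  for (m in markers) {
    if (!is.null(calibrator_sample) && m %in% colnames(calibrator_cn)) {
      for (cs in intersect(calibrator_sample, rownames(calibrator_cn))) {
        ds <- dset_of(cs, m)
        if (!is.null(ds) && !ds$zero_call && !is.na(ds$mean_delta_cq) &&
            !is.na(calibrator_cn[cs, m]) && calibrator_cn[cs, m] >= 1) {
          cal_dcq[m] <- ds$mean_delta_cq
          cal_ref[m] <- ds$mean_ref_cq
          cal_cn[m] <- calibrator_cn[cs, m]
          break
        }
      }
      if (!is.na(cal_cn[m])) next
    }
    if (!is.null(cohort_modes) && m %in% names(cohort_modes) &&
        !is.na(cohort_modes[[m]])) {
      dcqs <- vapply(samples, function(s) {
        ds <- dset_of(s, m)
        if (is.null(ds)) NA_real_ else ds$mean_delta_cq
      }, numeric(1))
      if (all(is.na(dcqs))) next   # nobody amplifies: zero calls need no anchor
      cc <- cohort_calibrate(dcqs, cohort_modes[[m]])
      cal_dcq[m] <- cc$mean_delta_cq
      cal_cn[m] <- cc$copy_number
      cal_ref[m] <- mean(vapply(samples, function(s) {
        ds <- dset_of(s, m)
        if (is.null(ds)) NA_real_ else ds$mean_ref_cq
      }, numeric(1)), na.rm = TRUE)
      cal_flags <- union(cal_flags, cc$flags)
    }
  }
  cal <- calibrator(copy_numbers = cal_cn[!is.na(cal_cn)],
                    mean_delta_cq = cal_dcq[!is.na(cal_cn)],
                    mean_ref_cq = cal_ref[!is.na(cal_cn)],
                    sample_id = calibrator_sample %||% "COHORT_MODE",
                    flags = cal_flags)

  rows <- vector("list", length(samples) * length(markers))
  k <- 0L
  for (s in samples) for (m in markers) {
    ds <- dset_of(s, m)
    if (is.null(ds)) next
    k <- k + 1L
    flags <- ds$flags
    calc <- if (is.na(cal_cn[m]) && !ds$zero_call) {
      flags <- c(flags, "NO_CALIBRATOR")
      NA_real_
    } else {
      call_copy_number(ds, cal, m, efficiency = efficiency,
                       reference_marker = ref_of[[m]])
    }
    rows[[k]] <- data.frame(
      sample_id = s, marker_id = m, calculated_cn = calc,
      predicted_cn = if (is.na(calc)) NA_integer_ else round_copy_number(calc),
      confidence = NA_real_, z_score = NA_real_,
      qc_flags = paste(unique(flags), collapse = ";"),
      n_replicates_used = ds$n_used, stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, rows[seq_len(k)])

  # cluster dispersion and per-sample metrics
  cs <- cluster_stats(calls)
  pooled <- vapply(split(cs, cs$marker_id), function(g) {
    g <- g[!is.na(g$sd) & g$n >= 2L, , drop = FALSE]
    if (nrow(g) == 0L) return(NA_real_)
    sqrt(sum((g$n - 1L) * g$sd^2) / sum(g$n - 1L))
  }, numeric(1))
  for (i in seq_len(nrow(calls))) {
    if (is.na(calls$predicted_cn[i])) next
    ci <- cs[cs$marker_id == calls$marker_id[i] &
             cs$copy_number == calls$predicted_cn[i], ]
    met <- confidence_metrics(calls$calculated_cn[i], calls$predicted_cn[i],
                              cluster_mean = ci$mean[1],
                              cluster_sd = ci$sd[1],
                              pooled_sd = pooled[[calls$marker_id[i]]])
    calls$confidence[i] <- met$confidence
    calls$z_score[i] <- met$z_score
    if (length(met$flags) > 0L)
      calls$qc_flags[i] <- paste(unique(c(
        strsplit(calls$qc_flags[i], ";")[[1]], met$flags)), collapse = ";")
  }

  pf <- paired_assay_check(calls, panel)
  if (nrow(pf) > 0L) {
    for (i in seq_len(nrow(pf))) {
      j <- which(calls$sample_id == pf$sample_id[i] &
                 calls$marker_id == pf$marker_id[i])
      calls$qc_flags[j] <- vapply(calls$qc_flags[j], function(f)
        paste(unique(c(strsplit(f, ";")[[1]], pf$flag[i])), collapse = ";"),
        character(1))
    }
  }
  calls$qc_flags <- sub("^;", "", calls$qc_flags)
  attr(calls, "cluster_stats") <- cs
  attr(calls, "calibrator") <- cal
  class(calls) <- c("copy_number_table", "data.frame")
  calls
}

#' End-to-end synthetic run
#'
#' Simulates a cohort from a haplotype library, generates Cq plates, calls
#' copy numbers (cohort-mode calibration by default), projects the calls
#' onto the library loci and resolves haplotype pairs.
#'
#' @param n_samples Cohort size.
#' @param panel A `qpcr_panel` (default: bundled KIR panel).
#' @param library A `haplotype_library` (default: bundled library).
#' @param noise A [noise_model()].
#' @param seed Integer master seed.
#' @param calibrator_sample,calibrator_cn,cohort_modes See [call_cohort()].
#'   By default, control samples of known copy number built from the
#'   library ([control_samples()]) are plated alongside the cohort and used
#'   as calibrators, mirroring run practice.
#' @return List with `truth` (cohort + controls), `wells`, `calls`,
#'   `genotypes`, `blocked`, `resolutions` (controls excluded from
#'   haplotype resolution).
#' @export
run_end_to_end <- function(n_samples, panel = kir_panel(),
                           library = fixture_library(),
                           noise = noise_model(), seed = 1L,
                           calibrator_sample = NULL, calibrator_cn = NULL,
                           cohort_modes = NULL) {
  truth <- simulate_cohort(library, n_samples, seed = seed)
  if (is.null(calibrator_sample) && is.null(cohort_modes)) {
    ctrl <- control_samples(library)
    truth <- combine_truth(truth, ctrl)
    calibrator_sample <- ctrl$truth$sample_id
    calibrator_cn <- true_marker_copy_numbers(ctrl, panel)
  }
  wells <- simulate_plate(truth, panel, noise, seed = seed + 1L)
  calls <- call_cohort(wells, panel, calibrator_sample = calibrator_sample,
                       calibrator_cn = calibrator_cn,
                       cohort_modes = cohort_modes)
  proj <- project_genotypes(calls, panel, library$markers)
  test_ids <- setdiff(rownames(proj$genotypes), calibrator_sample)
  g <- proj$genotypes[test_ids, , drop = FALSE]
  ok <- !apply(is.na(g), 1L, any)
  res <- resolve_cohort(g[ok, , drop = FALSE], library)
  list(truth = truth, wells = wells, calls = calls,
       genotypes = proj$genotypes, blocked = proj$blocked,
       resolutions = res)
}
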