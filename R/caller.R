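# Comparative-Cq (delta-delta-Cq) copy-number calling with replicate QC,
# outlier filtering, zero-copy detection, confidence/z metrics and
# cluster-dispersion diagnostics.

#' QC flag vocabulary
#'
#' Flags attached to copy-number calls: `REF_CQ_HIGH` (replicate dropped,
#' reference Cq above threshold), `REF_FAIL` (replicate dropped, reference
#' did not amplify), `OUTLIER_REMOVED` (replicate dropped by the 4-SD rule),
#' `ZERO_CANDIDATE` (a non-amplifying replicate in a mixed set),
#' `ZERO_CALL` (marker absent: target failed while reference amplified),
#' `TOO_FEW_REPLICATES` (no usable replicate), `PAIR_DISCORDANT` (two assays
#' of the same gene disagree), `RULE_VIOLATION` (a sum or haplotype rule
#' failed), `AMBIGUOUS_MODE` (cohort calibration tie), `SD_ZERO`
#' (degenerate cluster dispersion), `CLUSTER_TOO_SMALL` (z-score undefined).
#' @export
CN_FLAGS <- c("REF_CQ_HIGH", "REF_FAIL", "OUTLIER_REMOVED", "ZERO_CANDIDATE",
              "ZERO_CALL", "TOO_FEW_REPLICATES", "PAIR_DISCORDANT",
              "RULE_VIOLATION", "AMBIGUOUS_MODE", "SD_ZERO",
              "CLUSTER_TOO_SMALL")

#' Per-well delta-Cq
#'
#' Within-well normalisation: target Cq minus reference Cq of the same well,
#' cancelling DNA-input differences. A non-amplifying target yields `NA` with
#' attribute `flag = "ZERO_CANDIDATE"` (candidate zero-copy); a
#' non-amplifying reference makes the well uninterpretable.
#'
#' @param well A `well_record` (see [as_well_records()]).
#' @param marker_id Target marker id present in the well's reaction.
#' @param reference_marker Reference marker id of the well's reaction.
#' @return Numeric delta-Cq (cycles), or flagged `NA`.
#' @export
delta_cq <- function(well, marker_id, reference_marker) {
  cq <- well$cq_by_marker
  if (!marker_id %in% names(cq)) stop("marker ", marker_id, " not in well")
  if (!reference_marker %in% names(cq))
    stop("reference ", reference_marker, " not in well")
  ref <- cq[[reference_marker]]
  if (is.na(ref)) stop("REF_FAIL: reference assay did not amplify in well ",
                       well$well)
  tgt <- cq[[marker_id]]
  if (is.na(tgt)) return(structure(NA_real_, flag = "ZERO_CANDIDATE"))
  tgt - ref
}

#' Replicate QC and delta-Cq aggregation
#'
#' Applies the run QC rules to one sample x marker replicate set:
#' replicates whose reference Cq exceeds `ref_cq_max` (or whose reference
#' failed) are removed; a marker whose target Cq exceeds `zero_target_min`
#' (or did not amplify) while the reference is sound is a zero-copy
#' candidate, and a majority of such replicates yields a `ZERO_CALL`;
#' among amplifying survivors, a replicate whose delta-Cq deviates more than
#' `outlier_k` standard deviations from the others is removed. The deviation
#' is evaluated leave-one-out by default (mean/SD of the remaining
#' replicates) because in a quadruplicate an extreme point inflates its own
#' inclusive SD and can never exceed about 1.7 inclusive SDs; set
#' `leave_one_out = FALSE` for the inclusive variant.
#'
#' @param target_cq,ref_cq Numeric vectors of equal length, one entry per
#'   replicate well; `NA` means no amplification.
#' @param ref_cq_max Reference Cq above which a replicate is discarded
#'   (default 32).
#' @param zero_target_min Target Cq above which the target is treated as
#'   non-amplifying (default 35).
#' @param outlier_k Outlier threshold in SD units (default 4).
#' @param leave_one_out Use leave-one-out statistics for the outlier rule.
#' @return A `delta_cq_set`: list with `delta_cq` (surviving replicate
#'   values), `ref_cq`, `mean_delta_cq`, `mean_ref_cq`, `mean_target_cq`,
#'   `n_used`, `zero_call`, `flags`.
#' @export
qc_filter <- function(target_cq, ref_cq, ref_cq_max = 32,
                      zero_target_min = 35, outlier_k = 4,
                      leave_one_out = TRUE) {
  stopifnot(length(target_cq) == length(ref_cq), length(ref_cq) >= 1L)
  flags <- character(0)

  ref_ok <- !is.na(ref_cq) & ref_cq <= ref_cq_max
  if (any(is.na(ref_cq))) flags <- c(flags, "REF_FAIL")
  if (any(!is.na(ref_cq) & ref_cq > ref_cq_max)) flags <- c(flags, "REF_CQ_HIGH")
  tgt <- target_cq[ref_ok]
  ref <- ref_cq[ref_ok]

  empty <- function(fl) structure(
    list(delta_cq = numeric(0), ref_cq = numeric(0),
         mean_delta_cq = NA_real_, mean_ref_cq = NA_real_,
         mean_target_cq = NA_real_, n_used = 0L, zero_call = FALSE,
         flags = unique(fl)),
    class = "delta_cq_set")
  if (length(tgt) == 0L) return(empty(c(flags, "TOO_FEW_REPLICATES")))

  is_zero <- is.na(tgt) | tgt > zero_target_min
  if (sum(is_zero) > sum(!is_zero)) {
    out <- empty(c(flags, "ZERO_CALL"))
    out$zero_call <- TRUE
    out$n_used <- sum(is_zero)
    out$mean_ref_cq <- mean(ref[is_zero])
    return(out)
  }
  if (any(is_zero)) flags <- c(flags, "ZERO_CANDIDATE")
  tgt <- tgt[!is_zero]
  ref <- ref[!is_zero]
  dcq <- tgt - ref

  # iterative worst-first outlier removal on the delta-Cq scale
  repeat {
    n <- length(dcq)
    if (n < 3L) break
    dev_ratio <- vapply(seq_len(n), function(i) {
      others <- dcq[-i]
      s <- stats::sd(others)
      d <- abs(dcq[i] - mean(others))
      if (leave_one_out) {
        if (s == 0) return(if (d > 0) Inf else 0)
        d / s
      } else {
        s_all <- stats::sd(dcq)
        d_all <- abs(dcq[i] - mean(dcq))
        if (s_all == 0) return(0)
        d_all / s_all
      }
    }, numeric(1))
    worst <- which.max(dev_ratio)
    if (dev_ratio[worst] > outlier_k) {
      dcq <- dcq[-worst]; tgt <- tgt[-worst]; ref <- ref[-worst]
      flags <- c(flags, "OUTLIER_REMOVED")
    } else break
  }

  structure(list(delta_cq = dcq, ref_cq = ref,
                 mean_delta_cq = mean(dcq), mean_ref_cq = mean(ref),
                 mean_target_cq = mean(tgt), n_used = length(dcq),
                 zero_call = FALSE, flags = unique(flags)),
            class = "delta_cq_set")
}

#' Construct a calibrator
#'
#' A calibrator is a sample of known copy number against which all others are
#' compared; its per-marker mean delta-Cq anchors the delta-delta-Cq scale.
#'
#' @param copy_numbers Named integer vector: marker id -> known copy number.
#' @param mean_delta_cq Named numeric vector: marker id -> calibrator mean
#'   delta-Cq (from its own QC-filtered replicates).
#' @param mean_ref_cq Optional named numeric: marker id -> calibrator mean
#'   reference Cq (required for efficiency-corrected calling).
#' @param sample_id Calibrator sample id, or `"COHORT_MODE"` for a
#'   cohort-derived calibrator.
#' @param flags Character vector of calibration flags.
#' @return A `calibrator` object.
#' @export
calibrator <- function(copy_numbers, mean_delta_cq, mean_ref_cq = NULL,
                       sample_id = NA_character_, flags = character(0)) {
  stopifnot(all(copy_numbers >= 0), !is.null(names(copy_numbers)))
  structure(list(sample_id = sample_id, copy_numbers = copy_numbers,
                 mean_delta_cq = mean_delta_cq, mean_ref_cq = mean_ref_cq,
                 flags = flags),
            class = "calibrator")
}

#' Calculated (real-valued) copy number by comparative Cq
#'
#' Without efficiency correction, the copy number is
#' `cal_cn * 2^(-ddcq)` with `ddcq = mean delta-Cq(sample) - mean
#' delta-Cq(calibrator)`: a sample one cycle later than a two-copy calibrator
#' carries one copy. With per-assay efficiencies the efficiency-corrected
#' ratio `(1+E_target)^dCq_t / (1+E_ref)^dCq_r` is used, where `dCq` is the
#' calibrator-minus-sample Cq difference of each assay. When every
#' efficiency equals 1 the corrected form reduces to (and is computed as)
#' the uncorrected one. A `ZERO_CALL` replicate set short-circuits to 0.
#'
#' @param dset A `delta_cq_set` from [qc_filter()].
#' @param cal A [calibrator()].
#' @param marker_id Marker being called.
#' @param efficiency Optional named numeric of per-marker amplification
#'   efficiencies in (0, 1.2] (1 = perfect doubling); must then also name
#'   the reference assay via `reference_marker`.
#' @param reference_marker Reference marker id (needed with `efficiency`).
#' @return Calculated copy number (nonnegative real), `NA` if no call.
#' @export
call_copy_number <- function(dset, cal, marker_id, efficiency = NULL,
                             reference_marker = NULL) {
  if (dset$zero_call) return(0)
  if (is.na(dset$mean_delta_cq)) return(NA_real_)
  if (!marker_id %in% names(cal$copy_numbers))
    stop("calibrator has no copy number for marker ", marker_id)
  if (!marker_id %in% names(cal$mean_delta_cq))
    stop("calibrator has no delta-Cq for marker ", marker_id)
  cal_cn <- cal$copy_numbers[[marker_id]]
  ddcq <- dset$mean_delta_cq - cal$mean_delta_cq[[marker_id]]

  if (!is.null(efficiency)) {
    stopifnot(all(efficiency > 0), all(efficiency <= 1.2))
    if (is.null(reference_marker))
      stop("efficiency correction needs the reference marker id")
    e_t <- efficiency[[marker_id]]
    e_r <- efficiency[[reference_marker]]
    if (e_t != 1 || e_r != 1) {
      if (is.null(cal$mean_ref_cq))
        stop("efficiency correction needs calibrator reference Cq")
      cal_tgt <- cal$mean_ref_cq[[marker_id]] + cal$mean_delta_cq[[marker_id]]
      d_t <- cal_tgt - dset$mean_target_cq
      d_r <- cal$mean_ref_cq[[marker_id]] - dset$mean_ref_cq
      return(cal_cn * 2^(log2(1 + e_t) * d_t - log2(1 + e_r) * d_r))
    }
  }
  cal_cn * 2^(-ddcq)
}

#' Round a calculated copy number to the predicted integer
#'
#' Round-to-nearest with ties away from zero (so 2.5 becomes 3); this is the
#' convention needed for calculated values to agree with integer truth sets,
#' and a ceiling mode is deliberately not offered.
#'
#' @param calculated Nonnegative numeric vector.
#' @return Nonnegative integer vector.
#' @export
round_copy_number <- function(calculated) {
  stopifnot(all(calculated >= 0, na.rm = TRUE))
  as.integer(floor(calculated + 0.5))
}

#' Cohort-mode calibration
#'
#' When no sample of known copy number is available, the cohort itself
#' calibrates: the per-sample mean delta-Cq values are clustered onto the
#' integer-copy lattice (delta-Cq spacing `log2` of the copy ratio) with a
#' k-means-style alternation, and the largest cluster is assigned the copy
#' number expected to be most frequent in the cohort. Ties are broken toward
#' the lower-delta-Cq (higher copy) cluster and flagged `AMBIGUOUS_MODE`.
#'
#' @param delta_cqs Numeric vector of per-sample mean delta-Cq for one marker.
#' @param expected_modal_cn The most frequent copy number expected (>= 1).
#' @param max_cn Highest lattice copy number considered (default 8).
#' @param min_samples Below this a warning is issued (default 10).
#' @return List with `mean_delta_cq` (modal-cluster mean), `copy_number`
#'   (`expected_modal_cn`), `cluster_sizes`, `flags`.
#' @export
cohort_calibrate <- function(delta_cqs, expected_modal_cn, max_cn = 8L,
                             min_samples = 10L) {
  x <- delta_cqs[!is.na(delta_cqs)]
  if (length(x) == 0L) stop("no delta-Cq values to calibrate on")
  stopifnot(expected_modal_cn >= 1)
  flags <- character(0)
  if (length(x) < min_samples) {
    warning("cohort calibration on ", length(x),
            " samples; >= ", min_samples, " recommended")
  }
  if (length(x) == 1L) {
    return(list(mean_delta_cq = x, copy_number = expected_modal_cn,
                cluster_sizes = stats::setNames(1L, expected_modal_cn),
                flags = "SINGLE_SAMPLE"))
  }
  # lattice: delta-Cq(c) = B - log2(c); init B at the densest point
  d <- stats::density(x)
  B <- d$x[which.max(d$y)] + log2(expected_modal_cn)
  cns <- seq_len(max_cn)
  assign_cn <- NULL
  for (iter in 1:50) {
    mu <- B - log2(cns)
    new_assign <- cns[apply(abs(outer(x, mu, "-")), 1L, which.min)]
    if (identical(new_assign, assign_cn)) break
    assign_cn <- new_assign
    B <- mean(x + log2(assign_cn))
  }
  sizes <- table(assign_cn)
  top <- sizes[sizes == max(sizes)]
  if (length(top) > 1L) flags <- c(flags, "AMBIGUOUS_MODE")
  # tie toward the higher copy number = lower delta-Cq cluster
  winner <- max(as.integer(names(top)))
  list(mean_delta_cq = mean(x[assign_cn == winner]),
       copy_number = expected_modal_cn,
       cluster_sizes = sizes, flags = flags)
}

#' Per-cluster dispersion statistics
#'
#' Groups calculated copy numbers by their assigned (predicted) integer and
#' reports mean, standard deviation (n-1 denominator) and size per cluster;
#' the per-cluster SD quantifies how cleanly adjacent copy numbers separate.
#'
#' @param calls A `copy_number_table` data frame (or any data frame with
#'   `marker_id`, `calculated_cn`, `predicted_cn`).
#' @return Data frame with `marker_id`, `copy_number`, `mean`, `sd`, `n`.
#' @export
cluster_stats <- function(calls) {
  ok <- !is.na(calls$predicted_cn) & !is.na(calls$calculated_cn)
  calls <- calls[ok, , drop = FALSE]
  if (nrow(calls) == 0L)
    return(data.frame(marker_id = character(0), copy_number = integer(0),
                      mean = numeric(0), sd = numeric(0), n = integer(0)))
  key <- interaction(calls$marker_id, calls$predicted_cn, drop = TRUE)
  agg <- lapply(split(calls, key), function(g)
    data.frame(marker_id = g$marker_id[1], copy_number = g$predicted_cn[1],
               mean = mean(g$calculated_cn),
               sd = if (nrow(g) > 1L) stats::sd(g$calculated_cn) else NA_real_,
               n = nrow(g), stringsAsFactors = FALSE))
  out <- do.call(rbind, agg)
  out <- out[order(out$marker_id, out$copy_number), ]
  rownames(out) <- NULL
  out
}

#' Confidence and absolute z-score for one call
#'
#' The z-score counts how many cluster standard deviations the sample's
#' calculated value lies from the mean of its assigned cluster. The
#' confidence is the posterior probability of the assigned integer under an
#' equal-prior Gaussian mixture with components centred at the integer copy
#' numbers `0..max_cn` and a common (pooled cluster) SD — a value midway
#' between two well-separated clusters scores about 0.5.
#'
#' @param calculated Calculated copy number of the sample.
#' @param assigned_cn Its predicted integer copy number.
#' @param cluster_mean,cluster_sd Mean and SD of the assigned cluster
#'   (`cluster_mean` defaults to `assigned_cn`).
#' @param pooled_sd SD used for the mixture (defaults to `cluster_sd`).
#' @param max_cn Highest mixture component (default `assigned_cn + 3`).
#' @return List with `confidence` in [0, 1], `z_score` (>= 0, possibly
#'   `Inf`), `flags`.
#' @export
confidence_metrics <- function(calculated, assigned_cn,
                               cluster_mean = assigned_cn, cluster_sd,
                               pooled_sd = cluster_sd,
                               max_cn = assigned_cn + 3L) {
  flags <- character(0)
  dev <- abs(calculated - cluster_mean)
  if (is.na(cluster_sd)) {
    z <- NA_real_
    flags <- c(flags, "CLUSTER_TOO_SMALL")
  } else if (cluster_sd == 0) {
    z <- if (dev > 0) Inf else 0
    if (dev > 0) flags <- c(flags, "SD_ZERO")
  } else z <- dev / cluster_sd

  if (is.na(pooled_sd) || pooled_sd == 0) {
    conf <- if (!is.na(calculated) &&
                round_copy_number(calculated) == assigned_cn) 1 else 0
    if (!is.na(pooled_sd) && pooled_sd == 0) flags <- unique(c(flags, "SD_ZERO"))
  } else {
    comp <- 0:max(max_cn, assigned_cn)
    w <- stats::dnorm(calculated, mean = comp, sd = pooled_sd)
    conf <- if (sum(w) == 0) 0 else w[match(assigned_cn, comp)] / sum(w)
  }
  list(confidence = conf, z_score = z, flags = flags)
}

#' Theoretical delta-delta-Cq separation between adjacent copy numbers
#'
#' At perfect efficiency the delta-delta-Cq gap between `n` and `n+1` copies
#' is `log2((n+1)/n)`: one full cycle between 1 and 2 copies, then narrowing
#' as copy number grows.
#'
#' @param cn_low Lower copy number (>= 1).
#' @return Separation in cycles.
#' @export
cn_separation <- function(cn_low) {
  stopifnot(all(cn_low >= 1))
  log2((cn_low + 1) / cn_low)
}

#' Fold change between two copy numbers
#' @param cn_from,cn_to Copy numbers (`cn_from` >= 1).
#' @return `cn_to / cn_from` (2 for 1 to 2 copies, 1.5 for 2 to 3).
#' @export
cn_fold_change <- function(cn_from, cn_to) {
  stopifnot(all(cn_from >= 1))
  cn_to / cn_from
}

#' Maximum cluster SD for reliable copy-number discrimination
#'
#' To separate adjacent clusters in more than 99.6% of samples, at least 6
#' standard deviations must fit inside the cluster gap (`k = 6`); for the
#' more-than-95% tier, 4 SDs (`k = 4`). Between 1 and 2 copies the gap is one
#' cycle, so the thresholds are 0.167 and 0.25 cycles; they shrink at higher
#' copy number as the gap narrows. Discrimination of 0 versus 1 copy is
#' qualitative (amplification versus none), not a delta-delta-Cq distance.
#'
#' @param cn_low Lower copy number of the adjacent pair (>= 1).
#' @param k SD multiples required inside the gap: 6 (>99.6% tier) or 4
#'   (>95% tier).
#' @return Maximal per-cluster SD in cycles: `log2((cn_low+1)/cn_low) / k`.
#' @export
discrimination_threshold <- function(cn_low, k) {
  stopifnot(all(cn_low >= 1), all(k %in% c(4, 6)))
  cn_separation(cn_low) / k
}

#' Cross-assay consistency checks
#'
#' Flags `PAIR_DISCORDANT` when two assays targeting different regions of
#' the same gene disagree in predicted copy number (the signature of allele
#' dropout by a rare polymorphism under one assay), and `RULE_VIOLATION`
#' when a declared sum rule fails (e.g. the whole-gene assay must equal the
#' full-length plus the deletion-variant assays).
#'
#' @param calls A `copy_number_table` data frame.
#' @param panel A `qpcr_panel` declaring `paired_assays` and `sum_rules`.
#' @return Data frame with `sample_id`, `marker_id`, `flag`, `detail`;
#'   zero rows when all checks pass.
#' @export
paired_assay_check <- function(calls, panel) {
  out <- list()
  note <- function(sample, markers, flag, detail)
    out[[length(out) + 1L]] <<- data.frame(
      sample_id = sample, marker_id = markers, flag = flag, detail = detail,
      stringsAsFactors = FALSE)
  cn_of <- function(g, marker) {
    i <- match(marker, g$marker_id)
    if (is.na(i)) NA_integer_ else g$predicted_cn[i]
  }
  for (g in split(calls, calls$sample_id)) {
    s <- g$sample_id[1]
    for (p in panel$paired_assays) {
      a <- cn_of(g, p[1]); b <- cn_of(g, p[2])
      if (!is.na(a) && !is.na(b) && a != b)
        note(s, p, "PAIR_DISCORDANT",
             sprintf("%s=%d vs %s=%d", p[1], a, p[2], b))
    }
    for (total in names(panel$sum_rules)) {
      comp <- panel$sum_rules[[total]]
      tot <- cn_of(g, total)
      parts <- vapply(comp, function(m) cn_of(g, m), integer(1))
      if (!is.na(tot) && !anyNA(parts) && tot != sum(parts))
        note(s, c(total, comp), "RULE_VIOLATION",
             sprintf("%s=%d but %s sum to %d", total, tot,
                     paste(comp, collapse = "+"), sum(parts)))
    }
  }
  if (length(out) == 0L)
    data.frame(sample_id = character(0), marker_id = character(0),
               flag = character(0), detail = character(0),
               stringsAsFactors = FALSE)
  else do.call(rbind, out)
}

#' Load the default KIR haplotype consistency rules
#'
#' Framework genes expected at two copies, and co-duplication groups whose
#' members rise and fall together on expanded or contracted haplotypes. The
#' defaults ship as a YAML file and are fully user-overridable.
#'
#' @param path Optional path to a rules YAML; defaults to the bundled file.
#' @return List with `framework`, `framework_copies`, `locus_totals`,
#'   `coduplication_groups`.
#' @export
load_rules <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "kir_rules.yaml", package = "kircn",
                        mustWork = TRUE)
  cfg <- yaml::read_yaml(path)
  list(framework = unlist(cfg$framework),
       framework_copies = cfg$framework_copies %||% 2L,
       locus_totals = lapply(cfg$locus_totals %||% list(), unlist),
       coduplication_groups = lapply(cfg$coduplication_groups %||% list(),
                                     unlist))
}

#' Check a genotype against haplotype consistency rules
#'
#' A framework gene away from its expected two copies is flagged unless it
#' sits in a co-duplication group whose members all carry the same total
#' (a consistent expanded or contracted haplotype rather than an assay
#' artefact).
#'
#' @param genotype Named integer vector: locus -> total copy number. Locus
#'   totals defined in the rules (e.g. `3DL1/S1` = 3DL1 + 3DS1) are computed
#'   from their components.
#' @param rules Rules list from [load_rules()] (default: bundled rules).
#' @return Data frame with `rule`, `locus`, `message`; zero rows if clean.
#' @export
haplotype_rules_check <- function(genotype, rules = load_rules()) {
  viol <- list()
  flag <- function(rule, locus, message)
    viol[[length(viol) + 1L]] <<- data.frame(rule = rule, locus = locus,
                                             message = message,
                                             stringsAsFactors = FALSE)
  value_of <- function(locus) {
    if (locus %in% names(genotype)) return(genotype[[locus]])
    comp <- rules$locus_totals[[locus]]
    if (!is.null(comp) && all(comp %in% names(genotype)))
      return(sum(genotype[comp]))
    NA_integer_
  }
  group_consistent <- function(locus) {
    for (grp in rules$coduplication_groups) {
      if (!locus %in% grp) next
      vals <- vapply(grp, value_of, numeric(1))
      if (!anyNA(vals) && length(unique(vals)) == 1L) return(TRUE)
    }
    FALSE
  }
  for (g in rules$framework) {
    v <- value_of(g)
    if (is.na(v) || v == rules$framework_copies) next
    if (!group_consistent(g))
      flag("framework", g,
           sprintf("framework gene %s has %d copies (expected %d)",
                   g, v, rules$framework_copies))
  }
  if (length(viol) == 0L)
    data.frame(rule = character(0), locus = character(0),
               message = character(0), stringsAsFactors = FALSE)
  else do.call(rbind, viol)
}
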