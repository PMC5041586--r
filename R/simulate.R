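# Synthetic data: haplotype-structured genotypes and multiplex qPCR Cq
# plates, so the whole calling + haplotype stack runs end-to-end with no
# instrument data.

#' Noise model for simulated Cq plates
#'
#' Noise is Gaussian on the Cq scale. Per-channel noise has SD
#' `sigma_delta_cq / sqrt(2)` so that the within-well delta-Cq has SD
#' `sigma_delta_cq`. A per-sample log2 concentration offset shifts every Cq
#' of that sample equally (it cancels in delta-Cq — the rationale for
#' running target and reference in the same well). A zero-copy target does
#' not amplify (`NA`), or amplifies late (Cq 38-42) with
#' `leaky_zero = TRUE` to exercise the late-Cq zero-call rule. Dropout
#' events model a rare polymorphism under one assay: the affected assay
#' sees one copy fewer than the truth (a more-than-10-cycle shift when the
#' last copy is lost).
#'
#' @param sigma_delta_cq SD of the per-replicate delta-Cq (cycles;
#'   default 0.15, inside the tightest discrimination tier).
#' @param sigma_concentration SD of the per-sample log2 DNA concentration
#'   offset (cycles; default 0.5, about +/-40% input variation).
#' @param efficiency Optional named per-marker amplification efficiencies
#'   (default: 1 everywhere, perfect doubling).
#' @param base_cq Optional named per-marker baseline Cq at the reference
#'   copy number (default 24 for targets, 23 for the reference assay); must
#'   lie in (10, 35).
#' @param dropout_events Data frame with columns `sample_id`, `marker_id`:
#'   assays to hit with allele dropout.
#' @param leaky_zero Simulate zero-copy targets as late Cq instead of `NA`.
#' @return A `noise_model` list.
#' @export
noise_model <- function(sigma_delta_cq = 0.15, sigma_concentration = 0.5,
                        efficiency = NULL, base_cq = NULL,
                        dropout_events = NULL, leaky_zero = FALSE) {
  stopifnot(sigma_delta_cq >= 0, sigma_concentration >= 0)
  if (!is.null(base_cq)) stopifnot(all(base_cq > 10), all(base_cq < 35))
  structure(list(sigma_delta_cq = sigma_delta_cq,
                 sigma_concentration = sigma_concentration,
                 efficiency = efficiency, base_cq = base_cq,
                 dropout_events = dropout_events,
                 leaky_zero = isTRUE(leaky_zero)),
            class = "noise_model")
}

#' The bundled gene-content haplotype library
#'
#' Synthetic signatures following common A/B haplotype gene-content
#' patterns, one extended haplotype (duplicated 3DP1, 2DL4 and 3DL1/S1
#' locus) and one contracted haplotype (deletion from 3DL1 to 3DL2), with
#' placeholder frequencies. Aligned with the bundled KIR panel's loci.
#'
#' @return A `haplotype_library`.
#' @export
fixture_library <- function() {
  read_haplotype_library(system.file("extdata", "kir_haplotype_library.csv",
                                     package = "kircn", mustWork = TRUE))
}

#' Draw a cohort of genotypes from a haplotype library
#'
#' Each sample draws two haplotypes i.i.d. with probability proportional to
#' library frequency; the genotype is the element-wise sum of the two
#' signatures.
#'
#' @param library A `haplotype_library` with positive total frequency.
#' @param n_samples Number of samples.
#' @param seed Integer seed; the draw is reproducible given the seed.
#' @param prefix Sample-id prefix (default `"S"`).
#' @return A `truth_set`: list with `truth` (data frame `sample_id`,
#'   `haplotype_1`, `haplotype_2`), `genotypes` (integer matrix samples x
#'   library markers) and `markers`.
#' @export
simulate_cohort <- function(library, n_samples, seed = 1L, prefix = "S") {
  if (length(library) == 0L) stop("empty haplotype library")
  if (sum(library$frequency) <= 0) stop("library frequencies sum to zero")
  set.seed(seed)
  n <- length(library)
  i1 <- sample.int(n, n_samples, replace = TRUE, prob = library$frequency)
  i2 <- sample.int(n, n_samples, replace = TRUE, prob = library$frequency)
  ids <- sprintf("%s%04d", prefix, seq_len(n_samples))
  g <- library$signatures[i1, , drop = FALSE] +
       library$signatures[i2, , drop = FALSE]
  rownames(g) <- ids
  structure(list(truth = data.frame(sample_id = ids,
                                    haplotype_1 = library$haplotype_id[i1],
                                    haplotype_2 = library$haplotype_id[i2],
                                    stringsAsFactors = FALSE),
                 genotypes = g, markers = library$markers, seed = seed),
            class = "truth_set")
}

map_locus_matrix <- function(mat, loci, panel) {
  genes <- stats::setNames(panel_marker_field(panel, "gene"),
                           panel_marker_ids(panel))
  cols <- lapply(panel_target_markers(panel), function(m) {
    if (m %in% loci) return(mat[, m])
    comp <- panel$sum_rules[[m]]
    if (!is.null(comp) && all(comp %in% loci))
      return(rowSums(mat[, comp, drop = FALSE]))
    short <- sub("^KIR", "", genes[[m]])
    if (short %in% loci) return(mat[, short])
    stop("panel marker ", m, " maps to no truth marker")
  })
  out <- do.call(cbind, cols)
  dimnames(out) <- list(rownames(mat), panel_target_markers(panel))
  out
}

#' Per-assay true copy numbers implied by a truth set
#'
#' Maps each panel target marker to the truth markers: directly by name,
#' through the panel's sum rules (a whole-gene assay is the sum of its
#' variant assays), or through the gene name (all region assays of a gene
#' see the same copies).
#'
#' @param truth A `truth_set`.
#' @param panel A `qpcr_panel`.
#' @return Integer matrix samples x panel target markers.
#' @export
true_marker_copy_numbers <- function(truth, panel) {
  map_locus_matrix(truth$genotypes, truth$markers, panel)
}

#' Expected modal copy number per assay under a haplotype library
#'
#' The most frequent genotype copy number expected per marker when two
#' haplotypes are drawn i.i.d. by library frequency — the anchor that
#' cohort-mode calibration assigns to its largest delta-Cq cluster. Since
#' zero-copy samples never produce a delta-Cq, the mode is taken over
#' carriers (copy number >= 1); markers nobody carries return `NA`.
#'
#' @param library A `haplotype_library`.
#' @param panel A `qpcr_panel`.
#' @return Named integer vector over panel target markers.
#' @export
expected_modal_cn <- function(library, panel) {
  H <- map_locus_matrix(library$signatures, library$markers, panel)
  p <- library$frequency / sum(library$frequency)
  vapply(colnames(H), function(m) {
    v <- H[, m]
    gmax <- 2L * max(v)
    prob <- numeric(gmax + 1L)
    for (i in seq_along(v)) for (j in seq_along(v))
      prob[v[i] + v[j] + 1L] <- prob[v[i] + v[j] + 1L] + p[i] * p[j]
    carrier <- prob[-1L]
    if (sum(carrier) == 0) return(NA_integer_)
    as.integer(which.max(carrier))
  }, integer(1))
}

#' Control samples of known copy number
#'
#' Builds control genotypes by pairing library haplotypes so that, jointly,
#' the controls carry at least one copy of every locus the library
#' describes — the role of the known-copy-number controls included in every
#' run, and the calibrators for [call_cohort()]. Haplotypes are paired
#' greedily by descending frequency until every locus is covered.
#'
#' @param library A `haplotype_library`.
#' @param prefix Control sample-id prefix (default `"CTRL"`).
#' @return A `truth_set` covering the controls.
#' @export
control_samples <- function(library, prefix = "CTRL") {
  ord <- order(-library$frequency)
  uncovered <- colSums(library$signatures) > 0
  pairs <- list()
  covered <- rep(FALSE, length(library$markers))
  i <- 1L
  while (any(uncovered & !covered) && i < length(ord)) {
    h1 <- ord[i]; h2 <- ord[i + 1L]
    pairs[[length(pairs) + 1L]] <- c(h1, h2)
    covered <- covered | (library$signatures[h1, ] +
                          library$signatures[h2, ] > 0)
    i <- i + 2L
  }
  if (length(pairs) == 0L) pairs <- list(c(ord[1], ord[1]))
  ids <- sprintf("%s%d", prefix, seq_along(pairs))
  i1 <- vapply(pairs, `[`, integer(1), 1L)
  i2 <- vapply(pairs, `[`, integer(1), 2L)
  g <- library$signatures[i1, , drop = FALSE] +
       library$signatures[i2, , drop = FALSE]
  rownames(g) <- ids
  structure(list(truth = data.frame(sample_id = ids,
                                    haplotype_1 = library$haplotype_id[i1],
                                    haplotype_2 = library$haplotype_id[i2],
                                    stringsAsFactors = FALSE),
                 genotypes = g, markers = library$markers, seed = NA),
            class = "truth_set")
}

#' Combine truth sets (e.g. cohort plus controls)
#' @param ... `truth_set` objects over the same markers.
#' @return A single `truth_set`.
#' @export
combine_truth <- function(...) {
  ts <- list(...)
  structure(list(truth = do.call(rbind, lapply(ts, `[[`, "truth")),
                 genotypes = do.call(rbind, lapply(ts, `[[`, "genotypes")),
                 markers = ts[[1]]$markers, seed = ts[[1]]$seed),
            class = "truth_set")
}

#' Simulate multiplex qPCR plates for a cohort
#'
#' Generates quadruplicate wells per sample x reaction following the plate
#' planner's layout. Within each well, the reference Cq is the reference
#' baseline minus the sample's concentration offset plus channel noise, and
#' each target Cq additionally shifts by `-log(cn / reference_cn) /
#' log(1 + E)` — one cycle earlier per copy doubling at perfect efficiency.
#' Zero-copy targets do not amplify. Dropout events reduce the affected
#' assay's seen copies by one.
#'
#' @param truth A `truth_set` from [simulate_cohort()].
#' @param panel A `qpcr_panel`.
#' @param noise A [noise_model()].
#' @param seed Integer seed for the noise draws.
#' @return A `cq_data` data frame (same dialect [read_cq_export()] reads).
#' @export
simulate_plate <- function(truth, panel, noise = noise_model(), seed = 1L) {
  set.seed(seed)
  samples <- truth$truth$sample_id
  cn_mat <- true_marker_copy_numbers(truth, panel)
  ref_cn <- panel$reference_copy_number

  base <- stats::setNames(rep(24, length(panel$markers)),
                          panel_marker_ids(panel))
  base[panel_marker_ids(panel)[panel_marker_field(panel, "is_reference")]] <- 23
  if (!is.null(noise$base_cq)) base[names(noise$base_cq)] <- noise$base_cq
  eff <- stats::setNames(rep(1, length(panel$markers)),
                         panel_marker_ids(panel))
  if (!is.null(noise$efficiency)) eff[names(noise$efficiency)] <- noise$efficiency

  conc <- stats::setNames(stats::rnorm(length(samples), 0,
                                       noise$sigma_concentration), samples)

  layout <- plate_layout_table(plan_plates(panel, samples))
  rx_markers <- stats::setNames(lapply(panel$reactions, function(rx)
    c(rx$target_markers, rx$reference_marker)),
    vapply(panel$reactions, `[[`, character(1), "reaction_id"))
  n_mk <- lengths(rx_markers)[layout$reaction]
  long <- data.frame(
    plate = rep(layout$plate, n_mk), well = rep(layout$well, n_mk),
    sample_id = rep(layout$sample, n_mk),
    reaction_id = rep(layout$reaction, n_mk),
    replicate_index = rep(layout$replicate, n_mk),
    marker_id = unlist(rx_markers[layout$reaction], use.names = FALSE),
    stringsAsFactors = FALSE)

  is_ref <- stats::setNames(panel_marker_field(panel, "is_reference"),
                            panel_marker_ids(panel))[long$marker_id]
  cn <- rep(ref_cn, nrow(long))
  cn[!is_ref] <- cn_mat[cbind(long$sample_id[!is_ref],
                              long$marker_id[!is_ref])]
  if (!is.null(noise$dropout_events) && nrow(noise$dropout_events) > 0L) {
    hit <- paste(long$sample_id, long$marker_id) %in%
      paste(noise$dropout_events$sample_id, noise$dropout_events$marker_id)
    cn[hit] <- pmax(cn[hit] - 1L, 0L)
  }

  eps <- stats::rnorm(nrow(long), 0, noise$sigma_delta_cq / sqrt(2))
  cq <- base[long$marker_id] - conc[long$sample_id] -
    log(pmax(cn, 1L) / ref_cn) / log(1 + eff[long$marker_id]) + eps
  zero <- cn == 0L
  cq[zero] <- if (noise$leaky_zero)
    stats::runif(sum(zero), 38, 42) else NA_real_
  long$cq <- unname(cq)
  class(long) <- c("cq_data", "data.frame")
  long
}
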