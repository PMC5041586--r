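# Reading instrument-style Cq exports and haplotype libraries; writing
# copy-number tables and the three haplotype result files.
#
# Cq data travel as a long data frame of class "cq_data" with columns
# plate, well, sample_id, reaction_id, replicate_index, marker_id, cq
# (NA = no amplification). One CSV dialect is supported: comma-separated,
# dot decimal, UTF-8, header plate,well,sample,reaction,marker,cq with an
# optional replicate column.

#' Read an instrument-style Cq export
#'
#' Expects a CSV with header `plate,well,sample,reaction,marker,cq`
#' (an optional `replicate` column is honoured; otherwise replicate indices
#' are assigned by well order within each sample x reaction). The marker
#' column may carry either marker ids or channel names, which are resolved
#' through the named reaction of the panel. Blank, `"-"`, `">40"` or
#' numeric Cq above `no_amp_cq` cells become no-amplification (`NA`).
#'
#' @param path CSV path.
#' @param panel A `qpcr_panel` used to resolve reactions and channels.
#' @param no_amp_cq Cq above which a reading counts as no amplification
#'   (default 40).
#' @return A `cq_data` data frame.
#' @export
read_cq_export <- function(path, panel, no_amp_cq = 40) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("plate", "well", "sample", "reaction", "marker", "cq")
  if (!all(need %in% names(raw)))
    stop("Cq export must have columns: ", paste(need, collapse = ", "))

  rx_ids <- vapply(panel$reactions, `[[`, character(1), "reaction_id")
  bad_rx <- setdiff(unique(raw$reaction), rx_ids)
  if (length(bad_rx) > 0L)
    stop("unknown reaction(s) in export: ", paste(bad_rx, collapse = ", "))

  ids <- panel_marker_ids(panel)
  marker <- raw$marker
  for (i in which(!marker %in% ids)) {
    rx <- panel_reaction(panel, raw$reaction[i])
    mk <- c(rx$target_markers, rx$reference_marker)
    ch <- vapply(mk, function(m) panel_marker(panel, m)$channel, character(1))
    j <- match(raw$marker[i], ch)
    if (is.na(j))
      stop("row ", i, ": '", raw$marker[i], "' is neither a marker nor a ",
           "channel of reaction ", raw$reaction[i])
    marker[i] <- mk[j]
  }
  allowed <- stats::setNames(lapply(panel$reactions, function(rx)
    c(rx$target_markers, rx$reference_marker)), rx_ids)
  ok <- mapply(function(m, r) m %in% allowed[[r]], marker, raw$reaction)
  if (!all(ok)) {
    i <- which(!ok)[1]
    stop("row ", i, ": marker ", marker[i], " is not part of reaction ",
         raw$reaction[i])
  }

  cq_chr <- trimws(raw$cq)
  no_amp <- cq_chr %in% c("", "-", "NA") | grepl("^>", cq_chr)
  cq <- suppressWarnings(as.numeric(cq_chr))
  cq[no_amp] <- NA_real_
  if (any(!no_amp & is.na(cq)))
    stop("unparseable Cq value(s), e.g. '",
         cq_chr[which(!no_amp & is.na(cq))[1]], "'")
  cq[!is.na(cq) & cq > no_amp_cq] <- NA_real_
  if (any(!is.na(cq) & cq <= 0)) stop("Cq values must be positive")

  df <- data.frame(plate = raw$plate, well = raw$well,
                   sample_id = raw$sample, reaction_id = raw$reaction,
                   replicate_index = NA_integer_, marker_id = marker,
                   cq = cq, stringsAsFactors = FALSE)
  key <- paste(df$plate, df$well, df$marker_id)
  if (anyDuplicated(key))
    stop("duplicate (well, marker) entries, e.g. ", key[duplicated(key)][1])

  if ("replicate" %in% names(raw)) {
    df$replicate_index <- as.integer(raw$replicate)
  } else {
    for (grp in split(seq_len(nrow(df)),
                      paste(df$sample_id, df$reaction_id, df$marker_id))) {
      ord <- order(df$plate[grp], df$well[grp])
      df$replicate_index[grp[ord]] <- seq_along(grp)
    }
  }
  class(df) <- c("cq_data", "data.frame")
  df
}

#' Write Cq data in the export CSV dialect
#' @param cq_data A `cq_data` data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cq_export <- function(cq_data, path) {
  out <- data.frame(plate = cq_data$plate, well = cq_data$well,
                    sample = cq_data$sample_id,
                    reaction = cq_data$reaction_id,
                    replicate = cq_data$replicate_index,
                    marker = cq_data$marker_id,
                    # 17 significant digits: doubles survive the round trip
                    cq = ifelse(is.na(cq_data$cq), "",
                                sprintf("%.17g", cq_data$cq)),
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Well-record view of Cq data
#'
#' Regroups long Cq data into one record per well, each holding the per-marker
#' Cq map of its multiplex reaction (`NA` = no amplification).
#'
#' @param cq_data A `cq_data` data frame.
#' @return List of `well_record` objects with fields `plate_id`, `well`,
#'   `sample_id`, `reaction_id`, `replicate_index`, `cq_by_marker`.
#' @export
as_well_records <- function(cq_data) {
  lapply(split(cq_data, paste(cq_data$plate, cq_data$well)), function(g)
    structure(list(plate_id = g$plate[1], well = g$well[1],
                   sample_id = g$sample_id[1], reaction_id = g$reaction_id[1],
                   replicate_index = g$replicate_index[1],
                   cq_by_marker = stats::setNames(g$cq, g$marker_id)),
              class = "well_record"))
}

#' Read a haplotype library CSV
#'
#' Columns: `haplotype_id`, `signature` (per-marker copy counts, either a
#' plain digit string such as `10110...` or dash-delimited such as
#' `1-0-1-1-0`), `count`, `frequency`, `cen_motif`, `tel_motif`. The marker
#' order either is supplied via `marker_order` or read from a leading
#' comment line `# markers: a,b,c`. Frequencies are not silently
#' normalised; if they do not sum to 1 a warning is issued.
#'
#' @param path CSV path.
#' @param marker_order Character vector of marker names, or `NULL` to read
#'   the file's `# markers:` header line.
#' @return A `haplotype_library` (see [haplotype_library()]).
#' @export
read_haplotype_library <- function(path, marker_order = NULL) {
  lines <- readLines(path)
  hdr <- grep("^#\\s*markers\\s*:", lines, value = TRUE)
  if (is.null(marker_order)) {
    if (length(hdr) == 0L)
      stop("no marker_order given and no '# markers:' header in ", path)
    marker_order <- trimws(strsplit(sub("^#\\s*markers\\s*:", "", hdr[1]),
                                    ",")[[1]])
  }
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        stringsAsFactors = FALSE,
                        colClasses = "character")
  if (nrow(df) == 0L)
    return(haplotype_library(character(0),
                             matrix(0L, 0, length(marker_order)),
                             marker_order, integer(0), numeric(0),
                             character(0), character(0)))
  need <- c("haplotype_id", "signature", "count", "frequency")
  if (!all(need %in% names(df)))
    stop("haplotype library must have columns: ", paste(need, collapse = ", "))
  sig <- lapply(df$signature, parse_signature)
  len <- vapply(sig, length, integer(1))
  if (any(len != length(marker_order)))
    stop("signature length ", len[len != length(marker_order)][1],
         " does not match the ", length(marker_order), " library markers")
  sigm <- do.call(rbind, sig)
  haplotype_library(df$haplotype_id, sigm, marker_order,
                    count = as.integer(df$count),
                    frequency = as.numeric(df$frequency),
                    cen_motif = df$cen_motif %||% rep("", nrow(df)),
                    tel_motif = df$tel_motif %||% rep("", nrow(df)))
}

parse_signature <- function(s) {
  s <- trimws(s)
  v <- if (grepl("-", s)) as.integer(strsplit(s, "-")[[1]])
       else as.integer(strsplit(s, "")[[1]])
  if (anyNA(v)) stop("unparseable signature: ", s)
  if (any(v < 0)) stop("negative copy count in signature: ", s)
  v
}

#' Write a haplotype library CSV
#' @param library A `haplotype_library`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_haplotype_library <- function(library, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# markers: ", paste(library$markers, collapse = ",")),
             con)
  df <- data.frame(haplotype_id = library$haplotype_id,
                   signature = apply(library$signatures, 1L,
                                     paste, collapse = "-"),
                   count = library$count, frequency = library$frequency,
                   cen_motif = library$cen_motif,
                   tel_motif = library$tel_motif, stringsAsFactors = FALSE)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Write a copy-number table CSV
#' @param table A `copy_number_table` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_copy_number_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a copy-number table CSV
#' @param path CSV written by [write_copy_number_table()].
#' @return A `copy_number_table` data frame.
#' @export
read_copy_number_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$qc_flags <- ifelse(is.na(df$qc_flags), "", df$qc_flags)
  class(df) <- c("copy_number_table", "data.frame")
  df
}

#' Write the three haplotype result files
#'
#' File 1 (`haplotype_pairs.csv`) lists every candidate pair per sample with
#' each haplotype's frequency and the combined frequency; file 2
#' (`best_pairs.csv`) keeps only the pair(s) with the highest combined
#' frequency per resolved sample; file 3 (`unresolved_log.csv`) lists the
#' samples for which no pair could be assigned, with their possible single
#' haplotypes. Every sample lands in exactly one of files 2 and 3.
#'
#' @param results List of resolution records from [resolve_sample()] /
#'   [resolve_cohort()].
#' @param dir Output directory (created if missing).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_haplotype_outputs <- function(results, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pair_cols <- data.frame(sample_id = character(0),
                          haplotype_1 = character(0),
                          haplotype_2 = character(0),
                          frequency_1 = numeric(0), frequency_2 = numeric(0),
                          combined_frequency = numeric(0),
                          stringsAsFactors = FALSE)
  all_pairs <- pair_cols
  best_pairs <- pair_cols
  log_rows <- data.frame(sample_id = character(0),
                         single_haplotypes = character(0),
                         unexplained = character(0), stringsAsFactors = FALSE)
  for (r in results) {
    if (r$status == "RESOLVED") {
      all_pairs <- rbind(all_pairs, r$pairs)
      best_pairs <- rbind(best_pairs, r$best)
    } else {
      log_rows <- rbind(log_rows, data.frame(
        sample_id = r$sample_id,
        single_haplotypes = paste(r$single_matches, collapse = ";"),
        unexplained = r$note %||% "", stringsAsFactors = FALSE))
    }
  }
  paths <- c(pairs = file.path(dir, "haplotype_pairs.csv"),
             best = file.path(dir, "best_pairs.csv"),
             log = file.path(dir, "unresolved_log.csv"))
  utils::write.csv(all_pairs, paths["pairs"], row.names = FALSE)
  utils::write.csv(best_pairs, paths["best"], row.names = FALSE)
  utils::write.csv(log_rows, paths["log"], row.names = FALSE)
  invisible(paths)
}
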