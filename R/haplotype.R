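# Haplotype-pair resolution from unphased per-locus copy numbers: regex
# matching of genotype strings against a gene-content haplotype library,
# matrix subtraction for the complementary haplotype, ranking by combined
# frequency.

#' Construct a haplotype library
#'
#' Each haplotype is a per-marker copy-count signature describing one
#' chromosome's gene content, with an observation count, a population
#' frequency and centromeric/telomeric motif labels. Frequencies are used
#' to rank candidate pairs; they are not silently normalised (a warning is
#' issued if they do not sum to 1).
#'
#' @param haplotype_id Character vector of unique ids.
#' @param signatures Integer matrix, one row per haplotype, one column per
#'   marker; all entries >= 0.
#' @param markers Character vector of marker names (column order).
#' @param count Integer observation counts (>= 0).
#' @param frequency Nonnegative numeric frequencies.
#' @param cen_motif,tel_motif Motif labels.
#' @return A `haplotype_library` object.
#' @export
haplotype_library <- function(haplotype_id, signatures, markers,
                              count = rep(0L, length(haplotype_id)),
                              frequency = rep(0, length(haplotype_id)),
                              cen_motif = rep("", length(haplotype_id)),
                              tel_motif = rep("", length(haplotype_id))) {
  signatures <- matrix(as.integer(signatures), nrow = length(haplotype_id),
                       ncol = length(markers),
                       dimnames = list(haplotype_id, markers))
  stopifnot(ncol(signatures) == length(markers),
            all(signatures >= 0), all(count >= 0), all(frequency >= 0))
  if (anyDuplicated(haplotype_id)) stop("duplicate haplotype ids")
  n <- length(haplotype_id)
  if (n > 0L && abs(sum(frequency) - 1) > 1e-6)
    warning("library frequencies sum to ", signif(sum(frequency), 4),
            ", not 1; they are used as ranking weights, unnormalised")
  structure(list(haplotype_id = haplotype_id, signatures = signatures,
                 markers = markers, count = as.integer(count),
                 frequency = frequency, cen_motif = cen_motif,
                 tel_motif = tel_motif),
            class = "haplotype_library")
}

#' @export
print.haplotype_library <- function(x, ...) {
  cat("haplotype library:", length(x$haplotype_id), "haplotypes over",
      length(x$markers), "markers\n")
  invisible(x)
}

#' @export
length.haplotype_library <- function(x) length(x$haplotype_id)

#' Concatenated copy-number string (markersig)
#'
#' The genotype's per-marker copy numbers concatenated in marker order:
#' copy numbers (2, 1, 1) give `"211"`. The undelimited digit form requires
#' every copy number to be a single digit; with `delim` (or any value above
#' 9 and `delim = NULL` is an error) a delimiter-joined form is produced.
#'
#' @param copies Integer vector of copy numbers (>= 0).
#' @param delim `NULL` for the plain digit form, or a delimiter string.
#' @return Character scalar.
#' @export
markersig <- function(copies, delim = NULL) {
  stopifnot(all(copies >= 0))
  if (is.null(delim)) {
    if (any(copies > 9))
      stop("copy number above 9 needs a delimiter (set delim = \"-\")")
    paste(copies, collapse = "")
  } else paste(copies, collapse = delim)
}

#' Regular-expression pattern of all haplotype values under a genotype
#'
#' Per marker, an alternation of every copy number from the observed value
#' down to zero; concatenated over markers. A genotype of (2, 1, 1) gives
#' `"(2|1|0)(1|0)(1|0)"`: a haplotype matches exactly when its signature is
#' element-wise no greater than the genotype.
#'
#' @param copies Integer vector of copy numbers (each in 0..9).
#' @return Character scalar regex (unanchored).
#' @export
regex_pattern <- function(copies) {
  stopifnot(all(copies >= 0))
  if (any(copies > 9))
    stop("regex form is defined for single-digit copy numbers")
  paste(vapply(copies, function(k)
    paste0("(", paste(seq(k, 0), collapse = "|"), ")"), character(1)),
    collapse = "")
}

#' Haplotypes compatible with a genotype
#'
#' Matches the genotype's regex pattern against the library's signature
#' strings; a haplotype is compatible when each of its copy counts does not
#' exceed the genotype's. For copy numbers above 9 (no digit-string form)
#' the equivalent element-wise comparison is used.
#'
#' @param genotype Integer vector of per-marker copy numbers, in the
#'   library's marker order.
#' @param library A `haplotype_library`.
#' @return Integer vector of matching row indices into the library.
#' @export
match_library <- function(genotype, library) {
  if (length(genotype) != length(library$markers))
    stop("genotype has ", length(genotype), " markers; library has ",
         length(library$markers))
  if (length(library) == 0L) return(integer(0))
  if (all(genotype <= 9) && all(library$signatures <= 9)) {
    pat <- paste0("^", regex_pattern(genotype), "$")
    sigs <- apply(library$signatures, 1L, paste, collapse = "")
    which(grepl(pat, sigs))
  } else {
    which(apply(library$signatures, 1L,
                function(s) all(s <= genotype)))
  }
}

#' Residual haplotype after matrix subtraction
#'
#' Subtracts a matched haplotype signature from the genotype vector; the
#' residual is the signature the complementary haplotype must carry. `NULL`
#' when any entry would go negative (no valid complement).
#'
#' @param genotype Integer vector of per-marker copy numbers.
#' @param hap_signature Integer vector of the same length.
#' @return Integer residual vector, or `NULL` if invalid.
#' @export
complement <- function(genotype, hap_signature) {
  stopifnot(length(genotype) == length(hap_signature))
  res <- genotype - hap_signature
  if (any(res < 0)) return(NULL)
  as.integer(res)
}

#' Enumerate all haplotype pairs explaining a genotype
#'
#' Every unordered pair of library haplotypes (a haplotype may pair with
#' itself) whose signatures sum exactly to the genotype, each scored by the
#' product of the two haplotype frequencies and ordered by descending
#' combined frequency, then by ids. The score is a ranking weight, not a
#' genotype probability (homozygous pairs score f^2 with no
#' Hardy-Weinberg factor of 2 for heterozygous pairs).
#'
#' @param genotype Integer vector in the library's marker order.
#' @param library A `haplotype_library`.
#' @return Data frame with `haplotype_1`, `haplotype_2`, `frequency_1`,
#'   `frequency_2`, `combined_frequency`; zero rows if no pair exists.
#' @export
enumerate_pairs <- function(genotype, library) {
  empty <- data.frame(haplotype_1 = character(0), haplotype_2 = character(0),
                      frequency_1 = numeric(0), frequency_2 = numeric(0),
                      combined_frequency = numeric(0),
                      stringsAsFactors = FALSE)
  cand <- match_library(genotype, library)
  if (length(cand) == 0L) return(empty)
  sig_key <- apply(library$signatures, 1L, paste, collapse = "-")
  rows <- list()
  for (i in cand) {
    res <- complement(genotype, library$signatures[i, ])
    if (is.null(res)) next
    js <- which(sig_key == paste(res, collapse = "-"))
    for (j in js) {
      if (j < i) next   # unordered: emit each pair once (j >= i)
      a <- i; b <- j
      rows[[length(rows) + 1L]] <- data.frame(
        haplotype_1 = library$haplotype_id[a],
        haplotype_2 = library$haplotype_id[b],
        frequency_1 = library$frequency[a],
        frequency_2 = library$frequency[b],
        combined_frequency = library$frequency[a] * library$frequency[b],
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- unique(do.call(rbind, rows))
  out <- out[order(-out$combined_frequency, out$haplotype_1,
                   out$haplotype_2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Resolve one sample's genotype into haplotype pairs
#'
#' `RESOLVED` when at least one library pair sums to the genotype, carrying
#' all pairs plus the best pair(s) (every pair tied at the maximal combined
#' frequency); otherwise `UNRESOLVED`, carrying the single compatible
#' haplotypes for the log file.
#'
#' @param genotype Integer vector in the library's marker order.
#' @param library A `haplotype_library`.
#' @param sample_id Sample identifier carried into the outputs.
#' @return A `haplotype_resolution` list: `sample_id`, `status`, `pairs`,
#'   `best`, `single_matches`, `note`.
#' @export
resolve_sample <- function(genotype, library, sample_id = "sample") {
  pairs <- enumerate_pairs(genotype, library)
  if (nrow(pairs) > 0L) {
    pairs <- cbind(sample_id = sample_id, pairs, stringsAsFactors = FALSE)
    best <- pairs[pairs$combined_frequency == max(pairs$combined_frequency), ,
                  drop = FALSE]
    structure(list(sample_id = sample_id, status = "RESOLVED",
                   pairs = pairs, best = best,
                   single_matches = character(0), note = ""),
              class = "haplotype_resolution")
  } else {
    singles <- library$haplotype_id[match_library(genotype, library)]
    structure(list(sample_id = sample_id, status = "UNRESOLVED",
                   pairs = NULL, best = NULL, single_matches = singles,
                   note = if (length(singles) > 0L)
                     "no library pair sums to the genotype (unexplained residual)"
                   else "no library haplotype is compatible"),
              class = "haplotype_resolution")
  }
}

#' Resolve a cohort of genotypes
#'
#' @param genotypes Integer matrix, one row per sample (rownames = sample
#'   ids), columns in the library's marker order.
#' @param library A `haplotype_library`.
#' @return List of `haplotype_resolution` records, one per sample.
#' @export
resolve_cohort <- function(genotypes, library) {
  ids <- rownames(genotypes)
  if (is.null(ids)) ids <- paste0("S", seq_len(nrow(genotypes)))
  lapply(seq_len(nrow(genotypes)), function(i)
    resolve_sample(genotypes[i, ], library, ids[i]))
}

#' Trio-consistency filter on candidate pairs
#'
#' Keeps a child's candidate pair only if one haplotype occurs in some
#' paternal pair and the other in some maternal pair (either assignment of
#' the two child haplotypes to the parents counts). A Mendelian-transmission
#' screen, not full pedigree segregation.
#'
#' @param child_pairs,father_pairs,mother_pairs Pair data frames as returned
#'   by [enumerate_pairs()] (columns `haplotype_1`, `haplotype_2`).
#' @return The retained rows of `child_pairs`.
#' @export
pedigree_filter <- function(child_pairs, father_pairs, mother_pairs) {
  hap_set <- function(p) unique(c(p$haplotype_1, p$haplotype_2))
  f <- hap_set(father_pairs)
  m <- hap_set(mother_pairs)
  keep <- mapply(function(h1, h2)
    (h1 %in% f && h2 %in% m) || (h1 %in% m && h2 %in% f),
    child_pairs$haplotype_1, child_pairs$haplotype_2)
  child_pairs[as.logical(keep), , drop = FALSE]
}

#' Project a copy-number table onto a library's marker list
#'
#' Collapses per-assay calls to the per-locus genotype the haplotype
#' library expects: a library marker takes the call of the identically
#' named assay, or the consensus of all assays of its gene (e.g. the exon-4
#' and exon-9 assays). Discordant paired assays yield `NA` for that locus
#' and block haplotype inference for the sample.
#'
#' @param calls A `copy_number_table` data frame.
#' @param panel The `qpcr_panel` the calls came from.
#' @param markers Character vector: the library's marker order.
#' @return List with `genotypes` (integer matrix, samples x markers, `NA`
#'   where blocked) and `blocked` (data frame sample_id, marker, reason).
#' @export
project_genotypes <- function(calls, panel, markers) {
  ids <- panel_marker_ids(panel)
  genes <- stats::setNames(panel_marker_field(panel, "gene"), ids)
  map <- lapply(markers, function(L) {
    if (L %in% ids) return(L)
    hit <- ids[genes == paste0("KIR", L) | genes == L]
    hit <- setdiff(hit, ids[panel_marker_field(panel, "is_reference")])
    if (length(hit) == 0L) stop("library marker ", L,
                                " maps to no panel assay")
    hit
  })
  samples <- unique(calls$sample_id)
  g <- matrix(NA_integer_, length(samples), length(markers),
              dimnames = list(samples, markers))
  blocked <- list()
  for (s in samples) {
    rows <- calls[calls$sample_id == s, ]
    for (k in seq_along(markers)) {
      cn <- rows$predicted_cn[match(map[[k]], rows$marker_id)]
      cn <- cn[!is.na(cn)]
      if (length(cn) == 0L) next
      if (length(unique(cn)) == 1L) {
        g[s, k] <- cn[1]
      } else {
        blocked[[length(blocked) + 1L]] <- data.frame(
          sample_id = s, marker = markers[k],
          reason = "PAIR_DISCORDANT", stringsAsFactors = FALSE)
      }
    }
  }
  list(genotypes = g,
       blocked = if (length(blocked) > 0L) do.call(rbind, blocked)
                 else data.frame(sample_id = character(0),
                                 marker = character(0),
                                 reason = character(0),
                                 stringsAsFactors = FALSE))
}
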