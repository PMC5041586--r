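# Shared fixtures: a minimal one-target duplex panel, tiny haplotype
# libraries, and a brute-force pair-enumeration oracle.

mini_panel <- function(marker = "M", replicates = 4L) {
  qpcr_panel("mini",
             markers = list(
               marker_assay("STAT6", "STAT6", channel = "Cy5",
                            is_reference = TRUE),
               marker_assay(marker, marker, channel = "FAM")),
             reactions = list(multiplex_reaction("R1", marker, "STAT6")),
             replicates = replicates)
}

mini_library <- function() {
  suppressWarnings(haplotype_library(
    c("H1", "H0"), matrix(c(1L, 0L), 2, 1), "M",
    frequency = c(0.5, 0.5)))
}

# random small library + genotype, for property tests
random_library <- function(n_hap, n_marker, max_copy = 2L) {
  sig <- matrix(sample(0:max_copy, n_hap * n_marker, replace = TRUE,
                       prob = c(0.5, 0.35, 0.15)[seq_len(max_copy + 1L)]),
                n_hap, n_marker)
  suppressWarnings(haplotype_library(
    sprintf("h%02d", seq_len(n_hap)), sig,
    sprintf("m%02d", seq_len(n_marker)),
    frequency = stats::runif(n_hap)))
}

# independent oracle: double loop over all unordered library pairs
brute_force_pairs <- function(genotype, library) {
  n <- length(library)
  rows <- list()
  for (i in seq_len(n)) for (j in i:n) {
    if (n == 0L) break
    if (all(library$signatures[i, ] + library$signatures[j, ] == genotype)) {
      f <- sort(c(library$haplotype_id[i], library$haplotype_id[j]))
      rows[[length(rows) + 1L]] <- data.frame(
        haplotype_1 = f[1], haplotype_2 = f[2],
        combined_frequency = library$frequency[i] * library$frequency[j],
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(haplotype_1 = character(0), haplotype_2 = character(0),
                      combined_frequency = numeric(0)))
  out <- unique(do.call(rbind, rows))
  out[order(out$haplotype_1, out$haplotype_2), , drop = FALSE]
}

# canonical form for pair-set comparison (order-insensitive)
pair_key_set <- function(pairs) {
  if (nrow(pairs) == 0L) return(character(0))
  sort(apply(cbind(pmin(pairs$haplotype_1, pairs$haplotype_2),
                   pmax(pairs$haplotype_1, pairs$haplotype_2)),
             1L, paste, collapse = "|"))
}
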