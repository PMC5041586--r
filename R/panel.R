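# Multiplex qPCR panel model: marker assays, multiplex reactions, plate plans.

#' Construct a marker assay
#'
#' A marker assay is one primer pair + hydrolysis probe targeting a region of
#' a gene, read on one fluorophore channel of a multiplex reaction.
#'
#' @param marker_id Short unique identifier, e.g. `"3DL1e4"`.
#' @param gene Locus name, e.g. `"KIR3DL1"`.
#' @param region_label Free-text region description, e.g. `"exon 4"`.
#' @param channel Dye label (panel-declared, e.g. `"FAM"`, `"Orange"`, `"Cy5"`).
#' @param is_reference `TRUE` for the endogenous reference assay (fixed copy
#'   number on a different chromosome).
#' @return A `marker_assay` list.
#' @export
marker_assay <- function(marker_id, gene, region_label = "", channel,
                         is_reference = FALSE) {
  stopifnot(is.character(marker_id), nchar(marker_id) > 0,
            is.character(gene), is.character(channel))
  structure(list(marker_id = marker_id, gene = gene,
                 region_label = region_label, channel = channel,
                 is_reference = isTRUE(is_reference)),
            class = "marker_assay")
}

#' Construct a multiplex reaction
#'
#' A triplex reaction amplifies two target markers plus the reference assay in
#' one well; a duplex reaction amplifies one target plus the reference. All
#' assays sharing a well must be read on distinct channels.
#'
#' @param reaction_id Short unique identifier.
#' @param target_markers Character vector of 1 (duplex) or 2 (triplex) target
#'   marker ids.
#' @param reference_marker Marker id of the reference assay in this well.
#' @return A `multiplex_reaction` list.
#' @export
multiplex_reaction <- function(reaction_id, target_markers, reference_marker) {
  stopifnot(length(target_markers) %in% c(1L, 2L))
  structure(list(reaction_id = reaction_id,
                 target_markers = as.character(target_markers),
                 reference_marker = as.character(reference_marker)),
            class = "multiplex_reaction")
}

#' Construct a qPCR panel
#'
#' Bundles the assay design: markers, their grouping into multiplex reactions,
#' the reference copy number, the replicate count, and the consistency
#' metadata (paired assays targeting different regions of the same gene, and
#' sum rules tying a whole-gene assay to its variant-specific assays).
#'
#' @param name Panel name.
#' @param markers List of [marker_assay()] objects.
#' @param reactions List of [multiplex_reaction()] objects.
#' @param reference_copy_number Copies of the reference gene per diploid
#'   genome (default 2).
#' @param replicates Technical replicates per sample x reaction (default 4).
#' @param paired_assays List of length-2 character vectors: marker-id pairs
#'   that assay the same gene and must agree.
#' @param sum_rules Named list: `total_marker = c(component markers)`; the
#'   total must equal the sum of the components.
#' @param validate Check invariants and stop on violation (default `TRUE`).
#' @return A `qpcr_panel` object.
#' @export
qpcr_panel <- function(name, markers, reactions, reference_copy_number = 2L,
                       replicates = 4L, paired_assays = list(),
                       sum_rules = list(), validate = TRUE) {
  panel <- structure(list(name = name, markers = markers,
                          reactions = reactions,
                          reference_copy_number = as.integer(reference_copy_number),
                          replicates = as.integer(replicates),
                          paired_assays = paired_assays,
                          sum_rules = sum_rules),
                     class = "qpcr_panel")
  if (validate) {
    report <- validate_panel(panel)
    if (nrow(report) > 0L)
      stop("invalid panel '", name, "': ",
           paste(report$message, collapse = "; "))
  }
  panel
}

#' @export
print.qpcr_panel <- function(x, ...) {
  cat("qPCR panel:", x$name, "\n")
  cat("  markers:   ", length(x$markers),
      sprintf("(%d targets + %d reference)\n",
              sum(!panel_marker_field(x, "is_reference")),
              sum(panel_marker_field(x, "is_reference"))))
  cat("  reactions: ", length(x$reactions), "\n")
  cat("  replicates:", x$replicates,
      " wells/sample:", reactions_per_sample(x), "\n")
  invisible(x)
}

panel_marker_ids <- function(panel)
  vapply(panel$markers, `[[`, character(1), "marker_id")

panel_marker_field <- function(panel, field)
  sapply(panel$markers, `[[`, field)

panel_marker <- function(panel, marker_id) {
  i <- match(marker_id, panel_marker_ids(panel))
  if (is.na(i)) stop("unknown marker: ", marker_id)
  panel$markers[[i]]
}

panel_reaction <- function(panel, reaction_id) {
  ids <- vapply(panel$reactions, `[[`, character(1), "reaction_id")
  i <- match(reaction_id, ids)
  if (is.na(i)) stop("unknown reaction: ", reaction_id)
  panel$reactions[[i]]
}

#' Markers of a reaction (targets then reference)
#' @param panel A `qpcr_panel`.
#' @param reaction_id Reaction id.
#' @return Character vector of marker ids.
#' @export
reaction_markers <- function(panel, reaction_id) {
  rx <- panel_reaction(panel, reaction_id)
  c(rx$target_markers, rx$reference_marker)
}

#' Non-reference marker ids of a panel
#' @param panel A `qpcr_panel`.
#' @return Character vector of target marker ids.
#' @export
panel_target_markers <- function(panel)
  panel_marker_ids(panel)[!panel_marker_field(panel, "is_reference")]

#' Panel metadata summary
#'
#' @param panel A `qpcr_panel`.
#' @return List with `n_markers` (non-reference targets), `n_reactions`,
#'   `n_primer_pairs` (all assays including the reference),
#'   `wells_per_sample`.
#' @export
panel_metadata <- function(panel) {
  list(name = panel$name,
       n_markers = length(panel_target_markers(panel)),
       n_reactions = length(panel$reactions),
       n_primer_pairs = length(panel$markers),
       wells_per_sample = reactions_per_sample(panel))
}

#' Validate a panel
#'
#' Report-based validation: duplicate marker ids, channel clashes within a
#' reaction, dangling marker references in reactions, paired assays or sum
#' rules, a non-reference marker used as a reaction's reference, and marker
#' multiplicity (each target covered by exactly one reaction).
#'
#' @param panel A `qpcr_panel`.
#' @return Data frame with columns `rule` and `message`; zero rows when valid.
#' @export
validate_panel <- function(panel) {
  bad <- list()
  flag <- function(rule, message)
    bad[[length(bad) + 1L]] <<- data.frame(rule = rule, message = message,
                                           stringsAsFactors = FALSE)
  ids <- panel_marker_ids(panel)
  dup <- unique(ids[duplicated(ids)])
  for (d in dup) flag("duplicate_id", paste0("duplicate marker id: ", d))

  if (panel$reference_copy_number < 1L)
    flag("reference_cn", "reference_copy_number must be >= 1")

  chan <- stats::setNames(panel_marker_field(panel, "channel"), ids)
  isref <- stats::setNames(panel_marker_field(panel, "is_reference"), ids)

  target_use <- character(0)
  for (rx in panel$reactions) {
    mk <- c(rx$target_markers, rx$reference_marker)
    missing <- setdiff(mk, ids)
    for (m in missing)
      flag("dangling_reference",
           paste0("reaction ", rx$reaction_id, " references unknown marker ", m))
    present <- intersect(mk, ids)
    ch <- chan[present]
    if (anyDuplicated(ch))
      flag("channel_clash",
           paste0("reaction ", rx$reaction_id, " has two assays on channel ",
                  ch[duplicated(ch)][1]))
    if (rx$reference_marker %in% ids && !isref[[rx$reference_marker]])
      flag("reference_marker",
           paste0("reaction ", rx$reaction_id, " reference marker ",
                  rx$reference_marker, " is not flagged is_reference"))
    target_use <- c(target_use, intersect(rx$target_markers, ids))
  }
  for (m in setdiff(ids[!isref], target_use))
    flag("uncovered_marker", paste0("target marker ", m, " is in no reaction"))
  for (m in unique(target_use[duplicated(target_use)]))
    flag("multiply_covered",
         paste0("target marker ", m, " targeted by more than one reaction"))

  for (p in panel$paired_assays)
    for (m in setdiff(p, ids))
      flag("dangling_reference", paste0("paired_assays references unknown marker ", m))
  for (total in names(panel$sum_rules))
    for (m in setdiff(c(total, panel$sum_rules[[total]]), ids))
      flag("dangling_reference", paste0("sum_rules references unknown marker ", m))

  if (length(bad) == 0L)
    data.frame(rule = character(0), message = character(0),
               stringsAsFactors = FALSE)
  else do.call(rbind, bad)
}

#' Reactions (wells) required to fully type one sample
#'
#' With a 10-reaction panel run in quadruplicate this is 40 wells per sample.
#'
#' @param panel A `qpcr_panel`.
#' @return Integer: `length(reactions) * replicates`.
#' @export
reactions_per_sample <- function(panel)
  length(panel$reactions) * panel$replicates

#' Load a panel from a YAML configuration file
#'
#' The file lists `markers` (id, gene, region, channel, reference flag),
#' `reactions` (id, targets, reference), and optional `paired_assays`,
#' `sum_rules`, `reference_copy_number`, `replicates`. See the bundled
#' `kir_panel.yaml` under `extdata` for the documented schema.
#'
#' @param path Path to the YAML file, or one of the well-known bundled names
#'   `"kir"` (20-marker triplex panel) or `"lilr"` (duplex demo panel).
#' @return A validated `qpcr_panel`.
#' @export
load_panel <- function(path) {
  if (path %in% c("kir", "lilr")) {
    path <- system.file("extdata", paste0(path, "_panel.yaml"),
                        package = "kircn", mustWork = TRUE)
  }
  if (!file.exists(path)) stop("panel file not found: ", path)
  cfg <- yaml::read_yaml(path)
  for (field in c("name", "markers", "reactions"))
    if (is.null(cfg[[field]])) stop("panel config missing field: ", field)
  markers <- lapply(cfg$markers, function(m)
    marker_assay(m$id, gene = m$gene %||% m$id,
                 region_label = m$region %||% "",
                 channel = m$channel,
                 is_reference = isTRUE(m$reference)))
  reactions <- lapply(cfg$reactions, function(r)
    multiplex_reaction(r$id, unlist(r$targets), r$reference))
  qpcr_panel(cfg$name, markers, reactions,
             reference_copy_number = cfg$reference_copy_number %||% 2L,
             replicates = cfg$replicates %||% 4L,
             paired_assays = lapply(cfg$paired_assays %||% list(), unlist),
             sum_rules = lapply(cfg$sum_rules %||% list(), unlist))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The bundled 20-marker KIR panel
#'
#' Twenty target markers over the KIR loci (2DL1-5, 2DS1-3, 2DS4 plus its
#' full-length and deletion variants, 2DS5, 3DL1 exon 4 and exon 9, 3DL2 two
#' regions, 3DL3, 3DS1, 2DP1, 3DP1) grouped into ten triplex reactions, each
#' sharing the STAT6 reference assay. The grouping of targets into reactions
#' is a fixed convention of this package, not an instrument requirement.
#'
#' @return A validated `qpcr_panel`.
#' @export
kir_panel <- function() load_panel("kir")

#' Plan 384-well plate layouts
#'
#' Assigns every sample all reactions x replicates wells, row-major with
#' replicates contiguous, carrying the control samples onto every plate.
#' Deterministic: identical inputs give identical layouts.
#'
#' @param panel A `qpcr_panel`.
#' @param sample_ids Character vector of test sample ids.
#' @param controls Named list: control sample id -> known copy-number vector
#'   (named by marker). Controls are plated on every plate.
#' @param plate_rows,plate_cols Plate geometry (default 16 x 24 = 384).
#' @return List of `plate_layout` objects; each has `plate_id`, a `wells`
#'   data frame (well, sample_id, reaction_id, replicate_index) and
#'   `control_samples`.
#' @export
plan_plates <- function(panel, sample_ids, controls = list(),
                        plate_rows = 16L, plate_cols = 24L) {
  if (length(sample_ids) == 0L) stop("no samples to plate")
  if (length(panel$reactions) == 0L) stop("panel has no reactions")
  per_sample <- reactions_per_sample(panel)
  capacity <- plate_rows * plate_cols
  n_ctrl <- length(controls)
  ctrl_wells <- n_ctrl * per_sample
  if (ctrl_wells + per_sample > capacity)
    stop("controls plus one sample exceed plate capacity")
  per_plate <- (capacity - ctrl_wells) %/% per_sample
  n_plates <- ceiling(length(sample_ids) / per_plate)

  rx_ids <- vapply(panel$reactions, `[[`, character(1), "reaction_id")
  well_names <- as.vector(t(outer(LETTERS[seq_len(plate_rows)],
                                  seq_len(plate_cols), paste0)))
  plates <- vector("list", n_plates)
  for (p in seq_len(n_plates)) {
    batch <- sample_ids[((p - 1L) * per_plate + 1L):min(p * per_plate,
                                                        length(sample_ids))]
    ids <- c(names(controls), batch)
    grid <- expand.grid(replicate_index = seq_len(panel$replicates),
                        reaction_id = rx_ids, sample_id = ids,
                        stringsAsFactors = FALSE)
    # expand.grid varies the first factor fastest: replicates contiguous
    grid <- grid[, c("sample_id", "reaction_id", "replicate_index")]
    grid$well <- well_names[seq_len(nrow(grid))]
    plates[[p]] <- structure(
      list(plate_id = sprintf("plate%02d", p),
           wells = grid[, c("well", "sample_id", "reaction_id",
                            "replicate_index")],
           control_samples = controls),
      class = "plate_layout")
  }
  plates
}

#' Export plate layouts as a CSV-ready data frame
#' @param plates List of `plate_layout` objects from [plan_plates()].
#' @return Data frame (plate, well, sample, reaction, replicate).
#' @export
plate_layout_table <- function(plates) {
  do.call(rbind, lapply(plates, function(p)
    data.frame(plate = p$plate_id, well = p$wells$well,
               sample = p$wells$sample_id, reaction = p$wells$reaction_id,
               replicate = p$wells$replicate_index,
               stringsAsFactors = FALSE)))
}
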