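# Structure-anchored reference alignment: container, validation, anchor maps.

#' Load a reference alignment with its column annotation
#'
#' Reads an aligned FASTA or Nexus file plus a YAML annotation file supplying
#' the structural elements, the four ar/R filter columns, the phylogenetic
#' core interval, the anchor row ids and (optionally) the motif ledger,
#' characterized substrate filters and per-row subfamily labels.  All type
#' invariants are checked at load time.
#'
#' @param alignment_file path to an aligned FASTA (`.fa`, `.fasta`) or Nexus
#'   (`.nex`, `.nexus`) file; all rows must have equal length.
#' @param annotation_file path to the YAML annotation.
#' @return an object of class `mip_reference`.
#' @export
load_reference <- function(alignment_file, annotation_file) {
  aln <- read_alignment(alignment_file)
  ann <- yaml::read_yaml(annotation_file)
  elements <- do.call(rbind, lapply(ann$elements, function(e)
    data.frame(name = e$name, start_col = as.integer(e$start_col),
               end_col = as.integer(e$end_col), stringsAsFactors = FALSE)))
  motifs <- if (!is.null(ann$motifs))
    do.call(rbind, lapply(ann$motifs, function(m) {
      data.frame(motif_id = m$motif_id, kind = m$kind,
                 pattern = m$pattern %||% NA_character_,
                 window_start = as.integer(m$window_start %||% NA),
                 window_end = as.integer(m$window_end %||% NA),
                 anchor_id = m$anchor_id %||% NA_character_,
                 resnums = m$resnums %||% NA_character_,
                 expect = m$expect %||% NA_character_,
                 note = m$note %||% "", stringsAsFactors = FALSE)
    }))
  substrates <- if (!is.null(ann$substrates))
    do.call(rbind, lapply(ann$substrates, as.data.frame,
                          stringsAsFactors = FALSE))
  new_mip_reference(
    aln = aln,
    subfamily = unlist(ann$subfamilies),
    elements = elements,
    arr_columns = vapply(ann$arr_columns[c("H2", "H5", "LE1", "LE2")],
                         as.integer, integer(1)),
    core_interval = as.integer(ann$core_interval),
    anchor_ids = unlist(ann$anchors),
    motifs = motifs,
    substrates = substrates
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct and validate a reference alignment object
#'
#' @param aln character matrix of aligned rows (one character per cell, gap
#'   `"-"`), with row names.
#' @param subfamily named vector of subfamily labels for (a subset of) rows.
#' @param elements data.frame with columns name, start_col, end_col.
#' @param arr_columns integer vector named H2, H5, LE1, LE2.
#' @param core_interval length-2 integer vector.
#' @param anchor_ids row ids whose ungapped numbering anchors site motifs.
#' @param motifs,substrates optional ledger tables (see
#'   [synthesize_reference_set()] for the packaged defaults).
#' @return validated `mip_reference` object.
#' @export
new_mip_reference <- function(aln, subfamily, elements, arr_columns,
                              core_interval, anchor_ids,
                              motifs = NULL, substrates = NULL) {
  anchors <- lapply(stats::setNames(anchor_ids, anchor_ids), function(id) {
    if (!id %in% rownames(aln))
      stop("annotation error: anchor row absent from alignment: ", id)
    anchor_map(aln[id, ])
  })
  ref <- structure(list(
    aln = aln, subfamily = subfamily, elements = elements,
    arr_columns = arr_columns, core_interval = core_interval,
    anchors = anchors, motifs = motifs, substrates = substrates
  ), class = "mip_reference")
  validate_mip_reference(ref)
  ref
}

# alignment column -> anchor residue number (NA at gap columns)
anchor_map <- function(row) {
  m <- rep(NA_integer_, length(row))
  nongap <- row != "-"
  m[nongap] <- seq_len(sum(nongap))
  m
}

#' @export
print.mip_reference <- function(x, ...) {
  cat("mip_reference:", nrow(x$aln), "rows x", ncol(x$aln), "columns\n")
  cat("  subfamilies:", paste(sort(unique(x$subfamily)), collapse = ", "), "\n")
  cat("  core interval: [", x$core_interval[1], ",", x$core_interval[2], "]\n")
  cat("  ar/R columns:", paste(names(x$arr_columns), x$arr_columns,
                               sep = "=", collapse = " "), "\n")
  cat("  anchors:", paste(names(x$anchors), collapse = ", "), "\n")
  invisible(x)
}

validate_mip_reference <- function(ref) {
  aln <- ref$aln
  if (is.null(rownames(aln))) stop("format error: alignment rows must be named")
  el <- ref$elements
  if (any(el$start_col > el$end_col))
    stop("annotation error: element with start_col > end_col")
  if (any(el$start_col < 1L) || any(el$end_col > ncol(aln)))
    stop("annotation error: element outside alignment columns")
  # H1..H6 and loops must be pairwise disjoint; HB/HE (and the NPA boxes at
  # their N-termini) live inside loops B/E.
  main <- el[el$name %in% c("H1","LA","H2","LB","H3","LC","H4","LD","H5","LE","H6"), ]
  main <- main[order(main$start_col), ]
  if (nrow(main) > 1 && any(main$start_col[-1] <= main$end_col[-nrow(main)]))
    stop("annotation error: overlapping structural elements")
  within <- function(inner, outer) {
    i <- el[el$name == inner, ]; o <- el[el$name == outer, ]
    nrow(i) == 0 || nrow(o) == 0 ||
      (i$start_col >= o$start_col && i$end_col <= o$end_col)
  }
  if (!within("HB", "LB") || !within("HE", "LE"))
    stop("annotation error: half-helix not contained in its loop")
  if (!within("NPA1", "HB") ||
      el[el$name == "NPA1", "start_col"] != el[el$name == "HB", "start_col"])
    stop("annotation error: NPA1 must sit at the N-terminal end of HB")
  if (!within("NPA2", "HE") ||
      el[el$name == "NPA2", "start_col"] != el[el$name == "HE", "start_col"])
    stop("annotation error: NPA2 must sit at the N-terminal end of HE")
  arr <- ref$arr_columns
  if (length(arr) != 4L || anyDuplicated(arr))
    stop("annotation error: arr_columns must be 4 distinct columns")
  in_el <- function(col, name) {
    e <- el[el$name == name, ]
    col >= e$start_col && col <= e$end_col
  }
  if (!in_el(arr["H2"], "H2")) stop("annotation error: ar/R H2 column outside H2")
  if (!in_el(arr["H5"], "H5")) stop("annotation error: ar/R H5 column outside H5")
  npa2_end <- el[el$name == "NPA2", "end_col"]
  for (p in c("LE1", "LE2"))
    if (!in_el(arr[p], "LE") || arr[p] <= npa2_end)
      stop("annotation error: ar/R ", p, " column must lie in loop E after NPA2")
  ci <- ref$core_interval
  if (length(ci) != 2L || ci[1] > ci[2] || ci[1] < 1L || ci[2] > ncol(aln))
    stop("annotation error: invalid core_interval")
  invisible(ref)
}

#' Alignment column of an anchor residue
#'
#' Inverse of the anchor's column-to-residue-number map: returns the unique
#' alignment column whose anchor residue number equals `resnum`.
#'
#' @param ref a `mip_reference`.
#' @param anchor_id anchor row id (e.g. `"SoPIP2;1"`).
#' @param resnum residue number in the anchor's own ungapped numbering.
#' @return integer alignment column.
#' @export
anchor_residue <- function(ref, anchor_id, resnum) {
  if (!anchor_id %in% names(ref$anchors))
    stop("annotation error: unknown anchor: ", anchor_id)
  m <- ref$anchors[[anchor_id]]
  col <- which(m == resnum)
  if (length(col) != 1L)
    stop("range error: residue ", resnum, " maps to no column of anchor ",
         anchor_id)
  col
}

#' Write a reference alignment and its annotation back to disk
#'
#' @param ref a `mip_reference`.
#' @param alignment_file output path (`.nex`/`.nexus` for Nexus, otherwise
#'   aligned FASTA).
#' @param annotation_file output YAML path.
#' @export
write_reference <- function(ref, alignment_file, annotation_file) {
  write_alignment(ref$aln, alignment_file)
  ann <- list(
    elements = lapply(seq_len(nrow(ref$elements)), function(i)
      as.list(ref$elements[i, ])),
    arr_columns = as.list(ref$arr_columns),
    core_interval = ref$core_interval,
    anchors = names(ref$anchors),
    subfamilies = as.list(ref$subfamily)
  )
  if (!is.null(ref$motifs))
    ann$motifs <- lapply(seq_len(nrow(ref$motifs)), function(i) {
      m <- as.list(ref$motifs[i, ])
      m[!vapply(m, function(x) is.na(x) || identical(x, ""), logical(1))]
    })
  if (!is.null(ref$substrates))
    ann$substrates <- lapply(seq_len(nrow(ref$substrates)), function(i)
      as.list(ref$substrates[i, ]))
  yaml::write_yaml(ann, annotation_file)
  invisible(ref)
}

#' Read an alignment file as a character matrix
#'
#' Supports aligned FASTA (via Biostrings) and Nexus (via ape). Rows must all
#' have the same length.
#'
#' @param path input file.
#' @return character matrix (one character per cell, `"-"` gaps).
#' @export
read_alignment <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("nex", "nexus")) {
    rows <- ape::read.nexus.data(path)
    lens <- lengths(rows)
    if (length(unique(lens)) != 1L)
      stop("format error: ragged rows in alignment")
    aln <- do.call(rbind, lapply(rows, toupper))
  } else {
    ss <- Biostrings::readBStringSet(path)
    lens <- Biostrings::width(ss)
    if (length(unique(lens)) != 1L)
      stop("format error: ragged rows in alignment")
    aln <- do.call(rbind, strsplit(toupper(as.character(ss)), ""))
    rownames(aln) <- names(ss)
  }
  aln
}

#' Write a character-matrix alignment to aligned FASTA or Nexus
#' @param aln character matrix with row names.
#' @param path output file; `.nex`/`.nexus` selects Nexus.
#' @export
write_alignment <- function(aln, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("nex", "nexus")) {
    rows <- stats::setNames(lapply(seq_len(nrow(aln)), function(i) aln[i, ]),
                            rownames(aln))
    ape::write.nexus.data(rows, path, format = "protein", interleaved = FALSE)
  } else {
    seqs <- apply(aln, 1, paste, collapse = "")
    ss <- Biostrings::BStringSet(seqs)
    Biostrings::writeXStringSet(ss, path, width = 80L)
  }
  invisible(path)
}

.mip_ref_cache <- new.env(parent = emptyenv())

#' The packaged default reference alignment
#'
#' Loads (and caches) the synthetic reference set shipped under
#' `inst/extdata`: 27 reference rows covering the PIP, GIP, TIP, NIP, SIP,
#' XIP and HIP land-plant subfamilies, the algal MIPA-MIPE subfamilies and
#' two outgroup channels, with the full column annotation.
#'
#' @return a `mip_reference`.
#' @export
mip_reference <- function() {
  if (!is.null(.mip_ref_cache$ref)) return(.mip_ref_cache$ref)
  aln <- system.file("extdata", "reference_alignment.synthetic.fasta",
                     package = "mipscan", mustWork = TRUE)
  ann <- system.file("extdata", "reference_annotation.yml",
                     package = "mipscan", mustWork = TRUE)
  ref <- load_reference(aln, ann)
  .mip_ref_cache$ref <- ref
  ref
}
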