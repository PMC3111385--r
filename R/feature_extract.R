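# Extraction of NPA motifs, ar/R selectivity filter, subfamily-diagnostic
# motifs, loop lengths and C-terminal charge from an aligned query, plus the
# nearest-neighbour substrate heuristic.

element_cols <- function(ref, name) {
  e <- ref$elements[ref$elements$name == name, ]
  if (nrow(e) != 1L) stop("annotation error: element not annotated: ", name)
  seq.int(e$start_col, e$end_col)
}

#' Extract the two NPA motifs
#'
#' Reads the three residues at each NPA element's columns (loop B / loop E);
#' gap symbols where the query does not cover a column.
#'
#' @param aq a `mip_aligned`.
#' @param ref the `mip_reference`.
#' @return list of class `mip_npa` with `npa1`, `npa2` (3-character strings),
#'   `canonical1`, `canonical2` (equal to `"NPA"`).
#' @export
extract_npa <- function(aq, ref) {
  r1 <- aligned_residues(aq, element_cols(ref, "NPA1"))
  r2 <- aligned_residues(aq, element_cols(ref, "NPA2"))
  if (all(r1 == "-") && all(r2 == "-"))
    stop("extraction error: neither NPA element covered by ", aq$seq$id)
  npa1 <- paste(r1, collapse = "")
  npa2 <- paste(r2, collapse = "")
  structure(list(npa1 = npa1, npa2 = npa2,
                 canonical1 = npa1 == "NPA", canonical2 = npa2 == "NPA"),
            class = "mip_npa")
}

#' Extract the ar/R selectivity filter
#'
#' The four residues at the annotated H2, H5, LE1 and LE2 columns; a cysteine
#' at any filter position flags predicted mercury sensitivity.
#'
#' @inheritParams extract_npa
#' @return list of class `mip_arr` with `h2`, `h5`, `le1`, `le2` and
#'   `mercury_cysteine`.
#' @export
extract_filter <- function(aq, ref) {
  r <- aligned_residues(aq, ref$arr_columns)
  if (sum(r != "-") < 2L)
    stop("extraction error: fewer than 2 ar/R filter positions covered by ",
         aq$seq$id)
  structure(list(h2 = r[1], h5 = r[2], le1 = r[3], le2 = r[4],
                 mercury_cysteine = "C" %in% r), class = "mip_arr")
}

#' @export
format.mip_arr <- function(x, ...) paste(x$h2, x$h5, x$le1, x$le2)

# read residues for a site motif via anchor-mapped columns
.site_residues <- function(aq, ref, anchor_id, resnums) {
  cols <- vapply(resnums, function(r) anchor_residue(ref, anchor_id, r),
                 integer(1))
  aligned_residues(aq, cols)
}

#' Scan the packaged subfamily-diagnostic motifs
#'
#' Pattern motifs (KxSxxR, GGGAN, DxxxR, LxxN, DGCS, ...) are matched in the
#' gap-stripped query text of their designated column window; site motifs
#' (H193, D28/E31, the H2 glycine, H3 glutamine, H6 proline, the loop C and
#' post-HE cysteines, the GlpF packing residues) are read at anchor-mapped
#' columns.  A window with no query coverage yields `present = FALSE` flagged
#' `"no_coverage"`.
#'
#' @inheritParams extract_npa
#' @return data.frame with one row per ledger motif: motif_id, present,
#'   location, matched_text, flag.
#' @export
scan_diagnostics <- function(aq, ref) {
  led <- ref$motifs
  if (is.null(led)) led <- .mip_motif_ledger()
  out <- lapply(seq_len(nrow(led)), function(i) {
    m <- led[i, ]
    if (m$kind == "pattern") {
      cols <- seq.int(m$window_start, m$window_end)
      res <- aligned_residues(aq, cols)
      txt <- paste(res[res != "-"], collapse = "")
      if (!nzchar(txt))
        return(data.frame(motif_id = m$motif_id, present = FALSE,
                          location = "", matched_text = "",
                          flag = "no_coverage", stringsAsFactors = FALSE))
      hit <- regmatches(txt, regexpr(m$pattern, txt))
      data.frame(motif_id = m$motif_id, present = length(hit) == 1L,
                 location = sprintf("cols %d-%d", m$window_start, m$window_end),
                 matched_text = if (length(hit)) hit else "",
                 flag = "", stringsAsFactors = FALSE)
    } else {
      resnums <- as.integer(strsplit(m$resnums, ",")[[1]])
      expect <- strsplit(m$expect, ",")[[1]]
      obs <- .site_residues(aq, ref, m$anchor_id, resnums)
      covered <- obs != "-"
      present <- all(covered) && all(obs == expect)
      data.frame(motif_id = m$motif_id, present = present,
                 location = paste0(m$anchor_id, " ",
                                   paste(resnums, collapse = "/")),
                 matched_text = if (present) paste(obs, collapse = "") else "",
                 flag = if (!all(covered)) "no_coverage" else "",
                 stringsAsFactors = FALSE)
    }
  })
  hits <- do.call(rbind, out)
  attr(hits, "observed") <- .observed_sites(aq, ref, led)
  hits
}

# observed residues at single-site motifs, for substitution-aware rules
.observed_sites <- function(aq, ref, led) {
  site <- led[led$kind == "site", ]
  obs <- lapply(seq_len(nrow(site)), function(i) {
    resnums <- as.integer(strsplit(site$resnums[i], ",")[[1]])
    paste(.site_residues(aq, ref, site$anchor_id[i], resnums), collapse = "")
  })
  stats::setNames(unlist(obs), site$motif_id)
}

#' Loop lengths of an aligned query
#'
#' Number of query residues (gaps excluded) inside each annotated loop, plus
#' `LB_preNPA1`, the stretch of loop B preceding the first NPA box (short in
#' GlpF-like channels).
#'
#' @inheritParams extract_npa
#' @return named integer vector.
#' @export
loop_lengths <- function(aq, ref) {
  loops <- c("LA", "LB", "LC", "LD", "LE")
  out <- vapply(loops, function(nm)
    sum(aligned_residues(aq, element_cols(ref, nm)) != "-"), integer(1))
  hb_start <- ref$elements[ref$elements$name == "HB", "start_col"]
  lb <- element_cols(ref, "LB")
  pre <- lb[lb < hb_start]
  c(out, LB_preNPA1 = sum(aligned_residues(aq, pre) != "-"))
}

#' Fraction of positively charged residues in the C-terminal tail
#'
#' Counts lysine and arginine among the query residues after the last H6
#' column.  Tails shorter than 5 residues are flagged not evaluable (NA).
#'
#' @inheritParams extract_npa
#' @return numeric fraction in `[0, 1]`, or NA when not evaluable.
#' @export
cterm_charge <- function(aq, ref) {
  h6_end <- ref$elements[ref$elements$name == "H6", "end_col"]
  qres <- strsplit(aq$seq$residues, "")[[1]]
  in_h6 <- aq$col_map[seq_len(min(h6_end, length(aq$col_map)))]
  last_h6_res <- suppressWarnings(max(in_h6, na.rm = TRUE))
  if (!is.finite(last_h6_res)) return(NA_real_)
  if (last_h6_res + 5L > length(qres)) {
    out <- NA_real_
    attr(out, "flag") <- "tail_too_short"
    return(out)
  }
  tail <- qres[seq.int(last_h6_res + 1L, length(qres))]
  sum(tail %in% c("K", "R")) / length(tail)
}

#' Nearest-neighbour substrate heuristic
#'
#' Compares an ar/R filter to the characterized filters in the packaged table
#' position by position (identity count, strong-similarity-group count as
#' tie-break) and returns the substrate class of the best match; `"unknown"`
#' on ties, fewer than 2 identities, or fewer than 3 non-gap filter residues.
#'
#' @param f a `mip_arr` (or 4-character vector H2, H5, LE1, LE2).
#' @param substrates optional characterized-filter table; defaults to the
#'   packaged one.
#' @return one of `"water"`, `"glycerol"`, `"water/glycerol"`, `"unknown"`.
#' @export
substrate_heuristic <- function(f, substrates = NULL) {
  if (inherits(f, "mip_arr")) f <- c(f$h2, f$h5, f$le1, f$le2)
  if (sum(f != "-") < 3L) return("unknown")
  tab <- substrates %||% .mip_substrate_table()
  strong <- function(x, y) x != "-" && y != "-" && x != y &&
    any(vapply(.mip_strong_groups, function(g)
      grepl(x, g, fixed = TRUE) && grepl(y, g, fixed = TRUE), logical(1)))
  ids <- sim <- numeric(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    g <- c(tab$h2[i], tab$h5[i], tab$le1[i], tab$le2[i])
    ids[i] <- sum(f == g & f != "-")
    sim[i] <- sum(vapply(1:4, function(k) strong(f[k], g[k]), logical(1)))
  }
  best <- max(ids)
  if (best < 2L) return("unknown")
  cand <- which(ids == best)
  if (length(cand) > 1L) {
    cand <- cand[sim[cand] == max(sim[cand])]
    if (length(cand) > 1L &&
        length(unique(tab$substrate[cand])) > 1L) return("unknown")
  }
  tab$substrate[cand[1L]]
}

#' Full feature profile of an aligned query
#'
#' Bundles NPA motifs, ar/R filter, diagnostic motif hits, loop lengths,
#' C-terminal charge and the substrate heuristic.
#'
#' @inheritParams extract_npa
#' @return object of class `mip_features`.
#' @export
feature_profile <- function(aq, ref) {
  npa <- extract_npa(aq, ref)
  filt <- extract_filter(aq, ref)
  hits <- scan_diagnostics(aq, ref)
  structure(list(
    seq_id = aq$seq$id,
    species_tag = aq$seq$species_tag,
    npa = npa,
    filter = filt,
    hits = hits,
    observed_sites = attr(hits, "observed"),
    loop_lengths = loop_lengths(aq, ref),
    cterm_positive_fraction = cterm_charge(aq, ref),
    substrate_class = substrate_heuristic(filt, ref$substrates)
  ), class = "mip_features")
}

#' @export
print.mip_features <- function(x, ...) {
  cat(x$seq_id, " ar/R ", format(x$filter), "  NPA ", x$npa$npa1, "/",
      x$npa$npa2, "  substrate ", x$substrate_class, "\n", sep = "")
  pres <- x$hits$motif_id[x$hits$present]
  cat("  motifs:", if (length(pres)) paste(pres, collapse = ", ") else "none", "\n")
  invisible(x)
}

#' Serialize feature profiles to a Table 2-like TSV layout
#'
#' @param features list of `mip_features`.
#' @param subfamily optional named vector of subfamily labels.
#' @param path optional output file; when NULL the data.frame is returned only.
#' @return data.frame with columns subfamily, protein, H2, H5, LE1, LE2,
#'   NPA_loopB, NPA_loopE, substrate.
#' @export
features_table <- function(features, subfamily = NULL, path = NULL) {
  df <- do.call(rbind, lapply(features, function(f) data.frame(
    subfamily = if (!is.null(subfamily)) subfamily[[f$seq_id]] %||% "" else "",
    protein = f$seq_id,
    H2 = f$filter$h2, H5 = f$filter$h5, LE1 = f$filter$le1, LE2 = f$filter$le2,
    NPA_loopB = f$npa$npa1, NPA_loopE = f$npa$npa2,
    substrate = f$substrate_class, stringsAsFactors = FALSE)))
  rownames(df) <- NULL
  if (!is.null(path))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  df
}
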