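# Query-to-profile alignment: a deterministic global (Needleman-Wunsch style)
# aligner with affine gaps against the column-wise residue profile of the
# reference alignment, so that every reference column annotation transfers to
# the query.

#' Construct a MIP protein sequence object
#'
#' @param id sequence identifier.
#' @param residues amino-acid string (20 standard letters plus X).
#' @param species_tag optional two-letter genus/species code; guessed from a
#'   leading capital-lowercase pair of `id` when missing.
#' @return object of class `mip_seq` with a `length_plausible` flag (FALSE
#'   outside 150-600 residues).
#' @export
mip_sequence <- function(id, residues, species_tag = NULL) {
  residues <- toupper(residues)
  if (!nzchar(residues)) stop("input error: empty sequence: ", id)
  if (grepl("-", residues, fixed = TRUE))
    stop("input error: gap characters in unaligned sequence: ", id)
  if (grepl(paste0("[^", paste(.mip_aa, collapse = ""), "X]"), residues))
    stop("input error: non amino-acid characters in ", id)
  if (is.null(species_tag)) {
    m <- regmatches(id, regexpr("^[A-Z][a-z]{1,2}", id))
    species_tag <- if (length(m)) m else ""
  }
  n <- nchar(residues)
  structure(list(id = id, residues = residues, length = n,
                 species_tag = species_tag,
                 length_plausible = n >= 150L && n <= 600L),
            class = "mip_seq")
}

#' Alignment parameters
#'
#' @param matrix substitution matrix name (only `"BLOSUM62"` is shipped;
#'   residue X scores 0 against everything).
#' @param gap_open,gap_extend affine gap penalties; a gap of length L costs
#'   `gap_open + L * gap_extend`.
#' @return list of class `mip_align_params`.
#' @export
align_params <- function(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1) {
  stopifnot(gap_open >= 0, gap_extend >= 0)
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend), class = "mip_align_params")
}

.mip_submat_cache <- new.env(parent = emptyenv())

# 21x21 substitution matrix over the 20 standard residues + X (X scores 0)
.mip_submat <- function(name = "BLOSUM62") {
  key <- name
  if (!is.null(.mip_submat_cache[[key]])) return(.mip_submat_cache[[key]])
  if (name != "BLOSUM62") stop("input error: unknown substitution matrix: ", name)
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  B <- e$BLOSUM62[.mip_aa, .mip_aa]
  B <- rbind(cbind(B, X = 0), X = 0)
  rownames(B)[21L] <- "X"
  .mip_submat_cache[[key]] <- B
  B
}

# residue frequency profile of an alignment matrix: list(freq = ncol x 21,
# occupancy = fraction of non-gap rows per column)
.mip_profile <- function(aln) {
  alphabet <- c(.mip_aa, "X")
  m <- ncol(aln)
  freq <- matrix(0, nrow = m, ncol = 21L, dimnames = list(NULL, alphabet))
  occ <- numeric(m)
  for (j in seq_len(m)) {
    col <- aln[, j]
    col <- col[col != "-"]
    occ[j] <- length(col) / nrow(aln)
    if (length(col)) {
      tab <- table(factor(col, levels = alphabet))
      freq[j, ] <- as.numeric(tab) / length(col)
    }
  }
  list(freq = freq, occupancy = occ)
}

# score matrix S[i, j]: query residue i against profile column j.  The
# weighted-average substitution score counts each non-gap profile row with
# its frequency; profile gap positions contribute the gap-extension penalty,
# so mostly-gapped (insertion) columns cannot out-score well-occupied ones.
.mip_profile_scores <- function(qres, profile, B, ge = 1) {
  colsc <- profile$freq %*% B                       # m x 21, non-gap average
  colsc <- colsc * profile$occupancy - (1 - profile$occupancy) * ge
  S <- colsc[, match(qres, colnames(B)), drop = FALSE]  # m x n
  t(S)                                              # n x m
}

# Global affine-gap DP.  Returns the three (n+1)x(m+1) state matrices and the
# final score.  States: M diagonal, X consumes a query residue (gap in the
# reference), Y consumes a reference column (gap in the query).  Y-state gap
# costs are position specific: skipping reference column j costs
# `w[j] * (open|extend)`, with `w` the profile occupancy, so that skipping a
# mostly-gapped insertion column is nearly free (a gap there is gapped in
# most reference rows already) while skipping a fully occupied column pays
# the full penalty.
.mip_nw <- function(S, go, ge, w = rep(1, ncol(S))) {
  n <- nrow(S); m <- ncol(S)
  NEG <- -1e9
  goy <- go * w
  gey <- ge * w
  G <- cumsum(gey)                       # prefix sums of extension costs
  G0 <- c(0, G[-m])                      # G_{j-1}
  M <- X <- Y <- matrix(NEG, n + 1L, m + 1L)
  M[1L, 1L] <- 0
  if (m > 0) Y[1L, 2L:(m + 1L)] <- -goy[1L] - G
  if (n > 0) X[2L:(n + 1L), 1L] <- -go - ge * seq_len(n)
  for (i in seq_len(n)) {
    ip <- i + 1L
    best_prev <- pmax(M[i, ], X[i, ], Y[i, ])
    M[ip, 2L:(m + 1L)] <- S[i, ] + best_prev[1L:m]
    X[ip, ] <- pmax(M[i, ] - go - ge, X[i, ] - ge)
    # Y along the row via the running-maximum form of the affine recurrence:
    # Y[ip, j+1] = -G_j + max_{j' <= j} (M[ip, j'] - goy_{j'} + G_{j'-1})
    if (m > 0) {
      h <- M[ip, 1L:m] - goy + G0
      Y[ip, 2L:(m + 1L)] <- cummax(h) - G
    }
  }
  list(M = M, X = X, Y = Y,
       score = max(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L]))
}

# deterministic traceback; tie-breaking prefers diagonal, then up (query
# residue against a reference gap), then left (reference column skipped)
.mip_traceback <- function(dp, S, go, ge, w = rep(1, ncol(S))) {
  eps <- 1e-9
  n <- nrow(S); m <- ncol(S)
  i <- n; j <- m
  cand <- c(M = dp$M[n + 1L, m + 1L], X = dp$X[n + 1L, m + 1L],
            Y = dp$Y[n + 1L, m + 1L])
  state <- names(cand)[which(cand >= max(cand) - eps)[1L]]
  col_map <- rep(NA_integer_, m)
  ins_at <- integer(0)    # query residue indices inserted, with the column after
  ins_after <- integer(0)
  while (i > 0L || j > 0L) {
    if (state == "M") {
      col_map[j] <- i
      prev <- c(M = dp$M[i, j], X = dp$X[i, j], Y = dp$Y[i, j])
      state <- names(prev)[which(prev >= max(prev) - eps)[1L]]
      i <- i - 1L; j <- j - 1L
    } else if (state == "X") {
      ins_at <- c(ins_at, i); ins_after <- c(ins_after, j)
      from_m <- dp$M[i, j + 1L] - go - ge
      state <- if (from_m >= dp$X[i, j + 1L] - ge - eps) "M" else "X"
      i <- i - 1L
      if (i == 0L && j == 0L) break
    } else {
      from_m <- dp$M[i + 1L, j] - (go + ge) * w[j]
      state <- if (from_m >= dp$Y[i + 1L, j] - ge * w[j] - eps) "M" else "Y"
      j <- j - 1L
      if (i == 0L && j == 0L) break
    }
    if (i == 0L && j == 0L) break
  }
  list(col_map = col_map, ins_at = rev(ins_at), ins_after = rev(ins_after))
}

#' Align a query sequence to the reference profile
#'
#' Global profile alignment of a query against the column-wise residue profile
#' of the reference alignment.  Deterministic for fixed parameters: traceback
#' ties prefer diagonal, then up, then left.
#'
#' @param query a `mip_seq`, or a plain character string (an id is invented).
#' @param ref a `mip_reference`.
#' @param params an [align_params()] list.
#' @param exclude optional reference row ids excluded from the profile (used
#'   e.g. when re-aligning a reference row against the others).
#' @return object of class `mip_aligned` with fields `seq`, `col_map`
#'   (reference column to query residue index, NA at gaps), `inserted`
#'   (data.frame after_col/run for query residues matching no column), and
#'   `score`.
#' @export
align_to_profile <- function(query, ref, params = align_params(),
                             exclude = NULL) {
  if (is.character(query)) query <- mip_sequence("query", query)
  qres <- strsplit(query$residues, "")[[1]]
  if (length(qres) < 30L)
    stop("input error: query shorter than 30 residues: ", query$id)
  if (all(qres == "X"))
    stop("input error: all-X query: ", query$id)
  aln <- ref$aln
  if (!is.null(exclude)) aln <- aln[setdiff(rownames(aln), exclude), , drop = FALSE]
  B <- .mip_submat(params$matrix)
  prof <- .mip_profile(aln)
  S <- .mip_profile_scores(qres, prof, B, params$gap_extend)
  dp <- .mip_nw(S, params$gap_open, params$gap_extend, prof$occupancy)
  tb <- .mip_traceback(dp, S, params$gap_open, params$gap_extend,
                       prof$occupancy)
  inserted <- if (length(tb$ins_at)) {
    runs <- split(tb$ins_at, cumsum(c(1L, diff(tb$ins_at) != 1L |
                                        diff(tb$ins_after) != 0L)))
    data.frame(
      after_col = vapply(runs, function(r)
        tb$ins_after[match(r[1L], tb$ins_at)], integer(1)),
      run = vapply(runs, function(r) paste(qres[r], collapse = ""), character(1)),
      stringsAsFactors = FALSE, row.names = NULL)
  } else data.frame(after_col = integer(0), run = character(0))
  structure(list(seq = query, col_map = tb$col_map, inserted = inserted,
                 score = dp$score), class = "mip_aligned")
}

#' @export
print.mip_aligned <- function(x, ...) {
  cat("mip_aligned:", x$seq$id, "-", sum(!is.na(x$col_map)),
      "residues on reference columns,", nrow(x$inserted),
      "insertion run(s), score", round(x$score, 1), "\n")
  invisible(x)
}

# residues of an aligned query at given reference columns ("-" where unmapped)
aligned_residues <- function(aq, cols) {
  qres <- strsplit(aq$seq$residues, "")[[1]]
  idx <- aq$col_map[cols]
  out <- rep("-", length(cols))
  out[!is.na(idx)] <- qres[idx[!is.na(idx)]]
  out
}

# reference row wrapped as an aligned query (identity column map)
ref_row_aligned <- function(ref, id) {
  row <- ref$aln[id, ]
  keep <- row != "-"
  cm <- rep(NA_integer_, length(row))
  cm[keep] <- seq_len(sum(keep))
  structure(list(
    seq = mip_sequence(id, paste(row[keep], collapse = "")),
    col_map = cm,
    inserted = data.frame(after_col = integer(0), run = character(0)),
    score = NA_real_), class = "mip_aligned")
}

#' Restrict an aligned query to the phylogenetic core interval
#'
#' Drops column assignments and insertion runs outside the reference
#' `core_interval` (the highly divergent N- and C-terminal regions are thereby
#' excluded, as in the master alignment's dotted-line delimitation).
#' Idempotent.
#'
#' @param aq a `mip_aligned`.
#' @param ref the `mip_reference` it was aligned against.
#' @return a `mip_aligned` covering only core columns.
#' @export
trim_to_core <- function(aq, ref) {
  ci <- ref$core_interval
  cm <- aq$col_map
  cols <- seq_along(cm)
  cm[cols < ci[1] | cols > ci[2]] <- NA_integer_
  ins <- aq$inserted
  ins <- ins[ins$after_col >= ci[1] & ins$after_col < ci[2], , drop = FALSE]
  if (all(is.na(cm)))
    warning("empty core: query aligns entirely outside the core interval")
  out <- aq
  out$col_map <- cm
  out$inserted <- ins
  attr(out, "trimmed") <- TRUE
  out
}

#' Pairwise similarity annotation string
#'
#' Aligns two sequences globally and annotates each aligned column with `*`
#' (identity), `:` (strong similarity group), `.` (weak similarity group) or a
#' space (no similarity or gap), following the Clustal residue-group
#' convention.  With `region` and `ref` given, each sequence is first aligned
#' to the reference profile and only the residues mapping to the region
#' (an element name such as `"LE"` or a column range) are compared.
#'
#' @param a,b `mip_seq` objects or character strings.
#' @param region optional element name or length-2 column range.
#' @param ref `mip_reference`, required when `region` is given.
#' @param params alignment parameters.
#' @return the annotation string; the aligned sequences and the alignment
#'   score are attached as attributes `a_aln`, `b_aln` and `score`.
#' @export
similarity_string <- function(a, b, region = NULL, ref = NULL,
                              params = align_params()) {
  if (is.character(a)) a <- mip_sequence("a", a)
  if (is.character(b)) b <- mip_sequence("b", b)
  if (!is.null(region)) {
    if (is.null(ref)) stop("input error: region comparison requires a reference")
    cols <- region_columns(ref, region)
    sub_of <- function(s) {
      aq <- align_to_profile(s, ref, params)
      res <- aligned_residues(aq, cols)
      paste(res[res != "-"], collapse = "")
    }
    a <- mip_sequence(a$id, sub_of(a))
    b <- mip_sequence(b$id, sub_of(b))
  }
  B <- .mip_submat(params$matrix)
  ares <- strsplit(a$residues, "")[[1]]
  bres <- strsplit(b$residues, "")[[1]]
  S <- matrix(B[ares, bres], nrow = length(ares))
  dp <- .mip_nw(S, params$gap_open, params$gap_extend)
  tb <- .mip_traceback(dp, S, params$gap_open, params$gap_extend)
  # expand to aligned strings
  acol <- character(0); bcol <- character(0)
  bi_used <- which(!is.na(tb$col_map))
  # walk reference (= b) columns, interleaving insertions of a
  ins <- split(tb$ins_at, tb$ins_after)
  emit_ins <- function(j) {
    k <- ins[[as.character(j)]]
    if (!is.null(k)) {
      acol <<- c(acol, ares[k]); bcol <<- c(bcol, rep("-", length(k)))
    }
  }
  emit_ins(0L)
  for (j in seq_along(bres)) {
    ai <- tb$col_map[j]
    acol <- c(acol, if (is.na(ai)) "-" else ares[ai])
    bcol <- c(bcol, bres[j])
    emit_ins(j)
  }
  sym <- vapply(seq_along(acol), function(k) {
    x <- acol[k]; y <- bcol[k]
    if (x == "-" || y == "-") return(" ")
    if (x == y) return("*")
    if (any(vapply(.mip_strong_groups, function(g)
      grepl(x, g, fixed = TRUE) && grepl(y, g, fixed = TRUE), logical(1))))
      return(":")
    if (any(vapply(.mip_weak_groups, function(g)
      grepl(x, g, fixed = TRUE) && grepl(y, g, fixed = TRUE), logical(1))))
      return(".")
    " "
  }, character(1))
  out <- paste(sym, collapse = "")
  attr(out, "a_aln") <- paste(acol, collapse = "")
  attr(out, "b_aln") <- paste(bcol, collapse = "")
  attr(out, "score") <- dp$score
  out
}

#' Columns of a named element or explicit column range
#' @param ref a `mip_reference`.
#' @param region element name (e.g. `"LE"`) or length-2 integer vector.
#' @return integer vector of alignment columns.
#' @export
region_columns <- function(ref, region) {
  if (is.numeric(region)) {
    stopifnot(length(region) == 2L)
    return(seq.int(region[1], region[2]))
  }
  e <- ref$elements[ref$elements$name == region, ]
  if (nrow(e) != 1L) stop("input error: unknown element: ", region)
  seq.int(e$start_col, e$end_col)
}
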