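# Distance-based placement and subfamily classification: protein distances on
# the trimmed core, neighbor joining with a fixed tie-break, bootstrap
# support, clade-based placement, and the motif-evidence rule table.

#' Character matrix of reference rows plus aligned queries over core columns
#'
#' @param ref a `mip_reference`.
#' @param aligned named list of `mip_aligned` queries (may be empty).
#' @param include_refs include the reference rows themselves.
#' @return character matrix (sequences x core columns).
#' @export
core_matrix <- function(ref, aligned = list(), include_refs = TRUE) {
  ci <- ref$core_interval
  cols <- seq.int(ci[1], ci[2])
  rows <- list()
  if (include_refs)
    for (id in rownames(ref$aln)) rows[[id]] <- ref$aln[id, cols]
  for (aq in aligned) rows[[aq$seq$id]] <- aligned_residues(aq, cols)
  do.call(rbind, rows)
}

#' Pairwise protein distances
#'
#' p-distance over shared non-gap columns, with an optional Kimura-style
#' correction for multiple hits, `d = -ln(1 - p - p^2/5)`.  Pairs overlapping
#' fewer than `min_overlap` columns (or whose corrected distance diverges) are
#' flagged and imputed ultrametrically from the remaining distances.
#'
#' @param x character matrix (sequences x alignment columns, `"-"` gaps).
#' @param correction `"kimura"` (default) or `"none"`.
#' @param min_overlap minimum number of shared non-gap columns.
#' @return object of class `mip_dist`: list with `ids`, `d` (symmetric
#'   matrix), and `flagged` (data.frame of imputed pairs).
#' @export
pairwise_distances <- function(x, correction = c("kimura", "none"),
                               min_overlap = 50L) {
  correction <- match.arg(correction)
  if (nrow(x) < 3L) stop("input error: need at least 3 sequences")
  ids <- rownames(x)
  n <- nrow(x)
  xi <- matrix(match(x, c(.mip_aa, "X")), nrow = n)  # NA at gaps
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  flagged <- list()
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    ok <- !is.na(xi[i, ]) & !is.na(xi[j, ])
    L <- sum(ok)
    if (L < min_overlap) {
      d[i, j] <- d[j, i] <- NA_real_
      flagged[[length(flagged) + 1L]] <-
        data.frame(a = ids[i], b = ids[j], reason = "low_overlap")
      next
    }
    p <- sum(xi[i, ok] != xi[j, ok]) / L
    dij <- if (correction == "kimura") {
      arg <- 1 - p - p^2 / 5
      if (arg <= 0) NA_real_ else -log(arg)
    } else p
    if (is.na(dij)) {
      flagged[[length(flagged) + 1L]] <-
        data.frame(a = ids[i], b = ids[j], reason = "saturated")
    }
    d[i, j] <- d[j, i] <- dij
  }
  # ultrametric imputation for flagged pairs
  if (any(is.na(d))) {
    mx <- max(d, na.rm = TRUE)
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
      if (is.na(d[i, j])) {
        k <- which(!is.na(d[i, ]) & !is.na(d[j, ]) & seq_len(n) != i &
                     seq_len(n) != j)
        d[i, j] <- d[j, i] <- if (length(k))
          max(pmin(d[i, k], d[j, k])) else mx
      }
    }
  }
  structure(list(ids = ids, d = d,
                 flagged = if (length(flagged)) do.call(rbind, flagged)
                           else data.frame(a = character(0), b = character(0),
                                           reason = character(0))),
            class = "mip_dist")
}

#' Write a distance matrix in PHYLIP square format
#' @param D a `mip_dist`.
#' @param path output file.
#' @export
write_phylip <- function(D, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", length(D$ids)), con)
  for (i in seq_along(D$ids))
    writeLines(paste(formatC(D$ids[i], width = -12),
                     paste(sprintf("%.6f", D$d[i, ]), collapse = " ")), con)
  invisible(path)
}

#' Neighbor-joining tree
#'
#' Standard neighbor joining with a deterministic tie-break: among joins with
#' equal Q criterion the lowest index pair (by current row order) is joined.
#' Negative branch lengths are clamped to zero.  Fewer than 4 sequences yield
#' a star/trivial topology with a warning.
#'
#' @param D a `mip_dist` or a symmetric numeric matrix with dimnames.
#' @return an unrooted `phylo` tree (ape).
#' @export
nj_tree <- function(D) {
  if (inherits(D, "mip_dist")) d <- D$d else d <- as.matrix(D)
  ids <- rownames(d)
  if (is.null(ids)) stop("input error: distance matrix must have dimnames")
  if (any(!is.finite(d))) stop("input error: non-finite distances")
  n <- nrow(d)
  quote_lab <- function(x) gsub("[,();: ]", "_", x)
  labs <- quote_lab(ids)
  if (n < 4L) {
    warning("fewer than 4 sequences: trivial topology returned")
    if (n == 2L)
      return(ape::read.tree(text = sprintf("(%s:%f,%s:%f);", labs[1],
                                           d[1, 2] / 2, labs[2], d[1, 2] / 2)))
    b <- c((d[1, 2] + d[1, 3] - d[2, 3]) / 2,
           (d[1, 2] + d[2, 3] - d[1, 3]) / 2,
           (d[1, 3] + d[2, 3] - d[1, 2]) / 2)
    b <- pmax(b, 0)
    return(ape::read.tree(text = sprintf("(%s:%f,%s:%f,%s:%f);",
                                         labs[1], b[1], labs[2], b[2],
                                         labs[3], b[3])))
  }
  node <- labs
  while (length(node) > 3L) {
    m <- nrow(d)
    r <- rowSums(d)
    Q <- (m - 2) * d - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    best <- NULL
    for (i in seq_len(m - 1L)) {
      j <- which(Q[i, ] <= qmin + 1e-12 & seq_len(m) > i)
      if (length(j)) { best <- c(i, j[1L]); break }
    }
    i <- best[1L]; j <- best[2L]
    bi <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    bj <- d[i, j] - bi
    bi <- max(bi, 0); bj <- max(bj, 0)
    new_lab <- sprintf("(%s:%.10f,%s:%.10f)", node[i], bi, node[j], bj)
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    node <- c(node[keep], new_lab)
    dimnames(d2) <- list(NULL, NULL)
    d <- d2
  }
  b <- c((d[1, 2] + d[1, 3] - d[2, 3]) / 2,
         (d[1, 2] + d[2, 3] - d[1, 3]) / 2,
         (d[1, 3] + d[2, 3] - d[1, 2]) / 2)
  b <- pmax(b, 0)
  txt <- sprintf("(%s:%.10f,%s:%.10f,%s:%.10f);",
                 node[1], b[1], node[2], b[2], node[3], b[3])
  tr <- ape::read.tree(text = txt)
  tr$tip.label <- ids[match(tr$tip.label, labs)]
  tr
}

#' Neighbor-joining tree with bootstrap support
#'
#' Builds the tree on the full column set, then resamples columns with
#' replacement `n_reps` times; support of each internal bipartition is the
#' percentage of replicate trees containing it.  Nodes below
#' `collapse_threshold` keep their support value but are flagged.
#'
#' @param x character matrix (sequences x core columns).
#' @param n_reps number of bootstrap replicates (>= 10).
#' @param seed integer seed (results are a pure function of input and seed).
#' @param correction distance correction, see [pairwise_distances()].
#' @param collapse_threshold support percentage below which nodes are flagged
#'   as collapsed.
#' @return object of class `mip_boottree`: list with `tree` (phylo, node
#'   labels = support %), `n_reps`, `seed`, `collapse_threshold`.
#' @export
bootstrap_tree <- function(x, n_reps = 100L, seed = 1L,
                           correction = "kimura", collapse_threshold = 50) {
  if (n_reps < 1L) stop("input error: n_reps must be >= 1")
  main <- nj_tree(pairwise_distances(x, correction))
  set.seed(seed)
  reps <- vector("list", n_reps)
  for (b in seq_len(n_reps)) {
    idx <- sample.int(ncol(x), replace = TRUE)
    reps[[b]] <- nj_tree(pairwise_distances(x[, idx, drop = FALSE], correction))
  }
  counts <- ape::prop.clades(main, reps, rooted = FALSE)
  support <- round(100 * counts / n_reps)
  main$node.label <- as.character(support)
  structure(list(tree = main, n_reps = n_reps, seed = seed,
                 collapse_threshold = collapse_threshold,
                 support = support), class = "mip_boottree")
}

#' @export
print.mip_boottree <- function(x, ...) {
  cat("mip_boottree:", length(x$tree$tip.label), "tips,", x$n_reps,
      "bootstrap replicates (seed", x$seed, ")\n")
  invisible(x)
}

#' Place a query into the reference subfamilies
#'
#' Finds the smallest well-supported clade (bootstrap support at or above the
#' collapse threshold) that groups the query with reference sequences of a
#' single subfamily.  A query terminal branch longer than twice the median
#' terminal branch is flagged as a potential long-branch artifact.
#'
#' @param bt a `mip_boottree` built on references plus queries.
#' @param query_id tip label of the query.
#' @param subfamily named vector: reference tip label -> subfamily.
#' @param threshold minimum support (%); defaults to the tree's collapse
#'   threshold.
#' @return object of class `mip_placement` with `query_id`,
#'   `sister_subfamily` (label or `"none"`), `support`, `clade_size`,
#'   `long_branch`.
#' @export
place_query <- function(bt, query_id, subfamily,
                        threshold = bt$collapse_threshold) {
  tr <- bt$tree
  tips <- tr$tip.label
  if (!query_id %in% tips) stop("input error: query not in tree: ", query_id)
  parts <- ape::prop.part(tr)
  labs <- attr(parts, "labels")
  support <- suppressWarnings(as.numeric(tr$node.label))
  best <- NULL
  refs <- names(subfamily)
  for (k in seq_along(parts)) {
    if (k == 1L) next  # root pseudo-clade (all tips)
    s <- support[k]
    if (is.na(s) || s < threshold) next
    clade <- labs[parts[[k]]]
    side <- if (query_id %in% clade) clade else setdiff(tips, clade)
    in_refs <- intersect(side, refs)
    if (!length(in_refs)) next
    fams <- unique(subfamily[in_refs])
    if (length(fams) != 1L) next
    if (is.null(best) || length(side) < best$size ||
        (length(side) == best$size && s > best$support))
      best <- list(fam = fams, support = s, size = length(side))
  }
  # long-branch diagnostic
  term <- tr$edge.length[tr$edge[, 2] <= length(tips)]
  qb <- tr$edge.length[tr$edge[, 2] == match(query_id, tips)]
  long_branch <- length(qb) == 1L && qb > 2 * stats::median(term)
  structure(list(
    query_id = query_id,
    sister_subfamily = if (is.null(best)) "none" else unname(best$fam),
    support = if (is.null(best)) NA_real_ else best$support,
    clade_size = if (is.null(best)) NA_integer_ else best$size,
    long_branch = long_branch), class = "mip_placement")
}

#' Default classification rule parameters
#' @param placement_support minimum bootstrap support for a placement call.
#' @param prenpa1_max maximum pre-NPA1 loop length for the GlpF-like rule.
#' @param cterm_min minimum C-terminal positive-residue fraction (MIPC rule).
#' @param filter_mismatch_max allowed mismatches to the PIP-type filter.
#' @export
classify_rules <- function(placement_support = 50, prenpa1_max = 28L,
                           cterm_min = 0.3, filter_mismatch_max = 1L) {
  list(placement_support = placement_support, prenpa1_max = prenpa1_max,
       cterm_min = cterm_min, filter_mismatch_max = filter_mismatch_max)
}

.mip_call_labels <- c("PIP", "GIP", "MIPA", "MIPB", "MIPC", "MIPD", "MIPE",
                      "TIP", "NIP", "SIP", "XIP", "HIP")

# motif-evidence vote; returns list(label or NA, evidence data.frame)
.mip_vote <- function(f, rules) {
  pres <- stats::setNames(f$hits$present, f$hits$motif_id)
  obs <- f$observed_sites
  arr <- c(f$filter$h2, f$filter$h5, f$filter$le1, f$filter$le2)
  pip_filter_mm <- sum(arr[1] != "F", arr[2] != "H",
                       !(arr[3] %in% c("C", "T")), arr[4] != "R")
  ct <- f$cterm_positive_fraction
  rule <- list(
    PIP  = isTRUE(pres["kxsxxr"]) && isTRUE(pres["h193"]) &&
           pip_filter_mm <= rules$filter_mismatch_max,
    GIP  = isTRUE(pres["dxxxr"]) &&
           f$loop_lengths["LB_preNPA1"] < rules$prenpa1_max,
    MIPC = !isTRUE(pres["h2_gly"]) && !isTRUE(pres["h3_gln"]) &&
           substr(obs[["h3_gln"]], 1, 1) %in% c("S", "T") &&
           identical(obs[["h6_pro"]], "A") &&
           !is.na(ct) && ct >= rules$cterm_min,
    MIPD = !isTRUE(pres["h6_pro"]) &&
           substr(obs[["h6_pro"]], 1, 1) %in% c("Q", "E", "H") &&
           isTRUE(pres["loopC_cys"]) && isTRUE(pres["postHE_cys"]),
    MIPE = isTRUE(pres["dgcs"]) && isTRUE(pres["lxxn"]) &&
           pip_filter_mm <= rules$filter_mismatch_max,
    MIPB = !f$npa$canonical1 && !f$npa$canonical2 && !isTRUE(pres["pre_npa1"])
  )
  rule$MIPE <- rule$MIPE && !rule$PIP  # MIPEs are PIP-like but fail PIP rules
  ev <- data.frame(rule_id = paste0("motif_", names(rule)),
                   pass = unlist(rule), stringsAsFactors = FALSE)
  hit <- names(rule)[unlist(rule)]
  list(label = if (length(hit)) hit[1L] else NA_character_, evidence = ev)
}

#' Combine placement and motif evidence into a subfamily call
#'
#' A well-supported placement into a single-subfamily reference clade wins;
#' without one, the motif-evidence rule table votes.  When a confident
#' placement and a confident motif vote name different subfamilies the call is
#' `unclassified` with conflict evidence.
#'
#' @param features a `mip_features`.
#' @param placement a `mip_placement` for the same sequence (or NULL).
#' @param rules a [classify_rules()] list.
#' @return object of class `mip_call` with `seq_id`, `label`, `evidence`,
#'   `proposed_name` (filled by [propose_name()]).
#' @export
place_and_classify <- function(features, placement = NULL,
                               rules = classify_rules()) {
  vote <- .mip_vote(features, rules)
  pl_label <- NA_character_
  pl_support <- NA_real_
  if (!is.null(placement)) {
    if (!identical(placement$query_id, features$seq_id))
      stop("input error: placement and features refer to different sequences")
    if (placement$sister_subfamily %in% .mip_call_labels &&
        !is.na(placement$support) &&
        placement$support >= rules$placement_support) {
      pl_label <- placement$sister_subfamily
      pl_support <- placement$support
    }
  }
  ev <- rbind(
    data.frame(rule_id = "placement",
               pass = !is.na(pl_label), stringsAsFactors = FALSE),
    vote$evidence)
  label <- if (!is.na(pl_label) && !is.na(vote$label) &&
               pl_label != vote$label) {
    ev <- rbind(ev, data.frame(rule_id = "conflict_placement_vs_motifs",
                               pass = FALSE))
    "unclassified"
  } else if (!is.na(pl_label)) pl_label
  else if (!is.na(vote$label)) vote$label
  else "unclassified"
  structure(list(seq_id = features$seq_id, label = label,
                 placement_support = pl_support,
                 long_branch = isTRUE(placement$long_branch),
                 evidence = ev, proposed_name = NA_character_),
            class = "mip_call")
}

#' @export
print.mip_call <- function(x, ...) {
  cat(x$seq_id, "->", x$label,
      if (!is.na(x$placement_support))
        paste0("(placement ", x$placement_support, "%)") else "(motif vote)",
      "\n")
  invisible(x)
}

#' Parse a MIP isoform name
#'
#' Splits names of the form `<Tag><LABEL><group>;<isoform>` (e.g.
#' `CcPIP4;1`, `PbcvMT325GIP1;1`).
#'
#' @param x character name.
#' @return list with `species_tag`, `label`, `group`, `isoform`.
#' @export
parse_mip_name <- function(x) {
  pat <- "^(.*?)(PIP|TIP|NIP|SIP|XIP|HIP|GIP|MIP[A-E])([0-9]+);([0-9]+)$"
  if (!grepl(pat, x)) stop("registry error: malformed MIP name: ", x)
  m <- regmatches(x, regexec(pat, x))[[1]]
  list(species_tag = m[2], label = m[3], group = as.integer(m[4]),
       isoform = as.integer(m[5]))
}

#' Propose the next free isoform name
#'
#' Builds `<Tag><LABEL><group>;<isoform>`, where the isoform number is the
#' next free integer within (tag, label, group).  Without an explicit group,
#' the highest existing group for the same tag and label is reused; a novel
#' (tag, label) starts at group 1.
#'
#' @param call a `mip_call` or a subfamily label.
#' @param species_tag species tag (e.g. `"Cc"`).
#' @param existing_names character vector of registered names.
#' @param group optional explicit group number.
#' @return the proposed name.
#' @export
propose_name <- function(call, species_tag, existing_names = character(0),
                         group = NULL) {
  label <- if (inherits(call, "mip_call")) call$label else call
  if (!label %in% .mip_call_labels)
    stop("input error: cannot propose a name for label: ", label)
  parsed <- lapply(existing_names, parse_mip_name)
  same <- vapply(parsed, function(p)
    p$species_tag == species_tag && p$label == label, logical(1))
  if (is.null(group)) {
    group <- if (any(same)) max(vapply(parsed[same], `[[`, integer(1), "group"))
             else 1L
  }
  iso <- vapply(parsed[same], function(p)
    if (p$group == group) p$isoform else 0L, integer(1))
  isoform <- if (length(iso)) max(iso) + 1L else 1L
  if (isoform < 1L) isoform <- 1L
  sprintf("%s%s%d;%d", species_tag, label, group, isoform)
}
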