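# User-facing synthetic data generators: families of subfamily-typical
# sequences with a truth table, gene models with introns, and two-group
# divergence sets for the enrichment statistic.

#' Specification for a synthetic family
#'
#' @param subfamilies subfamily template names to draw from.
#' @param n_per_subfamily sequences generated per subfamily.
#' @param mutation_rate per-column substitution rate applied outside the
#'   protected feature columns.
#' @param seed integer seed (< 2^31); output is a pure function of the spec.
#' @param ablations named list of switches: `no_protect = TRUE` also mutates
#'   the diagnostic feature columns; `canonical_npa = TRUE` forces both NPA
#'   boxes to the canonical `NPA`.
#' @return object of class `mip_synth_spec`.
#' @export
synth_spec <- function(subfamilies = c("PIP", "GIP", "MIPA", "MIPB",
                                       "MIPC", "MIPD", "MIPE"),
                       n_per_subfamily = 3L, mutation_rate = 0.05,
                       seed = 1L, ablations = list()) {
  if (seed >= 2^31 || seed < 0) stop("input error: seed must be in [0, 2^31)")
  known <- names(.mip_templates())
  bad <- setdiff(subfamilies, known)
  if (length(bad))
    stop("input error: unknown subfamily template(s): ",
         paste(bad, collapse = ", "))
  if (mutation_rate < 0 || mutation_rate > 1)
    stop("input error: mutation_rate must be in [0, 1]")
  structure(list(subfamilies = subfamilies,
                 n_per_subfamily = as.integer(n_per_subfamily),
                 mutation_rate = mutation_rate, seed = as.integer(seed),
                 ablations = ablations), class = "mip_synth_spec")
}

#' Generate a synthetic family with its truth table
#'
#' Each sequence is its subfamily template mutated at `mutation_rate` outside
#' the protected feature columns (landmark sites, motif windows, ar/R and NPA
#' columns), so the encoded features are true by construction.  The truth
#' table records, per sequence, the subfamily and the feature values read
#' directly off the generating alignment row.
#'
#' @param spec a [synth_spec()].
#' @return list with `proteins` (named character), `rows` (character matrix of
#'   generating alignment rows), `truth` (data.frame: id, subfamily, h2, h5,
#'   le1, le2, npa1, npa2), `spec`.
#' @export
generate_family <- function(spec) {
  stopifnot(inherits(spec, "mip_synth_spec"))
  templates <- .mip_templates()
  protected <- if (isTRUE(spec$ablations$no_protect)) integer(0)
               else .mip_protected_cols()
  el <- .mip_elements()
  npa1_cols <- seq.int(el[el$name == "NPA1", "start_col"],
                       el[el$name == "NPA1", "end_col"])
  npa2_cols <- seq.int(el[el$name == "NPA2", "start_col"],
                       el[el$name == "NPA2", "end_col"])
  arr <- .mip_arr_columns()
  rows <- list()
  truth <- list()
  counter <- 0L
  for (fam in spec$subfamilies) for (i in seq_len(spec$n_per_subfamily)) {
    counter <- counter + 1L
    row <- .mip_mutate(templates[[fam]], rate = spec$mutation_rate,
                       seed = .mip_derive_seed(spec$seed, 1000, counter),
                       protected = protected)
    if (isTRUE(spec$ablations$canonical_npa)) {
      row[npa1_cols] <- c("N", "P", "A")
      row[npa2_cols] <- c("N", "P", "A")
    }
    id <- sprintf("SYN_%s_%02d", fam, i)
    rows[[id]] <- row
    truth[[id]] <- data.frame(
      id = id, subfamily = fam,
      h2 = row[arr["H2"]], h5 = row[arr["H5"]],
      le1 = row[arr["LE1"]], le2 = row[arr["LE2"]],
      npa1 = paste(row[npa1_cols], collapse = ""),
      npa2 = paste(row[npa2_cols], collapse = ""),
      stringsAsFactors = FALSE)
  }
  mat <- do.call(rbind, rows)
  proteins <- vapply(rows, function(r) paste(r[r != "-"], collapse = ""),
                     character(1))
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(proteins = proteins, rows = mat, truth = truth, spec = spec)
}

# random intron sequence: GT ... AG, interior drawn uniformly
.mip_intron_seq <- function(len) {
  if (len < 4L) stop("input error: intron length must be >= 4")
  paste(c("GT", sample(c("A", "C", "G", "T"), len - 4L, replace = TRUE), "AG"),
        collapse = "")
}

#' Generate gene models encoding given proteins
#'
#' Back-translates each protein (most-frequent-codon table plus a `TAA`
#' stop), splits the CDS at the planned intron junctions and embeds the exons
#' in a genomic sequence with `GT..AG` introns of random length between
#' `intron_len[1]` and `intron_len[2]`.  Genes assigned to the minus strand
#' are stored reverse-complemented with flipped coordinates, so that
#' [translate_model()] recovers the protein exactly.
#'
#' @param proteins named character vector of protein sequences.
#' @param plans named list (per gene) of data.frames with columns
#'   `codon_index`, `phase`; `NULL` draws `n_introns` random junctions.
#' @param n_introns introns per gene when `plans` is NULL.
#' @param minus_strand character vector of gene ids placed on the minus
#'   strand (default: none).
#' @param intron_len length-2 integer range of intron lengths.
#' @param seed integer seed.
#' @return list with `models` (named list of `mip_gene_model`), `genome`
#'   (named character of genomic sequences), `cds` (named character),
#'   `plans` (the realized intron plans).
#' @export
generate_gene_models <- function(proteins, plans = NULL, n_introns = 2L,
                                 minus_strand = character(0),
                                 intron_len = c(60L, 200L), seed = 1L) {
  set.seed(seed)
  models <- list()
  genome <- list()
  cds_out <- list()
  plans_out <- list()
  for (id in names(proteins)) {
    cds <- .mip_back_translate(proteins[[id]])
    L <- nchar(cds)
    plan <- if (!is.null(plans)) as.data.frame(plans[[id]]) else {
      n_aa <- nchar(proteins[[id]])
      cum <- sort(sample.int(L - 3L, min(n_introns, n_aa - 1L)))
      data.frame(codon_index = ifelse(cum %% 3L > 0L, cum %/% 3L + 1L,
                                      cum %/% 3L),
                 phase = cum %% 3L)
    }
    # cumulative CDS nt upstream of each junction
    cum <- ifelse(plan$phase > 0L, 3L * (plan$codon_index - 1L) + plan$phase,
                  3L * plan$codon_index)
    if (any(cum <= 0L | cum >= L) || is.unsorted(cum, strictly = TRUE))
      stop("input error: invalid intron plan for ", id)
    bounds <- c(0L, cum, L)
    pieces <- substring(cds, bounds[-length(bounds)] + 1L, bounds[-1])
    introns <- vapply(seq_len(length(pieces) - 1L), function(k)
      .mip_intron_seq(sample(seq.int(intron_len[1], intron_len[2]), 1L)),
      character(1))
    gseq <- pieces[1]
    starts <- 1L
    ends <- nchar(pieces[1])
    for (k in seq_along(introns)) {
      gseq <- paste0(gseq, introns[k], pieces[k + 1L])
      starts <- c(starts, nchar(gseq) - nchar(pieces[k + 1L]) + 1L)
      ends <- c(ends, nchar(gseq))
    }
    strand <- if (id %in% minus_strand) "-" else "+"
    if (strand == "-") {
      gl <- nchar(gseq)
      gseq <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(gseq)))
      new_starts <- gl - ends + 1L
      new_ends <- gl - starts + 1L
      ord <- order(new_starts)
      starts <- new_starts[ord]
      ends <- new_ends[ord]
    }
    seq_id <- paste0("scaffold_", id)
    genome[[seq_id]] <- gseq
    models[[id]] <- gene_model(id, seq_id, strand,
                               data.frame(start = starts, end = ends))
    cds_out[[id]] <- cds
    plans_out[[id]] <- plan
  }
  list(models = models, genome = unlist(genome), cds = unlist(cds_out),
       plans = plans_out)
}

#' Two-group divergence set for the enrichment statistic
#'
#' Draws two groups of rows from the base scaffold, each mutated at its own
#' rate across all columns (no protected columns), for calibrating or
#' exercising [icelogo()].  With `rate_test == rate_ref` the groups share one
#' generating distribution, giving a null data set.
#'
#' @param n_test,n_ref group sizes.
#' @param rate_test,rate_ref per-column substitution rates.
#' @param seed integer seed.
#' @return list with character matrices `test` and `reference`.
#' @export
two_group_divergence_set <- function(n_test = 15L, n_ref = 30L,
                                     rate_test = 0.2, rate_ref = 0.2,
                                     seed = 1L) {
  base <- .mip_base_row()
  gen <- function(n, rate, off) {
    m <- do.call(rbind, lapply(seq_len(n), function(i)
      .mip_mutate(base, rate = rate,
                  seed = .mip_derive_seed(seed, 10000, off + i),
                  protected = integer(0))))
    rownames(m) <- sprintf("g%d_%02d", off / 1000L + 1L, seq_len(n))
    m
  }
  list(test = gen(n_test, rate_test, 0L),
       reference = gen(n_ref, rate_ref, 1000L))
}
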