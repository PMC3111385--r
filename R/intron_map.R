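# Gene models, intron positions in protein coordinates, projection onto
# alignment columns, and detection of intron positions shared across genes.

#' Construct and validate a gene model
#'
#' @param gene_id gene identifier.
#' @param seq_id identifier of the genomic sequence the exons refer to.
#' @param strand `"+"` or `"-"`.
#' @param exons data.frame with integer columns `start`, `end` (1-based,
#'   inclusive, genomic coordinates); exons must be ordered by `start`,
#'   non-overlapping, and their total length a multiple of 3.
#' @param genome optional named character vector / list of genomic sequences;
#'   when present the CDS is extracted and translated and the translation
#'   checked for internal stops.
#' @return object of class `mip_gene_model`.
#' @export
gene_model <- function(gene_id, seq_id, strand, exons, genome = NULL) {
  if (!strand %in% c("+", "-")) stop("input error: strand must be '+' or '-'")
  exons <- as.data.frame(exons)[, c("start", "end")]
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  if (nrow(exons) < 1L) stop("input error: gene model needs >= 1 exon")
  if (any(exons$start > exons$end))
    stop("input error: exon with start > end in ", gene_id)
  if (is.unsorted(exons$start, strictly = TRUE))
    stop("input error: exons must be ordered by start in ", gene_id)
  if (nrow(exons) > 1L &&
      any(exons$start[-1] <= exons$end[-nrow(exons)]))
    stop("input error: overlapping exons in ", gene_id)
  cds_len <- sum(exons$end - exons$start + 1L)
  if (cds_len %% 3L != 0L)
    stop("input error: CDS length not a multiple of 3 in ", gene_id)
  gm <- structure(list(gene_id = gene_id, seq_id = seq_id, strand = strand,
                       exons = exons, cds_length = cds_len),
                  class = "mip_gene_model")
  if (!is.null(genome)) {
    prot <- translate_model(gm, genome)
    body <- sub("\\*$", "", prot)
    if (grepl("\\*", body))
      stop("input error: internal stop codon in translation of ", gene_id)
  }
  gm
}

#' Extract and translate the CDS of a gene model
#'
#' @param gm a `mip_gene_model`.
#' @param genome named character vector / list of genomic sequences.
#' @return protein string (standard code, may end in `*`).
#' @export
translate_model <- function(gm, genome) {
  g <- genome[[gm$seq_id]]
  if (is.null(g)) stop("input error: genomic sequence absent: ", gm$seq_id)
  pieces <- substring(g, gm$exons$start, gm$exons$end)
  cds <- paste(pieces, collapse = "")
  if (gm$strand == "-")
    cds <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
  as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                     no.init.codon = TRUE))
}

#' Intron positions in protein coordinates
#'
#' For each intron the cumulative CDS length upstream of the junction (in the
#' direction of translation) gives `phase = cum %% 3` and the interrupted (or,
#' for phase 0, the last complete) codon index.
#'
#' @param gm a `mip_gene_model`.
#' @return data.frame with columns `gene_id`, `intron`, `codon_index`,
#'   `phase`; zero rows for single-exon genes.
#' @export
introns_from_model <- function(gm) {
  ex <- gm$exons
  n <- nrow(ex)
  if (n < 2L)
    return(data.frame(gene_id = character(0), intron = integer(0),
                      codon_index = integer(0), phase = integer(0)))
  lens <- ex$end - ex$start + 1L
  if (gm$strand == "-") lens <- rev(lens)  # translation order
  cum <- cumsum(lens)[-n]
  phase <- cum %% 3L
  codon <- ifelse(phase > 0L, cum %/% 3L + 1L, cum %/% 3L)
  data.frame(gene_id = gm$gene_id, intron = seq_len(n - 1L),
             codon_index = as.integer(codon), phase = as.integer(phase),
             stringsAsFactors = FALSE)
}

#' Project intron positions onto alignment columns
#'
#' Maps each intron's codon index through the protein's alignment column map.
#' Codons falling inside an insertion (no reference column) are reported as
#' `after_col`, the last preceding mapped column, with `in_insertion = TRUE`.
#'
#' @param introns data.frame from [introns_from_model()].
#' @param aq the `mip_aligned` object of the encoded protein.
#' @return the input with added columns `column`, `after_col`, `in_insertion`.
#' @export
project_to_alignment <- function(introns, aq) {
  cm <- aq$col_map  # column -> residue
  res2col <- rep(NA_integer_, aq$seq$length)
  res2col[cm[!is.na(cm)]] <- which(!is.na(cm))
  introns$column <- NA_integer_
  introns$after_col <- NA_integer_
  introns$in_insertion <- FALSE
  for (i in seq_len(nrow(introns))) {
    ci <- introns$codon_index[i]
    if (ci < 1L || ci > aq$seq$length) {
      introns$in_insertion[i] <- NA
      next
    }
    col <- res2col[ci]
    if (!is.na(col)) {
      introns$column[i] <- col
    } else {
      prev <- res2col[seq_len(ci)]
      prev <- prev[!is.na(prev)]
      introns$after_col[i] <- if (length(prev)) max(prev) else 0L
      introns$in_insertion[i] <- TRUE
    }
  }
  introns
}

#' Intron positions shared across genes
#'
#' Groups projected introns by single linkage: two introns are linked when
#' they have the same phase and their alignment columns differ by at most
#' `tolerance` (default 0, i.e. the identical column).  Groups supported by at
#' least `min_genes` distinct genes are reported.
#'
#' @param projected data.frame of projected introns (rbind over genes), with
#'   columns `gene_id`, `phase`, `column`.
#' @param min_genes minimum number of distinct genes per shared position.
#' @param tolerance allowed column difference.
#' @return data.frame with one row per shared position: `column` (median),
#'   `phase`, `n_genes`, `genes` (comma separated).
#' @export
shared_introns <- function(projected, min_genes = 2L, tolerance = 0L) {
  p <- projected[!is.na(projected$column), , drop = FALSE]
  if (!nrow(p))
    return(data.frame(column = integer(0), phase = integer(0),
                      n_genes = integer(0), genes = character(0)))
  p <- p[order(p$phase, p$column), ]
  grp <- integer(nrow(p))
  g <- 0L
  for (i in seq_len(nrow(p))) {
    if (i == 1L || p$phase[i] != p$phase[i - 1L] ||
        p$column[i] - p$column[i - 1L] > tolerance)
      g <- g + 1L
    grp[i] <- g
  }
  out <- lapply(split(p, grp), function(s) {
    genes <- sort(unique(s$gene_id))
    data.frame(column = as.integer(stats::median(s$column)),
               phase = s$phase[1L], n_genes = length(genes),
               genes = paste(genes, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[out$n_genes >= min_genes, , drop = FALSE]
}

#' Read gene models from an exon table
#'
#' The exon table is a TSV with columns `gene_id`, `seq_id`, `strand`,
#' `start`, `end`, one row per exon.
#'
#' @param path TSV file.
#' @param genome optional genome (see [gene_model()]) for translation checks.
#' @return named list of `mip_gene_model`.
#' @export
read_exon_table <- function(path, genome = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("gene_id", "seq_id", "strand", "start", "end")
  if (!all(need %in% names(tab)))
    stop("format error: exon table needs columns ",
         paste(need, collapse = ", "))
  lapply(split(tab, tab$gene_id)[unique(tab$gene_id)], function(s)
    gene_model(s$gene_id[1], s$seq_id[1], s$strand[1],
               s[order(s$start), c("start", "end")], genome))
}

#' Write gene models to an exon table
#' @param models list of `mip_gene_model`.
#' @param path output TSV.
#' @export
write_exon_table <- function(models, path) {
  tab <- do.call(rbind, lapply(models, function(gm)
    data.frame(gene_id = gm$gene_id, seq_id = gm$seq_id, strand = gm$strand,
               start = gm$exons$start, end = gm$exons$end,
               stringsAsFactors = FALSE)))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene models from the CDS features of a GFF3 file
#'
#' Minimal reader: `CDS` lines are grouped by their `Parent` (or `ID`)
#' attribute; other feature types and directives are ignored.
#'
#' @param path GFF3 file.
#' @param genome optional genome for translation checks.
#' @return named list of `mip_gene_model`.
#' @export
read_gff3_cds <- function(path, genome = NULL) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  f <- f[vapply(f, length, integer(1)) == 9L]
  f <- f[vapply(f, function(x) x[3] == "CDS", logical(1))]
  if (!length(f)) stop("format error: no CDS features in ", path)
  attr1 <- function(attrs, key) {
    m <- regmatches(attrs, regexec(paste0("(?:^|;)", key, "=([^;]+)"), attrs))[[1]]
    if (length(m) == 2L) m[2] else NA_character_
  }
  tab <- do.call(rbind, lapply(f, function(x) {
    gid <- attr1(x[9], "Parent")
    if (is.na(gid)) gid <- attr1(x[9], "ID")
    if (is.na(gid)) stop("format error: CDS without Parent/ID attribute")
    data.frame(gene_id = gid, seq_id = x[1], strand = x[7],
               start = as.integer(x[4]), end = as.integer(x[5]),
               stringsAsFactors = FALSE)
  }))
  lapply(split(tab, tab$gene_id)[unique(tab$gene_id)], function(s)
    gene_model(s$gene_id[1], s$seq_id[1], s$strand[1],
               s[order(s$start), c("start", "end")], genome))
}
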