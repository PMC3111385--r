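#!/usr/bin/env Rscript
# Regenerates the packaged text fixtures under inst/extdata from the
# synthetic-data generators.  Everything is a pure function of the fixed
# seeds, so this script is idempotent.  Run from the package root:
#   Rscript tools/make_extdata.R

for (f in list.files("R", full.names = TRUE)) source(f)

out <- "inst/extdata"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

rs <- synthesize_reference_set()
qs <- synthesize_query_set()

## reference alignment (reference rows only) + annotation -------------------
ref_rows <- rs$aln[rs$role == "ref", ]
write_alignment(ref_rows, file.path(out, "reference_alignment.synthetic.fasta"))

ann <- rs$annotation
yaml::write_yaml(list(
  elements = lapply(seq_len(nrow(ann$elements)), function(i)
    as.list(ann$elements[i, ])),
  arr_columns = ann$arr_columns,
  core_interval = ann$core_interval,
  anchors = as.list(ann$anchors),
  subfamilies = ann$subfamilies,
  motifs = lapply(seq_len(nrow(ann$motifs)), function(i) {
    m <- as.list(ann$motifs[i, ])
    m[!vapply(m, function(x) is.na(x) || identical(x, ""), logical(1))]
  }),
  substrates = lapply(seq_len(nrow(ann$substrates)), function(i)
    as.list(ann$substrates[i, ]))
), file.path(out, "reference_annotation.yml"))

## query coding sequences ----------------------------------------------------
viral <- "PbcvMT325GIP1;1"
algal <- setdiff(names(qs$cds), viral)
Biostrings::writeXStringSet(Biostrings::BStringSet(qs$cds[algal]),
                            file.path(out, "algal_mip_cds.synthetic.fasta"))
Biostrings::writeXStringSet(Biostrings::BStringSet(qs$cds[viral]),
                            file.path(out, "pbcv_gip_cds.synthetic.fasta"))

## expected feature-table catalog --------------------------------------------
catalog <- qs$truth
catalog$substrate <- vapply(seq_len(nrow(catalog)), function(i)
  substrate_heuristic(c(catalog$h2[i], catalog$h5[i],
                        catalog$le1[i], catalog$le2[i])), character(1))
utils::write.table(catalog, file.path(out, "table2_catalog.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

## PIP gene models: two algal and two moss PIP genes with planted introns ----
# Intron positions are planned in anchor space (SoPIP2;1 residue -> column)
# so that homologous positions land on the same alignment column:
#   algal plan: residues 100 (phase 2), 150 (phase 1), 262 (phase 0)
#   moss plan:  residues 150 (phase 1), 210 (phase 0), 262 (phase 0)
# giving two positions shared between the algal and the moss pair.
res2row <- function(id) {
  if (id %in% rownames(rs$aln)) rs$aln[id, ] else stop("unknown row ", id)
}
plan_for <- function(id, anchor_res, phases) {
  row <- res2row(id)
  cm <- rep(NA_integer_, ncol(rs$aln))
  cm[row != "-"] <- seq_len(sum(row != "-"))
  cols <- vapply(anchor_res, .anchor_col, integer(1))
  ci <- cm[cols]
  stopifnot(!anyNA(ci))
  data.frame(codon_index = ci, phase = phases)
}
pip_genes <- c("CcPIP4;1", "CcPIP4;2", "PpPIP1;1", "PpPIP2;1")
plans <- list(
  "CcPIP4;1" = plan_for("CcPIP4;1", c(100L, 150L, 262L), c(2L, 1L, 0L)),
  "CcPIP4;2" = plan_for("CcPIP4;2", c(100L, 150L, 262L), c(2L, 1L, 0L)),
  "PpPIP1;1" = plan_for("PpPIP1;1", c(150L, 210L, 262L), c(1L, 0L, 0L)),
  "PpPIP2;1" = plan_for("PpPIP2;1", c(150L, 210L, 262L), c(1L, 0L, 0L))
)
pip_prot <- vapply(pip_genes, function(id) {
  row <- res2row(id)
  paste(row[row != "-"], collapse = "")
}, character(1))
gm <- generate_gene_models(pip_prot, plans = plans,
                           minus_strand = "CcPIP4;2", seed = 424242L)
write_exon_table(gm$models, file.path(out, "pip_gene_models.synthetic.tsv"))
Biostrings::writeXStringSet(
  Biostrings::BStringSet(gm$genome),
  file.path(out, "pip_genomic.synthetic.fasta"))
Biostrings::writeXStringSet(
  Biostrings::BStringSet(pip_prot),
  file.path(out, "pip_proteins.synthetic.fasta"))

cat("wrote", length(list.files(out)), "files to", out, "\n")
for (f in list.files(out, full.names = TRUE))
  cat(sprintf("  %-45s %6.1f KB\n", basename(f), file.size(f) / 1024))
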