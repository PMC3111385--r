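test_that("gene model validation rejects malformed exon sets", {
  ok <- data.frame(start = c(1L, 200L), end = c(90L, 300L))  # 90+101=191 no
  expect_error(gene_model("g", "s", "+", ok), "multiple of 3")
  expect_error(gene_model("g", "s", "*",
                          data.frame(start = 1L, end = 9L)), "strand")
  expect_error(gene_model("g", "s", "+",
                          data.frame(start = c(1L, 50L), end = c(60L, 100L))),
               "overlapping")
  expect_error(gene_model("g", "s", "+",
                          data.frame(start = c(100L, 1L), end = c(150L, 60L))),
               "ordered")
  gm <- gene_model("g", "s", "+", data.frame(start = c(1L, 100L),
                                             end = c(90L, 102L)))
  expect_s3_class(gm, "mip_gene_model")
  expect_equal(gm$cds_length, 93L)
})

test_that("intron phases follow the cumulative-length convention", {
  # exon lengths 10 and 14 -> junction after 10 nt: phase 1, codon 4
  gm <- gene_model("g", "s", "+", data.frame(start = c(1L, 100L),
                                             end = c(10L, 113L)))
  ii <- introns_from_model(gm)
  expect_equal(ii$phase, 1L)
  expect_equal(ii$codon_index, 4L)
  # phase 0 junction: exon lengths 12 and 12 -> codon 4, phase 0
  gm0 <- gene_model("g0", "s", "+", data.frame(start = c(1L, 100L),
                                               end = c(12L, 111L)))
  ii0 <- introns_from_model(gm0)
  expect_equal(ii0$phase, 0L)
  expect_equal(ii0$codon_index, 4L)
  # single-exon genes have no introns
  expect_equal(nrow(introns_from_model(
    gene_model("g1", "s", "+", data.frame(start = 1L, end = 9L)))), 0L)
})

test_that("minus-strand models translate and phase identically", {
  fam <- generate_family(synth_spec(n_per_subfamily = 1L, seed = 99L))
  prot <- fam$proteins[1:2]
  gm <- generate_gene_models(prot, n_introns = 2L,
                             minus_strand = names(prot)[2], seed = 31L)
  for (id in names(prot)) {
    p <- translate_model(gm$models[[id]], gm$genome)
    expect_identical(sub("\\*$", "", p), unname(prot[[id]]))
    ii <- introns_from_model(gm$models[[id]])
    expect_equal(ii$codon_index, gm$plans[[id]]$codon_index)
    expect_equal(ii$phase, gm$plans[[id]]$phase)
  }
  expect_equal(gm$models[[names(prot)[2]]]$strand, "-")
})

test_that("projection maps codons to columns and flags insertions", {
  ref <- fixture_ref()
  aq <- fixture_aligned("CcPIP4;1")
  ii <- data.frame(gene_id = "CcPIP4;1", intron = 1:2,
                   codon_index = c(50L, 150L), phase = c(0L, 1L))
  pr <- project_to_alignment(ii, aq)
  expect_true(all(!is.na(pr$column)))
  expect_equal(unname(aq$col_map[pr$column]), pr$codon_index)
})

test_that("exon tables and GFF3 CDS features load equivalently", {
  fam <- generate_family(synth_spec(n_per_subfamily = 1L, seed = 77L))
  gm <- generate_gene_models(fam$proteins[1:2], n_introns = 2L, seed = 5L)
  tsv <- tempfile(fileext = ".tsv")
  write_exon_table(gm$models, tsv)
  back <- read_exon_table(tsv, genome = gm$genome)
  expect_equal(names(back), names(gm$models))
  expect_equal(back[[1]]$exons, gm$models[[1]]$exons, ignore_attr = TRUE)
  # equivalent GFF3
  gff <- tempfile(fileext = ".gff3")
  lines <- c("##gff-version 3")
  for (m in gm$models)
    lines <- c(lines, sprintf("%s\tsynth\tCDS\t%d\t%d\t.\t%s\t.\tParent=%s",
                              m$seq_id, m$exons$start, m$exons$end,
                              m$strand, m$gene_id))
  writeLines(lines, gff)
  g2 <- read_gff3_cds(gff, genome = gm$genome)
  expect_equal(lapply(g2, `[[`, "exons"), lapply(back, `[[`, "exons"),
               ignore_attr = TRUE)
  unlink(c(tsv, gff))
})

test_that("shared introns require equal phase and linked columns", {
  pr <- data.frame(
    gene_id = c("a", "b", "c", "a", "b"),
    phase = c(1L, 1L, 1L, 0L, 2L),
    column = c(100L, 100L, 100L, 200L, 200L))
  sh <- shared_introns(pr)
  expect_equal(nrow(sh), 1L)  # the phase-0/phase-2 pair must not merge
  expect_equal(sh$column, 100L)
  expect_equal(sh$n_genes, 3L)
  # tolerance links neighbouring columns
  pr2 <- data.frame(gene_id = c("a", "b"), phase = c(0L, 0L),
                    column = c(100L, 101L))
  expect_equal(nrow(shared_introns(pr2)), 0L)
  expect_equal(nrow(shared_introns(pr2, tolerance = 1L)), 1L)
})

test_that("packaged PIP gene models share two algal/moss intron positions", {
  ref <- fixture_ref()
  genome_ss <- Biostrings::readBStringSet(extdata("pip_genomic.synthetic.fasta"))
  genome <- stats::setNames(as.character(genome_ss), names(genome_ss))
  models <- read_exon_table(extdata("pip_gene_models.synthetic.tsv"),
                            genome = genome)
  prot_ss <- Biostrings::readBStringSet(extdata("pip_proteins.synthetic.fasta"))
  prots <- stats::setNames(as.character(prot_ss), names(prot_ss))
  proj <- do.call(rbind, lapply(names(models), function(id) {
    aq <- align_to_profile(mip_sequence(id, prots[[id]]), ref)
    project_to_alignment(introns_from_model(models[[id]]), aq)
  }))
  sh <- shared_introns(proj)
  algal <- c("CcPIP4;1", "CcPIP4;2")
  both <- vapply(strsplit(sh$genes, ","), function(g)
    any(g %in% algal) && any(!g %in% algal), logical(1))
  expect_equal(sum(both), 2L)
})
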