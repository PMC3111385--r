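test_that("synth_spec validates its arguments", {
  expect_error(synth_spec(seed = 2^31), "seed")
  expect_error(synth_spec(subfamilies = "NOTAFAM"), "unknown subfamily")
  expect_error(synth_spec(mutation_rate = 1.5), "mutation_rate")
})

test_that("generation is a pure function of the spec", {
  a <- generate_family(synth_spec(n_per_subfamily = 2L, seed = 123L))
  b <- generate_family(synth_spec(n_per_subfamily = 2L, seed = 123L))
  expect_identical(a$proteins, b$proteins)
  expect_identical(a$truth, b$truth)
  c <- generate_family(synth_spec(n_per_subfamily = 2L, seed = 124L))
  expect_false(identical(a$proteins, c$proteins))
})

test_that("rate zero reproduces the templates; features survive any rate", {
  f0 <- generate_family(synth_spec(n_per_subfamily = 1L, mutation_rate = 0,
                                   seed = 1L))
  f3 <- generate_family(synth_spec(n_per_subfamily = 1L, mutation_rate = 0.3,
                                   seed = 1L))
  # protected feature columns are identical across rates
  expect_identical(f0$truth[, c("h2", "h5", "le1", "le2", "npa1", "npa2")],
                   f3$truth[, c("h2", "h5", "le1", "le2", "npa1", "npa2")])
  # but the sequences do diverge
  expect_false(identical(f0$proteins, f3$proteins))
})

test_that("ablations take effect", {
  sp <- synth_spec(subfamilies = "MIPB", n_per_subfamily = 1L, seed = 9L,
                   ablations = list(canonical_npa = TRUE))
  f <- generate_family(sp)
  expect_equal(f$truth$npa1, "NPA")  # MIPB normally carries NPS
  expect_equal(f$truth$npa2, "NPA")
  sp2 <- synth_spec(subfamilies = "PIP", n_per_subfamily = 2L, seed = 9L,
                    mutation_rate = 0.3,
                    ablations = list(no_protect = TRUE))
  f2 <- generate_family(sp2)
  # without protection the feature columns drift for at least one row
  expect_false(all(f2$truth$npa1 == "NPA" & f2$truth$npa2 == "NPA" &
                     f2$truth$h2 == "F"))
})

test_that("extraction recovers the truth table exactly at moderate drift", {
  ref <- fixture_ref()
  fam <- generate_family(synth_spec(n_per_subfamily = 1L,
                                    mutation_rate = 0.05, seed = 202L))
  for (i in seq_len(nrow(fam$truth))) {
    tr <- fam$truth[i, ]
    aq <- trim_to_core(align_to_profile(
      mip_sequence(tr$id, fam$proteins[[tr$id]]), ref), ref)
    f <- feature_profile(aq, ref)
    expect_equal(c(f$filter$h2, f$filter$h5, f$filter$le1, f$filter$le2,
                   f$npa$npa1, f$npa$npa2),
                 c(tr$h2, tr$h5, tr$le1, tr$le2, tr$npa1, tr$npa2),
                 info = tr$id)
  }
})

test_that("the packaged reference set is reproducible from its seed", {
  rs <- synthesize_reference_set()
  packaged <- read_alignment(extdata("reference_alignment.synthetic.fasta"))
  expect_equal(packaged, rs$aln[rs$role == "ref", ], ignore_attr = TRUE)
  expect_equal(rownames(packaged), names(rs$role)[rs$role == "ref"])
})

test_that("gene-model generation round-trips all strands exactly", {
  fam <- generate_family(synth_spec(n_per_subfamily = 1L, seed = 55L))
  prot <- fam$proteins[1:4]
  gm <- generate_gene_models(prot, n_introns = 3L,
                             minus_strand = names(prot)[c(2, 4)], seed = 66L)
  for (id in names(prot)) {
    expect_identical(sub("\\*$", "", translate_model(gm$models[[id]],
                                                     gm$genome)),
                     unname(prot[[id]]), )
  }
  # introns carry canonical GT..AG boundaries on the coding strand
  g <- gm$genome[[gm$models[[1]]$seq_id]]
  ex <- gm$models[[1]]$exons
  intron1 <- substr(g, ex$end[1] + 1L, ex$start[2] - 1L)
  expect_equal(substr(intron1, 1, 2), "GT")
  expect_equal(substr(intron1, nchar(intron1) - 1L, nchar(intron1)), "AG")
})
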