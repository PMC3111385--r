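test_that("packaged reference loads and validates", {
  ref <- fixture_ref()
  expect_s3_class(ref, "mip_reference")
  expect_equal(ncol(ref$aln), 301L)
  expect_equal(nrow(ref$aln), 27L)
  expect_setequal(unique(ref$subfamily),
                  c("PIP", "GIP", "TIP", "NIP", "SIP", "XIP", "HIP",
                    "MIPA", "MIPB", "MIPC", "MIPD", "MIPE", "AQP", "GLP"))
  expect_equal(unname(ref$arr_columns),
               c(89L, 218L, 237L, 240L))
  expect_equal(ref$core_interval, c(34L, 286L))
})

test_that("anchor numbering maps landmark residues to annotated columns", {
  ref <- fixture_ref()
  # ar/R filter positions in the SoPIP2;1 numbering
  expect_equal(anchor_residue(ref, "SoPIP2;1", 81L), unname(ref$arr_columns["H2"]))
  expect_equal(anchor_residue(ref, "SoPIP2;1", 210L), unname(ref$arr_columns["H5"]))
  expect_equal(anchor_residue(ref, "SoPIP2;1", 229L), unname(ref$arr_columns["LE1"]))
  expect_equal(anchor_residue(ref, "SoPIP2;1", 232L), unname(ref$arr_columns["LE2"]))
  # GlpF packing residues carry their own numbering
  glpf <- ref$aln["EcGlpF", ]
  expect_equal(glpf[anchor_residue(ref, "EcGlpF", 72L)], "T",
               ignore_attr = TRUE)
  expect_equal(glpf[anchor_residue(ref, "EcGlpF", 89L)], "F",
               ignore_attr = TRUE)
  expect_equal(glpf[anchor_residue(ref, "EcGlpF", 93L)], "Q",
               ignore_attr = TRUE)
})

test_that("anchor_residue errors on unmapped residues and unknown anchors", {
  ref <- fixture_ref()
  expect_error(anchor_residue(ref, "SoPIP2;1", 999L), "range error")
  expect_error(anchor_residue(ref, "NotAnAnchor", 1L), "unknown anchor")
})

test_that("validation rejects malformed annotations", {
  ref <- fixture_ref()
  bad <- ref
  bad$arr_columns["H2"] <- 150L  # outside helix 2
  expect_error(validate_mip_reference(bad), "outside H2")
  bad2 <- ref
  bad2$elements$start_col[bad2$elements$name == "NPA1"] <-
    bad2$elements$start_col[bad2$elements$name == "NPA1"] + 1L
  expect_error(validate_mip_reference(bad2), "NPA1")
  expect_error(
    new_mip_reference(ref$aln, ref$subfamily, ref$elements, ref$arr_columns,
                      c(400L, 500L), names(ref$anchors)),
    "core_interval")
})

test_that("alignment io round-trips through FASTA and Nexus", {
  ref <- fixture_ref()
  fa <- tempfile(fileext = ".fasta")
  nx <- tempfile(fileext = ".nex")
  write_alignment(ref$aln, fa)
  write_alignment(ref$aln, nx)
  expect_equal(read_alignment(fa), ref$aln, ignore_attr = TRUE)
  rt <- read_alignment(nx)
  expect_equal(unname(rt), unname(ref$aln))
  unlink(c(fa, nx))
})

test_that("write_reference/load_reference round-trips the annotation", {
  ref <- fixture_ref()
  fa <- tempfile(fileext = ".fasta")
  yml <- tempfile(fileext = ".yml")
  write_reference(ref, fa, yml)
  ref2 <- load_reference(fa, yml)
  expect_equal(ref2$elements, ref$elements, ignore_attr = TRUE)
  expect_equal(ref2$arr_columns, ref$arr_columns)
  expect_equal(ref2$core_interval, ref$core_interval)
  expect_equal(rownames(ref2$aln), rownames(ref$aln))
  unlink(c(fa, yml))
})

test_that("ragged alignments are rejected", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACDEF", ">b", "ACD"), fa)
  expect_error(read_alignment(fa), "ragged")
  unlink(fa)
})
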