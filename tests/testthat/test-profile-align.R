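test_that("mip_sequence validates input", {
  s <- mip_sequence("CcTest1", paste(rep("ACDEFGHIKLMNPQRSTVWY", 15),
                                     collapse = ""))
  expect_s3_class(s, "mip_seq")
  expect_true(s$length_plausible)
  expect_error(mip_sequence("bad", "ACDEF123"), "non amino-acid")
  short <- mip_sequence("short", "ACDEFGHIKL")
  expect_false(short$length_plausible)
})

test_that("queries realign to their planted reference columns", {
  ref <- fixture_ref()
  qs <- fixture_queries()
  # feature columns must be recovered exactly for every query
  feature_cols <- c(unname(ref$arr_columns),
                    128:130, 232:234)  # ar/R + both NPA boxes
  for (id in c("CcPIP4;1", "OlMIPB1;1", "CrMIPD1;1", "CnGIP1;1")) {
    aq <- align_to_profile(mip_sequence(id, qs$proteins[[id]]), ref)
    expect_equal(aq$col_map[feature_cols],
                 qs$col_maps[[id]][feature_cols],
                 info = id)
    # overall columnwise agreement with the planted map is near-total
    tc <- which(!is.na(qs$col_maps[[id]]))
    agree <- mean(!is.na(aq$col_map[tc]) &
                    aq$col_map[tc] == qs$col_maps[[id]][tc])
    expect_gt(agree, 0.95)
  }
})

test_that("re-aligning each reference row reproduces >=95% of its columns", {
  ref <- fixture_ref()
  for (id in c("SoPIP2;1", "EcGlpF", "MIPD_REF1", "HsAQP5")) {
    row <- ref$aln[id, ]
    prot <- paste(row[row != "-"], collapse = "")
    aq <- align_to_profile(mip_sequence(id, prot), ref, exclude = id)
    truth <- rep(NA_integer_, length(row))
    truth[row != "-"] <- seq_len(sum(row != "-"))
    tc <- which(!is.na(truth))
    agree <- mean(!is.na(aq$col_map[tc]) & aq$col_map[tc] == truth[tc])
    expect_gte(agree, 0.95)
  }
})

test_that("alignment rejects degenerate queries", {
  ref <- fixture_ref()
  expect_error(align_to_profile(mip_sequence("x", "ACDEFGHIKLMNPQRSTVWYACDEF"),
                                ref), "shorter than 30")
  expect_error(align_to_profile(
    mip_sequence("x", paste(rep("X", 50), collapse = "")), ref), "all-X")
})

test_that("substitutions never increase the pairwise score", {
  p <- align_params()
  a <- "MKKLVVAGLLALSSCFA"
  s0 <- attr(similarity_string(a, a), "score")
  b <- sub("G", "W", a)
  s1 <- attr(similarity_string(a, b), "score")
  expect_lte(s1, s0)
})

test_that("trim_to_core is idempotent and masks non-core columns", {
  ref <- fixture_ref()
  qs <- fixture_queries()
  aq <- align_to_profile(mip_sequence("CcPIP4;1", qs$proteins[["CcPIP4;1"]]),
                         ref)
  t1 <- trim_to_core(aq, ref)
  t2 <- trim_to_core(t1, ref)
  expect_identical(t1$col_map, t2$col_map)
  ci <- ref$core_interval
  outside <- setdiff(seq_len(ncol(ref$aln)), seq.int(ci[1], ci[2]))
  expect_true(all(is.na(t1$col_map[outside])))
})

test_that("similarity strings follow the Clustal symbol convention", {
  s <- similarity_string("ACDEF", "ACDEF")
  expect_equal(unclass(s), "*****", ignore_attr = TRUE)
  s2 <- similarity_string("KR", "RK")
  expect_equal(unclass(s2), "::", ignore_attr = TRUE)
})

test_that("loop E regions of OlMIPB1;1 and OrMIPE1;1 share similarity", {
  ref <- fixture_ref()
  qs <- fixture_queries()
  s <- similarity_string(qs$proteins[["OlMIPB1;1"]],
                         qs$proteins[["OrMIPE1;1"]],
                         region = "LE", ref = ref)
  sym <- strsplit(unclass(s), "")[[1]]
  runs <- rle(sym %in% c("*", ":"))
  expect_gte(max(c(0, runs$lengths[runs$values])), 4)
})
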