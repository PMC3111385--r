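test_that("NPA motifs and ar/R filter match the planted truth", {
  qs <- fixture_queries()
  for (id in c("CcPIP4;1", "OlMIPB1;1", "OtMIPC1;1", "CrMIPD2;1",
               "CnMIPE1;2", "CcMIPA1;1")) {
    f <- fixture_features(id)
    tr <- qs$truth[qs$truth$id == id, ]
    expect_equal(f$npa$npa1, tr$npa1, info = id)
    expect_equal(f$npa$npa2, tr$npa2, info = id)
    expect_equal(format(f$filter),
                 paste(tr$h2, tr$h5, tr$le1, tr$le2), info = id)
  }
})

test_that("canonical flags and mercury cysteine behave as defined", {
  f <- fixture_features("CcPIP4;1")
  expect_true(f$npa$canonical1 && f$npa$canonical2)
  expect_true(f$filter$mercury_cysteine)  # FHCR has a filter cysteine
  f2 <- fixture_features("OlMIPB1;1")
  expect_false(f2$npa$canonical1)  # NPS
  expect_false(f2$npa$canonical2)  # NAA
  expect_false(f2$filter$mercury_cysteine)  # YLGR
})

test_that("diagnostic motifs are detected per subfamily design", {
  pres <- function(id) {
    h <- fixture_features(id)$hits
    stats::setNames(h$present, h$motif_id)
  }
  pip <- pres("CcPIP4;1")
  expect_true(all(pip[c("kxsxxr", "h193", "gggan", "dgcs", "loopA_cys",
                        "s115")]))
  gip <- pres("CcGIP1;1")
  expect_true(gip["dxxxr"])
  expect_false(gip["kxsxxr"])
  mipd <- pres("CrMIPD1;1")
  expect_true(all(mipd[c("loopC_cys", "h2_gly")]))
  expect_false(mipd["h6_pro"])
  mipe <- pres("CnMIPE1;1")
  expect_true(all(mipe[c("dgcs", "lxxn")]))
})

test_that("uncovered windows are flagged, not silently absent", {
  # CnMIPE1;3 carries a sequence gap spanning the pH-gating histidine
  h <- fixture_features("CnMIPE1;3")$hits
  row <- h[h$motif_id == "h193", ]
  expect_false(row$present)
  expect_equal(row$flag, "no_coverage")
})

test_that("extraction errors on queries covering no NPA element", {
  ref <- fixture_ref()
  qs <- fixture_queries()
  aq <- fixture_aligned("CcPIP4;1")
  broken <- aq
  broken$col_map[] <- NA_integer_
  expect_error(extract_npa(broken, ref), "neither NPA")
  expect_error(extract_filter(broken, ref), "fewer than 2")
})

test_that("loop lengths distinguish GlpF-like short pre-NPA1 loops", {
  ref <- fixture_ref()
  ll_gip <- loop_lengths(fixture_aligned("CcGIP1;1"), ref)
  ll_pip <- loop_lengths(fixture_aligned("CcPIP4;1"), ref)
  expect_lt(ll_gip["LB_preNPA1"], ll_pip["LB_preNPA1"])
  expect_true(all(loop_lengths(fixture_aligned("CrMIPD1;1"), ref) >= 0))
})

test_that("C-terminal charge separates MIPC tails from the default tail", {
  ref <- fixture_ref()
  ct_mipc <- cterm_charge(fixture_aligned("MpMIPC1;1"), ref)
  ct_pip <- cterm_charge(fixture_aligned("CcPIP4;1"), ref)
  expect_gte(ct_mipc, 0.3)
  expect_lt(ct_pip, 0.3)
})

test_that("substrate heuristic follows the characterized-filter table", {
  expect_equal(substrate_heuristic(c("F", "H", "C", "R")), "water")
  expect_equal(substrate_heuristic(c("N", "A", "A", "R")), "glycerol")
  expect_equal(substrate_heuristic(c("H", "M", "M", "R")), "water")
  # fewer than 3 informative positions -> unknown
  expect_equal(substrate_heuristic(c("F", "-", "-", "R")), "unknown")
})

test_that("features_table has the Table 2 layout", {
  f <- list(fixture_features("CcPIP4;1"), fixture_features("OlMIPB1;1"))
  tab <- features_table(f, subfamily = c("CcPIP4;1" = "PIP",
                                         "OlMIPB1;1" = "MIPB"))
  expect_named(tab, c("subfamily", "protein", "H2", "H5", "LE1", "LE2",
                      "NPA_loopB", "NPA_loopE", "substrate"))
  expect_equal(tab$NPA_loopE[tab$protein == "OlMIPB1;1"], "NAA")
})
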