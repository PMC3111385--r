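test_that("neighbor joining reconstructs additive trees exactly", {
  set.seed(501)
  for (r in 1:10) {
    tr <- ape::rtree(sample(5:15, 1))
    D <- stats::cophenetic(tr)
    mine <- nj_tree(D)
    expect_equal(ape::dist.topo(ape::unroot(tr), mine), 0,
                 ignore_attr = TRUE)
  }
})

test_that("neighbor joining matches the ape oracle on perturbed matrices", {
  set.seed(502)
  for (r in 1:5) {
    tr <- ape::rtree(10)
    D <- stats::cophenetic(tr) + matrix(stats::runif(100, 0, 0.01), 10, 10)
    D <- (D + t(D)) / 2
    diag(D) <- 0
    expect_equal(ape::dist.topo(ape::nj(D), nj_tree(D)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("small inputs give trivial topologies with a warning", {
  D <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3,
              dimnames = list(letters[1:3], letters[1:3]))
  expect_warning(tr <- nj_tree(D), "trivial")
  expect_equal(length(tr$tip.label), 3L)
})

test_that("distances: p-distance, correction and low-overlap flagging", {
  x <- rbind(a = c("A", "A", "A", "A"),
             b = c("A", "A", "A", "C"),
             c = c("C", "C", "A", "A"))
  d0 <- pairwise_distances(x, correction = "none", min_overlap = 2L)
  expect_equal(d0$d["a", "b"], 0.25)
  expect_equal(d0$d["a", "c"], 0.5)
  p <- 0.25
  dk <- pairwise_distances(x, correction = "kimura", min_overlap = 2L)
  expect_equal(dk$d["a", "b"], -log(1 - p - p^2 / 5))
  # low-overlap pair flagged and imputed, matrix still finite
  y <- x
  y["c", 1:3] <- "-"
  dl <- pairwise_distances(y, min_overlap = 2L)
  expect_true(all(is.finite(dl$d)))
  expect_true(any(dl$flagged$reason == "low_overlap"))
})

test_that("bootstrap support is deterministic given a seed", {
  ref <- fixture_ref()
  cm <- core_matrix(ref)[1:10, ]
  b1 <- bootstrap_tree(cm, n_reps = 20, seed = 7)
  b2 <- bootstrap_tree(cm, n_reps = 20, seed = 7)
  expect_identical(b1$tree$node.label, b2$tree$node.label)
  expect_identical(ape::write.tree(b1$tree), ape::write.tree(b2$tree))
})

test_that("placement finds the smallest supported single-subfamily clade", {
  ref <- fixture_ref()
  ids <- c("OlMIPB1;1", "MpMIPC1;1")
  aligned <- lapply(ids, function(id) fixture_aligned(id))
  bt <- bootstrap_tree(core_matrix(ref, aligned), n_reps = 50, seed = 11)
  pl <- place_query(bt, "OlMIPB1;1", ref$subfamily)
  expect_equal(pl$sister_subfamily, "MIPB")
  expect_gte(pl$support, 50)
  pl2 <- place_query(bt, "MpMIPC1;1", ref$subfamily)
  expect_equal(pl2$sister_subfamily, "MIPC")
})

test_that("motif votes and conflicts are resolved as specified", {
  f <- fixture_features("CcPIP4;1")
  # vote alone
  call <- place_and_classify(f, placement = NULL)
  expect_equal(call$label, "PIP")
  # confident conflicting placement forces unclassified + conflict evidence
  pl <- structure(list(query_id = "CcPIP4;1", sister_subfamily = "TIP",
                       support = 95, clade_size = 3, long_branch = FALSE),
                  class = "mip_placement")
  call2 <- place_and_classify(f, pl)
  expect_equal(call2$label, "unclassified")
  expect_true("conflict_placement_vs_motifs" %in% call2$evidence$rule_id)
  # agreeing placement keeps the label and records support
  pl$sister_subfamily <- "PIP"
  call3 <- place_and_classify(f, pl)
  expect_equal(call3$label, "PIP")
  expect_equal(call3$placement_support, 95)
})

test_that("name proposal and parsing are inverse and collision-free", {
  p <- parse_mip_name("CcPIP4;1")
  expect_equal(p, list(species_tag = "Cc", label = "PIP", group = 4L,
                       isoform = 1L))
  expect_equal(parse_mip_name("PbcvMT325GIP1;1")$species_tag, "PbcvMT325")
  expect_error(parse_mip_name("nonsense"), "malformed")
  nm <- propose_name("MIPD", "Vc", c("VcMIPD1;1", "VcMIPD1;2"))
  expect_equal(nm, "VcMIPD1;3")
  expect_equal(propose_name("MIPB", "Ot", character(0)), "OtMIPB1;1")
  expect_error(propose_name("unclassified", "Cc"), "cannot propose")
})

test_that("phylip export writes a square matrix header", {
  ref <- fixture_ref()
  cm <- core_matrix(ref)[1:6, ]
  D <- pairwise_distances(cm)
  f <- tempfile(fileext = ".dist")
  write_phylip(D, f)
  expect_equal(as.integer(trimws(readLines(f, 1))), 6L)
  unlink(f)
})
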