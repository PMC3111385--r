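# Construction of the packaged synthetic reference set.
#
# The original structure-guided master alignment cannot be redistributed, so
# the package ships a synthetic stand-in built on a single MIP scaffold: a
# 301-column alignment in which every structural element, anchor landmark,
# diagnostic motif and ar/R filter column is placed by construction (see
# blueprint.R).  Subfamily templates diverge from the scaffold at a fixed rate
# outside protected feature columns, and individual rows (reference proteins
# and the algal/viral query set) add row-level divergence plus the exact
# feature strings tabulated for them (ar/R filter, NPA boxes, motif
# presence/absence).  Everything is a pure function of the seeds fixed here,
# so the packaged text files under inst/extdata can be regenerated at any
# time.

.mip_gap <- "-"

.mip_helix_pool <- c("A","L","I","V","F","G","S","T","M","W")
.mip_loop_pool  <- c("G","S","T","N","D","E","K","R","P","Q","A","H","Y")

# columns that carry curated features and are never drifted
.mip_protected_cols <- function() {
  ac <- .anchor_col
  sort(unique(c(
    ac(28L), ac(31L),                 # Ca2+ gating sites
    ac(55L):ac(69L),                  # loop A cysteine window
    ac(76L), ac(81L),                 # H2 glycine, ar/R H2
    ac(99L),                          # loop B histidine
    ac(102L):ac(110L),                # pre-NPA1 motif window
    ac(110L):ac(121L),                # KxSxxR window
    ac(120L):ac(122L),                # NPA1
    ac(124L),                         # GlpF T72 column
    ac(137L), ac(141L), ac(145L),     # H3 glutamine, GlpF F89/Q93 columns
    ac(151L):ac(161L),                # GGGAN window
    ac(157L):ac(166L),                # LxxN window
    ac(166L),                         # loop C cysteine
    ac(193L),                         # H193
    ac(210L),                         # ar/R H5
    ac(224L):ac(234L),                # NPA2 + DGCS/DxxxR block + LE1/LE2
    ac(240L),                         # post-HE cysteine
    ac(250L),                         # H6 proline
    ac(265L):ac(281L)                 # C-terminal tail (charge statistic)
  )))
}

# helix vs loop character of each alignment column (for the base draw)
.mip_col_is_helix <- function() {
  el <- .mip_elements()
  helix <- el[el$name %in% c("H1","H2","H3","H4","H5","H6","HB","HE"), ]
  out <- rep(FALSE, .mip_ncol)
  for (i in seq_len(nrow(helix))) out[helix$start_col[i]:helix$end_col[i]] <- TRUE
  out
}

# Base scaffold: one residue per column, landmark columns set to the
# family-wide consensus state (features present in "most MIPs", absent
# otherwise).
.mip_base_row <- function() {
  set.seed(42L)
  helix <- .mip_col_is_helix()
  row <- ifelse(helix,
                sample(.mip_helix_pool, .mip_ncol, replace = TRUE),
                sample(.mip_loop_pool, .mip_ncol, replace = TRUE))
  ac <- .anchor_col
  row[ac(1L)] <- "M"
  row[ac(28L)] <- "S"; row[ac(31L)] <- "T"      # Ca2+ gating absent by default
  row[ac(60L)] <- "A"; row[ac(62L)] <- "G"      # loop A cysteine absent
  row[ac(76L)] <- "G"                           # H2 glycine present
  row[ac(81L)] <- "F"                           # ar/R H2 default
  row[ac(99L)] <- "H"                           # loop B histidine
  row[ac(102L):ac(110L)] <- c("A","T","G","G","H","S","M","E","T")  # GGH at 105-107
  row[ac(113L):ac(118L)] <- c("T","N","G","A","L","G")              # no KxSxxR
  row[ac(119L)] <- "V"
  row[ac(120L):ac(122L)] <- c("N","P","A")      # NPA1
  row[ac(123L):ac(127L)] <- c("V","L","T","G","A")
  row[ac(137L)] <- "Q"                          # H3 glutamine
  row[ac(141L)] <- "A"; row[ac(145L)] <- "V"
  row[ac(151L):ac(158L)] <- c("P","T","S","T","S","D","G","K")      # no GGGAN
  row[ac(159L):ac(166L)] <- c("G","S","S","V","A","F","T","D")      # no LxxN, no cys
  row[ac(193L)] <- "S"                          # pH-gating histidine absent
  row[ac(210L)] <- "H"                          # ar/R H5 default
  row[ac(224L):ac(226L)] <- c("N","P","A")      # NPA2
  row[ac(227L):ac(231L)] <- c("S","D","A","T","G")  # loop E block, no DxxxR
  row[ac(232L)] <- "R"                          # ar/R LE2 default
  row[ac(240L)] <- "T"                          # post-HE cysteine absent
  row[ac(250L)] <- "P"                          # H6 proline present
  row[ac(265L):ac(281L)] <-
    strsplit("SAETGNALSDKTAGETV", "")[[1]]      # low-charge default tail
  row
}

.mip_mutate <- function(row, rate, seed, protected) {
  free <- setdiff(which(row != .mip_gap), protected)
  set.seed(seed)
  k <- round(rate * length(free))
  if (k < 1L) return(row)
  pos <- sample(free, k)
  for (p in pos) row[p] <- sample(setdiff(.mip_aa, row[p]), 1L)
  row
}

# insertion-block fill strings
.mip_fill_la <- c("N","G","T","S")                       # 4 extra loop A residues
.mip_fill_le <- strsplit("ETTGWDSLKAGE", "")[[1]]        # extended loop E (12)

# Subfamily template overrides.  `set` entries are (anchor residue -> residue),
# `gaps` are anchor-residue ranges turned to gaps, `fill_la`/`fill_le` fill the
# insertion blocks.
.mip_subfamily_overrides <- function() {
  list(
    PIP = list(set = list("28" = "D", "31" = "E", "60" = "C", "193" = "H",
                          kxsxxr = TRUE, gggan = TRUE),
               le_block = c("D","G","T","S","K")),
    GIP = list(set = list("137" = "E", "124" = "T", "141" = "F", "145_q93" = TRUE),
               gaps = list(c(1L, 30L)), gap_prenpa1 = TRUE,
               le_block = c("D","A","P","G","R")),
    TIP = list(le_block = c("N","A","G","T","K")),
    NIP = list(le_block = c("S","A","G","N","K")),
    SIP = list(npa1 = "NPL", le_block = c("N","T","G","S","K"),
               cterm = "KASRTNKLSDKTRGETK"),
    XIP = list(set = list("166" = "C"), le_block = c("S","T","A","G","K")),
    HIP = list(le_block = c("N","T","A","G","K")),
    MIPA = list(npa1 = "NPM", le_block = c("T","A","M","G","K")),
    MIPB = list(npa1 = "NPS", npa2 = "NAA",
                set = list("99" = "Q", prenpa1_degenerate = TRUE),
                fill_le = TRUE, le_block = c("S","A","G","T","K")),
    MIPC = list(npa1 = "NPT",
                set = list("76" = "S", "137" = "T", "250" = "A"),
                le_block = c("N","T","G","S","K"),
                cterm = "KRSAKRLGKTRKAKSRV"),
    MIPD = list(set = list("166" = "C", "240" = "C", "250" = "Q"),
                gaps = list(c(36L, 40L), c(67L, 70L)),
                le_block = c("S","T","A","G","K")),
    MIPE = list(set = list(lxxn = TRUE),
                le_block = c("D","G","C","S","K")),
    AQP = list(set = list(lxxn = TRUE), le_block = c("N","T","C","S","K")),
    GLP = list(le_block = c("D","V","P","G","R"))
  )
}

.mip_apply_overrides <- function(row, ov) {
  ac <- .anchor_col
  if (is.null(ov)) return(row)
  st <- ov$set
  if (!is.null(st)) {
    for (nm in names(st)) {
      if (nm == "kxsxxr") {
        row[ac(113L):ac(118L)] <- c("K","V","S","A","F","R")
      } else if (nm == "gggan") {
        row[ac(154L):ac(158L)] <- c("G","G","G","A","N")
      } else if (nm == "lxxn") {
        row[ac(160L):ac(163L)] <- c("L","A","G","N")
      } else if (nm == "prenpa1_degenerate") {
        row[ac(105L):ac(107L)] <- c("S","K","T")
      } else if (nm == "145_q93") {
        row[ac(145L)] <- "Q"
      } else {
        row[ac(as.integer(nm))] <- st[[nm]]
      }
    }
  }
  if (!is.null(ov$npa1)) row[ac(120L):ac(122L)] <- strsplit(ov$npa1, "")[[1]]
  if (!is.null(ov$npa2)) row[ac(224L):ac(226L)] <- strsplit(ov$npa2, "")[[1]]
  if (!is.null(ov$le_block)) row[ac(227L):ac(231L)] <- ov$le_block
  if (!is.null(ov$cterm)) row[ac(265L):ac(281L)] <- strsplit(ov$cterm, "")[[1]]
  if (isTRUE(ov$fill_la)) row[63L + seq_along(.mip_fill_la)] <- .mip_fill_la
  if (isTRUE(ov$fill_le)) row[246L + seq_along(.mip_fill_le)] <- .mip_fill_le
  if (isTRUE(ov$gap_prenpa1)) row[ac(105L):ac(113L)] <- .mip_gap
  for (g in ov$gaps) row[ac(g[1]):ac(g[2])] <- .mip_gap
  if (!is.null(ov$filter)) {
    arr <- .mip_arr_columns()
    f <- strsplit(ov$filter, "")[[1]]
    row[arr] <- f
  }
  if (!is.null(ov$gap_cols)) for (g in ov$gap_cols) row[g[1]:g[2]] <- .mip_gap
  row
}

# Subfamily template rows: base + subfamily drift + subfamily overrides.
.mip_templates <- function() {
  base <- .mip_base_row()
  base[c(63:70, 247:258)] <- .mip_gap   # insertion blocks empty by default
  prot <- .mip_protected_cols()
  ovs <- .mip_subfamily_overrides()
  out <- list()
  for (i in seq_along(ovs)) {
    s <- names(ovs)[i]
    row <- .mip_mutate(base, rate = 0.25, seed = 7000L + i, protected = prot)
    out[[s]] <- .mip_apply_overrides(row, ovs[[s]])
  }
  out
}

# Every packaged row: reference proteins (role "ref") and the algal + viral
# query entries (role "query").  `filter` is the ar/R filter H2,H5,LE1,LE2 as
# printed; `ov` holds row-specific deviations from the subfamily template.
.mip_row_catalog <- function() {
  ac <- .anchor_col
  row <- function(id, role, label, tag, template, filter, npa1, npa2,
                  substrate = NA_character_, ov = NULL) {
    list(id = id, role = role, label = label, tag = tag, template = template,
         filter = filter, npa1 = npa1, npa2 = npa2, substrate = substrate,
         ov = ov)
  }
  c(list(
    ## reference rows -----------------------------------------------------
    row("AtPIP2;3", "ref", "PIP", "At", "PIP", "FHTR", "NPA", "NPA", "water"),
    row("SoPIP2;1", "ref", "PIP", "So", "PIP", "FHTR", "NPA", "NPA"),
    row("PpPIP1;1", "ref", "PIP", "Pp", "PIP", "FHTR", "NPA", "NPA"),
    row("PpPIP2;1", "ref", "PIP", "Pp", "PIP", "FHTR", "NPA", "NPA"),
    row("PpGIP1;1", "ref", "GIP", "Pp", "GIP", "FVPR", "NPA", "NPA", "glycerol"),
    # 43 N-terminal gap columns + the loop A block + the short pre-NPA1 loop
    # put EcGlpF residues 72/89/93 at the GlpF packing columns by construction
    row("EcGlpF",   "ref", "GIP", "Ec", "GIP", "WGFR", "NPA", "NPA",
        ov = list(gaps = list(c(1L, 43L)))),
    row("AtTIP2;1", "ref", "TIP", "At", "TIP", "HIGR", "NPA", "NPA", "water"),
    row("OsTIP4;1", "ref", "TIP", "Os", "TIP", "TTAR", "NPA", "NPA", "water/glycerol",
        ov = list(le_block = c("S","T","A","G","K"))),
    row("OsNIP2;1", "ref", "NIP", "Os", "NIP", "GSGR", "NPA", "NPA", "unknown"),
    row("AtNIP1;1", "ref", "NIP", "At", "NIP", "WVAR", "NPA", "NPA",
        ov = list(le_block = c("S","T","A","G","K"))),
    row("ZmSIP2;1", "ref", "SIP", "Zm", "SIP", "SHGS", "NPL", "NPA", "unknown"),
    row("PpSIP1;1", "ref", "SIP", "Pp", "SIP", "IVGS", "NPT", "NPA"),
    row("PpXIP1;1", "ref", "XIP", "Pp", "XIP", "IVAR", "NPA", "NPA"),
    row("NtXIP1;1", "ref", "XIP", "Nt", "XIP", "IVAR", "NPA", "NPA"),
    row("PpHIP1;1", "ref", "HIP", "Pp", "HIP", "HIAR", "NPA", "NPA"),
    row("MIPA_REF1", "ref", "MIPA", "", "MIPA", "HMMR", "NPM", "NPA"),
    row("MIPA_REF2", "ref", "MIPA", "", "MIPA", "HMMR", "NPM", "NPA"),
    row("MIPB_REF1", "ref", "MIPB", "", "MIPB", "YLGR", "NPS", "NAA"),
    row("MIPB_REF2", "ref", "MIPB", "", "MIPB", "YFGR", "NPS", "NAA"),
    row("MIPC_REF1", "ref", "MIPC", "", "MIPC", "LCGV", "NPT", "NPA"),
    row("MIPC_REF2", "ref", "MIPC", "", "MIPC", "ITGV", "NPT", "NPA"),
    row("MIPD_REF1", "ref", "MIPD", "", "MIPD", "NAAR", "NPA", "NPA"),
    row("MIPD_REF2", "ref", "MIPD", "", "MIPD", "TLSR", "NPA", "NPA"),
    row("MIPE_REF1", "ref", "MIPE", "", "MIPE", "FHCR", "NPA", "NPA"),
    row("MIPE_REF2", "ref", "MIPE", "", "MIPE", "FHCR", "NPA", "NPA"),
    row("HsAQP5",   "ref", "AQP", "Hs", "AQP", "FHCR", "NPA", "NPA", "water"),
    row("GLA_Llac", "ref", "GLP", "",  "GLP", "YVPR", "NPA", "NPA", "water/glycerol"),
    ## algal queries (Table 1 naming) -------------------------------------
    row("CrMIPD1;1", "query", "MIPD", "Cr", "MIPD", "NAAR", "NPA", "NPA", "glycerol"),
    row("CrMIPD2;1", "query", "MIPD", "Cr", "MIPD", "TLSR", "NPL", "NPA",
        ov = list(set = list("250" = "E"), le_block = c("S","T","S","G","K"))),
    row("VcMIPD1;1", "query", "MIPD", "Vc", "MIPD", "NAAR", "NPA", "NPA"),
    row("VcMIPD2;1", "query", "MIPD", "Vc", "MIPD", "TLSR", "NPA", "NPA",
        ov = list(set = list("250" = "E"), le_block = c("S","T","S","G","K"))),
    row("VcMIPD4;1", "query", "MIPD", "Vc", "MIPD", "NATH", "NPT", "NPA",
        ov = list(set = list("250" = "H"), le_block = c("S","T","T","G","K"))),
    row("CcMIPD1;1", "query", "MIPD", "Cc", "MIPD", "NAAR", "NPA", "NPA"),
    row("CcMIPD3;1", "query", "MIPD", "Cc", "MIPD", "STAR", "NPA", "NPA"),
    row("CnMIPD1;1", "query", "MIPD", "Cn", "MIPD", "NAAR", "NPA", "NPA"),
    row("CcMIPA1;1", "query", "MIPA", "Cc", "MIPA", "HMMR", "NPM", "NPA"),
    row("CcPIP4;1", "query", "PIP", "Cc", "PIP", "FHCR", "NPA", "NPA",
        ov = .mip_algal_pip_ov()),
    row("CcPIP4;2", "query", "PIP", "Cc", "PIP", "FHCR", "NPA", "NPA",
        ov = c(.mip_algal_pip_ov(),
               list(set2 = list(gggan_partial = TRUE)))),
    row("CcGIP1;1", "query", "GIP", "Cc", "GIP", "FLNR", "NPA", "NPA",
        ov = list(le_block = c("D","A","N","G","R"))),
    row("CnGIP1;1", "query", "GIP", "Cn", "GIP", "FIIR", "NPA", "NPA",
        ov = list(le_block = c("D","A","I","G","R"), scramble_h4 = TRUE)),
    row("CnMIPE1;1", "query", "MIPE", "Cn", "MIPE", "FHCR", "NPA", "NPA",
        ov = list(set = list("99" = "Q"))),
    row("CnMIPE1;2", "query", "MIPE", "Cn", "MIPE", "AHCR", "NAA", "NPT"),
    row("CnMIPE1;3", "query", "MIPE", "Cn", "MIPE", "FHCR", "NPA", "NPA",
        ov = list(gaps = list(c(180L, 207L)))),
    row("OrMIPE1;1", "query", "MIPE", "Or", "MIPE", "FHCR", "NPA", "NPA",
        ov = list(set = list("99" = "Q"), fill_le = TRUE, fill_le_variant = TRUE)),
    row("MpMIPC1;1", "query", "MIPC", "Mp", "MIPC", "LCGV", "NPT", "NPA"),
    row("MrMIPC1;1", "query", "MIPC", "Mr", "MIPC", "ITGV", "NPT", "NPA"),
    row("OtMIPC1;1", "query", "MIPC", "Ot", "MIPC", "VMCP", "NPV", "NPS",
        ov = list(set = list("137" = "S"), le_block = c("N","T","C","S","K"))),
    row("OlMIPB1;1", "query", "MIPB", "Ol", "MIPB", "YLGR", "NPS", "NAA"),
    row("OrMIPB1;1", "query", "MIPB", "Or", "MIPB", "YFGR", "NPS", "NAA"),
    row("PbcvMT325GIP1;1", "query", "GIP", "PbcvMT325", "GIP", "FVIR", "NPA", "NPA",
        ov = list(le_block = c("D","A","I","G","R")))
  ))
}

# algal PIPs: Ca2+ gating absent, loop A cysteine offset by two, longer loop A,
# DGCS loop E block (cysteine at LE1)
.mip_algal_pip_ov <- function() {
  list(set = list("28" = "N", "31" = "Q", "60" = "A", "62" = "C"),
       fill_la = TRUE, le_block = c("D","G","C","S","K"))
}

.mip_build_row <- function(entry, templates, prot, seed_offset) {
  row <- templates[[entry$template]]
  ov <- entry$ov
  # row-level drift first (protected columns excluded), then row overrides
  row <- .mip_mutate(row, rate = 0.05, seed = seed_offset, protected = prot)
  row <- .mip_apply_overrides(row, c(ov, list(
    filter = entry$filter, npa1 = entry$npa1, npa2 = entry$npa2)))
  ac <- .anchor_col
  if (!is.null(ov$set2$gggan_partial))
    row[ac(154L):ac(158L)] <- c("L","G","A","S","N")
  if (isTRUE(ov$fill_le_variant))
    row[247L:258L] <- strsplit("ETTGWDSLKSGE", "")[[1]]
  if (isTRUE(ov$scramble_h4)) {
    h4 <- setdiff(ac(172L):ac(187L), prot)
    set.seed(seed_offset + 1L)
    row[h4] <- sample(.mip_aa, length(h4), replace = TRUE)
  }
  row
}

#' Synthesize the packaged reference set
#'
#' Builds the synthetic stand-in for the curated master alignment: 27
#' reference rows (at least one per subfamily, including the SoPIP2;1 and
#' EcGlpF anchor rows) plus the 22 algal and one viral query entries, together
#' with the column annotation (structural elements, ar/R columns, core
#' interval, anchors, motif ledger, characterized substrate filters).
#'
#' @param seed integer seed; the packaged files use the default.
#' @return list with components `aln` (character matrix, rows x 301 columns,
#'   gap `"-"`), `role`, `subfamily`, `species_tag` (named vectors), and
#'   `annotation` (list mirroring the YAML annotation schema).
#' @export
synthesize_reference_set <- function(seed = 101L) {
  cat_ <- .mip_row_catalog()
  templates <- .mip_templates()
  prot <- .mip_protected_cols()
  aln <- matrix(.mip_gap, nrow = length(cat_), ncol = .mip_ncol)
  ids <- character(length(cat_))
  role <- subfam <- tag <- character(length(cat_))
  for (i in seq_along(cat_)) {
    e <- cat_[[i]]
    ids[i] <- e$id
    role[i] <- e$role
    subfam[i] <- e$label
    tag[i] <- e$tag
    aln[i, ] <- .mip_build_row(e, templates, prot,
                               seed_offset = .mip_derive_seed(seed, 100, i))
  }
  rownames(aln) <- ids
  el <- .mip_elements()
  annotation <- list(
    elements = el,
    arr_columns = as.list(.mip_arr_columns()),
    core_interval = .mip_core_interval(),
    anchors = c("SoPIP2;1", "EcGlpF"),
    subfamilies = stats::setNames(as.list(subfam[role == "ref"]),
                                  ids[role == "ref"]),
    motifs = .mip_motif_ledger(),
    substrates = .mip_substrate_table()
  )
  list(aln = aln, role = stats::setNames(role, ids),
       subfamily = stats::setNames(subfam, ids),
       species_tag = stats::setNames(tag, ids),
       annotation = annotation)
}

#' Synthesize the packaged query set
#'
#' Returns the 22 algal plus one viral synthetic query entries as unaligned
#' proteins and back-translated coding sequences, together with the truth
#' table of planted features (ar/R filter, NPA boxes, true column map).
#'
#' @inheritParams synthesize_reference_set
#' @return list with `proteins` (named character vector), `cds` (named
#'   character vector), `truth` (data.frame) and `col_maps` (list of integer
#'   vectors mapping alignment columns to query residue indices).
#' @export
synthesize_query_set <- function(seed = 101L) {
  rs <- synthesize_reference_set(seed)
  q <- names(rs$role)[rs$role == "query"]
  proteins <- character(0)
  col_maps <- list()
  for (id in q) {
    row <- rs$aln[id, ]
    keep <- row != .mip_gap
    proteins[id] <- paste(row[keep], collapse = "")
    cm <- rep(NA_integer_, .mip_ncol)
    cm[keep] <- seq_len(sum(keep))
    col_maps[[id]] <- cm
  }
  cds <- vapply(proteins, .mip_back_translate, character(1))
  arr <- .mip_arr_columns()
  truth <- data.frame(
    id = q,
    subfamily = unname(rs$subfamily[q]),
    species_tag = unname(rs$species_tag[q]),
    h2 = rs$aln[q, arr["H2"]], h5 = rs$aln[q, arr["H5"]],
    le1 = rs$aln[q, arr["LE1"]], le2 = rs$aln[q, arr["LE2"]],
    npa1 = apply(rs$aln[q, .anchor_col(120L):.anchor_col(122L), drop = FALSE],
                 1, paste, collapse = ""),
    npa2 = apply(rs$aln[q, .anchor_col(224L):.anchor_col(226L), drop = FALSE],
                 1, paste, collapse = ""),
    stringsAsFactors = FALSE
  )
  rownames(truth) <- NULL
  list(proteins = proteins, cds = cds, truth = truth, col_maps = col_maps)
}

.mip_back_translate <- function(protein) {
  aa <- strsplit(protein, "")[[1]]
  paste(c(.mip_codon_table[aa], "TAA"), collapse = "")
}
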