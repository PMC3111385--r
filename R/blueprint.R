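# Internal blueprint of the curated reference alignment.
#
# The reference coordinate system is expressed in the residue numbering of the
# SoPIP2;1 anchor row (1..281) and mapped to alignment columns by inserting two
# gap blocks that absorb subfamily-specific insertions: 8 columns inside loop A
# (after anchor residue 62, the longer loop A of algal PIPs) and 12 columns in
# the loop connecting HE and H6 (after anchor residue 238, the extended loop E
# of MIPBs and OrMIPE1;1).  All landmark residue numbers below follow the
# anchor conventions used throughout the MIP literature: D28/E31 (Ca2+ gating),
# C60 (loop A cysteine), G76 (helix 2 packing glycine), F81 (ar/R H2), the
# KxSxxR loop B phosphorylation motif around S115, NPA1 at 120-122, Q137
# (helix 3 glutamine), H193 (pH-gating histidine in loop D), H210 (ar/R H5),
# NPA2 at 224-226, the loop E filter positions LE1/LE2, and P250 (helix 6
# proline).

.mip_ins_la <- 8L   # gap block after anchor residue 62
.mip_ins_le <- 12L  # gap block after anchor residue 238
.mip_anchor_len <- 281L
.mip_ncol <- .mip_anchor_len + .mip_ins_la + .mip_ins_le  # 301

# alignment column of an anchor (SoPIP2;1) residue number
.anchor_col <- function(r) {
  r + .mip_ins_la * (r > 62L) + .mip_ins_le * (r > 238L)
}

.mip_elements <- function() {
  res <- rbind(
    c("H1",   36, 56),
    c("LA",   57, 66),
    c("H2",   67, 87),
    c("LB",   88, 131),
    c("HB",  120, 131),
    c("NPA1",120, 122),
    c("H3",  132, 152),
    c("LC",  153, 170),
    c("H4",  171, 188),
    c("LD",  189, 196),
    c("H5",  197, 217),
    c("LE",  218, 243),
    c("HE",  224, 236),
    c("NPA2",224, 226),
    c("H6",  244, 264)
  )
  data.frame(
    name = res[, 1],
    start_col = .anchor_col(as.integer(res[, 2])),
    # an element ending right before a gap block also spans that block
    end_col = .anchor_col(as.integer(res[, 3]) + 1L) - 1L,
    stringsAsFactors = FALSE
  )
}

.mip_arr_columns <- function() {
  c(H2 = .anchor_col(81L), H5 = .anchor_col(210L),
    LE1 = .anchor_col(229L), LE2 = .anchor_col(232L))
}

.mip_core_interval <- function() c(34L, 286L)

.mip_subfamilies <- c("PIP", "GIP", "TIP", "NIP", "SIP", "XIP", "HIP",
                      "MIPA", "MIPB", "MIPC", "MIPD", "MIPE")

# Motif ledger.  Pattern motifs are regular expressions (X already expanded to
# ".") searched in the gap-stripped query text of a column window (the window
# includes +/- 3 columns of slack around the nominal element location).  Site
# motifs are read at anchor-mapped columns and require the stated residues.
.mip_motif_ledger <- function() {
  pat <- function(id, pattern, from, to, note) {
    data.frame(motif_id = id, kind = "pattern", pattern = pattern,
               window_start = from, window_end = to,
               anchor_id = NA_character_, resnums = NA_character_,
               expect = NA_character_, note = note, stringsAsFactors = FALSE)
  }
  site <- function(id, anchor, resnums, expect, note) {
    data.frame(motif_id = id, kind = "site", pattern = NA_character_,
               window_start = NA_integer_, window_end = NA_integer_,
               anchor_id = anchor, resnums = paste(resnums, collapse = ","),
               expect = paste(expect, collapse = ","), note = note,
               stringsAsFactors = FALSE)
  }
  ac <- .anchor_col
  rbind(
    pat("kxsxxr",   "K.S..R", ac(110L), ac(121L), "loop B phosphorylation motif of PIPs"),
    pat("pre_npa1", "GGH",    ac(102L), ac(110L), "conserved motif leading up to NPA1; degenerate in MIPBs"),
    pat("gggan",    "GGGAN",  ac(151L), ac(161L), "loop C motif of PIPs"),
    pat("lxxn",     "L..N",   ac(157L), ac(166L), "loop C motif shared by MIPEs and classical mammalian aquaporins"),
    pat("dgcs",     "DGCS",   ac(224L), ac(234L), "loop E motif of MIPEs and algal PIPs; C sits at LE1"),
    pat("dxxxr",    "D...R",  ac(227L), ac(234L), "glycerol-channel motif just after NPA2"),
    pat("loopA_cys","C",      ac(55L),  ac(69L),  "loop A cysteine of plant PIPs (offset by two in algal PIPs)"),
    site("h193",      "SoPIP2;1", 193L, "H", "pH-gating histidine, loop D"),
    site("ca_gating", "SoPIP2;1", c(28L, 31L), c("D", "E"), "N-terminal acidic residues of Ca2+ gating"),
    site("s115",      "SoPIP2;1", 115L, "S", "loop B phosphoserine"),
    site("h2_gly",    "SoPIP2;1", 76L,  "G", "helix 2 packing glycine; missing in MIPCs"),
    site("h3_gln",    "SoPIP2;1", 137L, "Q", "helix 3 glutamine; S/T in MIPCs, E/N in GIPs"),
    site("h6_pro",    "SoPIP2;1", 250L, "P", "helix 6 proline; substituted in MIPCs and MIPDs"),
    site("loopC_cys", "SoPIP2;1", 166L, "C", "loop C cysteine of MIPDs and XIPs"),
    site("postHE_cys","SoPIP2;1", 240L, "C", "cysteine in the loop after HE, conserved in MIPDs"),
    site("glpf_packing", "EcGlpF", c(72L, 89L, 93L), c("T", "F", "Q"),
         "GlpF-type core packing residues near NPA1 (EcGlpF numbering)")
  )
}

# Characterized ar/R filters used by the nearest-neighbour substrate heuristic.
# Substrates outside the {water, glycerol, water/glycerol} vocabulary collapse
# to "unknown".
.mip_substrate_table <- function() {
  data.frame(
    id        = c("AtTIP2;1", "GLA_Llac", "ZmSIP2;1", "OsNIP2;1", "OsTIP4;1",
                  "HsAQP5", "AtPIP2;3", "PpGIP1;1", "CrMIPD1;1"),
    h2        = c("H", "Y", "S", "G", "T", "F", "F", "F", "N"),
    h5        = c("I", "V", "H", "S", "T", "H", "H", "V", "A"),
    le1       = c("G", "P", "G", "G", "A", "C", "T", "P", "A"),
    le2       = c("R", "R", "S", "R", "R", "R", "R", "R", "R"),
    substrate = c("water", "water/glycerol", "unknown", "unknown",
                  "water/glycerol", "water", "water", "glycerol", "glycerol"),
    stringsAsFactors = FALSE
  )
}

# Clustal-convention residue similarity groups used by similarity_string().
.mip_strong_groups <- c("STA", "NEQK", "NHQK", "NDEQ", "QHRK", "MILV", "MILF",
                        "HY", "FYW")
.mip_weak_groups <- c("CSA", "ATV", "SAG", "STNK", "STPA", "SGND", "SNDEQK",
                      "NDEQHK", "NEQHRK", "FVLIM", "HFY")

# derive a per-unit seed from a base seed and a salt without integer
# overflow; equals base * scale + salt whenever that fits in an integer
.mip_derive_seed <- function(base, scale, salt) {
  as.integer((as.numeric(base) * scale + salt) %% 2147483647)
}

.mip_aa <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S",
             "T","W","Y","V")

# Most-frequent-codon back-translation table (a standard plant-biased choice).
.mip_codon_table <- c(
  A = "GCT", R = "AGA", N = "AAC", D = "GAT", C = "TGT", Q = "CAA", E = "GAA",
  G = "GGT", H = "CAT", I = "ATT", L = "CTT", K = "AAG", M = "ATG", F = "TTC",
  P = "CCA", S = "TCT", T = "ACT", W = "TGG", Y = "TAC", V = "GTT", X = "NNN"
)
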