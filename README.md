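# mipscan

Identification and classification of major intrinsic proteins (MIPs,
aquaporin-family channels) from protein or coding sequences.

MIPs are six-transmembrane channels whose function is readable from a handful
of sequence features: the twin NPA boxes in loops B and E, the four-residue
aromatic/arginine (ar/R) selectivity filter, subfamily-diagnostic motifs and
gating residues, and the charge of the cytoplasmic C-terminus.  `mipscan`
transfers all of these annotations from a structure-anchored reference
alignment onto query sequences, places the queries in a bootstrapped
neighbor-joining tree of reference subfamilies, and combines both kinds of
evidence into a subfamily call and a proposed isoform name.

## What the package does

* **Reference model** — a curated, structure-anchored reference alignment
  (packaged as a synthetic stand-in under `inst/extdata`) with per-column
  annotation: helices H1–H6, loops A–E with the two half-helices, NPA boxes,
  the ar/R filter columns, a motif ledger, characterized substrate filters
  and two anchor numbering systems (a spinach PIP2 and the *E. coli* glycerol
  facilitator).
* **Profile alignment** — deterministic global (Needleman–Wunsch) alignment
  of a query against the reference column profile with affine gaps
  (BLOSUM62, open 11, extend 1) and position-specific reference-gap costs;
  core trimming; Clustal-style similarity strings.
* **Feature extraction** — NPA motifs, ar/R filter (with mercury-sensitivity
  cysteine flag), diagnostic motif scan, loop lengths, C-terminal charge and
  a nearest-neighbour substrate heuristic.
* **Phylogenetic placement** — protein distances with a Kimura-style
  correction, an internal neighbor-joining implementation with a
  deterministic tie-break (validated against `ape::nj`), column-resampling
  bootstrap, smallest-supported-clade placement and a motif/placement rule
  table with explicit conflict handling.
* **Intron mapping** — gene models from exon tables or GFF3 CDS features,
  intron phase/codon-index computation on either strand, projection onto
  alignment columns and detection of intron positions shared across genes.
* **Enrichment statistic** — a resampling per-column residue-enrichment test
  between two groups of alignment rows (empirical `(r+1)/(n+1)` p-values,
  gaps excluded).
* **Synthetic data** — generators for subfamily-typical sequences with
  ground-truth feature tables, and for gene models that round-trip exactly.

## Quick start

```r
library(mipscan)

# classify coding sequences against the packaged reference
cds <- system.file("extdata", "algal_mip_cds.synthetic.fasta",
                   package = "mipscan")
run <- run_classify(cds, out_dir = "mipscan_out",
                    config = run_config(n_reps = 100, seed = 1))
run$calls_df            # subfamily calls, support, proposed names
run$table               # Table-2 style feature table

# features only
run_table2(cds, path = "features.tsv")

# one query, step by step
ref <- mip_reference()
qs  <- Biostrings::readBStringSet(cds)
aq  <- align_to_profile(mip_sequence("q1", as.character(
         Biostrings::translate(Biostrings::DNAString(
           substr(as.character(qs[[1]]), 1, width(qs)[1] - 3)),
           no.init.codon = TRUE))), ref)
feature_profile(trim_to_core(aq, ref), ref)
```

A thin command-line interface wrapping the same functions ships as
`inst/scripts/mipscan.R` (`classify`, `table2`, `tree`, `introns`, `logo`,
`simulate`).

## Reproducibility

Every stochastic step (bootstrap, resampling statistic, synthetic data) is a
pure function of an integer seed below 2^31.  The packaged fixtures under
`inst/extdata` are regenerated exactly by `tools/make_extdata.R`.

## Documentation

* `vignette("mipscan-methods")` — methods, coordinate conventions, rule
  table, limitations.
* `scripts/acceptance.R` — end-to-end acceptance metrics
  (`Rscript scripts/acceptance.R --seed 1 --out acceptance.json`).

## License

MIT (see `LICENSE`).
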