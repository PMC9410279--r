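---
title: "Discovering three-finger proteins by their LU-domain scaffold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering three-finger proteins by their LU-domain scaffold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lustar)
```

## The problem

Three-finger proteins (TFPs, the Ly6/uPAR family) are small β-structural
proteins whose conserved unit, the LU-domain, consists of three loops
("fingers") emerging from a compact core stabilized by four invariant
disulfide bonds, with up to three additional bonds in the fingers. The
family spans snake venom toxins, mammalian neuromodulators such as Lynx1/
Lynx2 and the SLURPs, complement regulators, and many invertebrate
proteins. Because overall sequence identity across the family is low while
the 8–10 scaffold cysteines are nearly invariant, finding new members in a
proteome and aligning them sensibly both hinge on treating cysteines as
anchors rather than ordinary residues.

`lustar` implements that analysis end to end: curate a reference set of
single-LU-domain proteins, search a target proteome for homologs with exact
local alignment and E-value statistics, extract candidate LU-domains, build
a neighbor-joining guide tree, compute a cysteine-anchored progressive
multiple alignment, and score pairwise relatedness with a grouped-residue
percent similarity. A synthetic-data generator emulates the statistical
structure of the real inputs so every stage is testable offline.

## Recognizing an LU-domain scaffold

No sequence database records "this is an LU-domain" in a machine-checkable
way, so detection needs an operational rule. Ours is:

* 8–10 consecutive cysteines within a window of at most 170 residues
  (`curation_config(window = )`), and
* the last four cysteines carry the family's C-terminal signature: an
  adjacent `CC` doublet, a short spacer (3–5 residues, canonically 4), the
  final cysteine, and a following `N` that is preferred but not required.

Among candidate windows the best is chosen by: terminal `CN` motif first,
then more cysteines, then the leftmost start. This rule is an
operationalization of the family's invariant disulfide core, not a database
convention, and every threshold is exposed in `curation_config()` so the
rule can be tightened or relaxed. Curation keeps reference proteins of at
most 190 residues — longer proteins risk carrying more than one LU-domain —
and additionally drops records with two or more disjoint scaffolds. The
pure length rule is recoverable with `check_multi_scaffold = FALSE`.
Domains are extracted from the first to the last scaffold cysteine plus a
2-residue margin (tolerates ragged ends without engulfing flanks), clipped
to the sequence, and must be at least 60 residues. All coordinates in every
output are 1-based inclusive.

```{r curation}
fam <- generate_family(scaffold_spec(n_cys = 10), n_members = 4,
                       mutation_rate = 0.25, seed = 1)
domains <- curate_reference_set(fam$records)
domains[, c("parent_id", "start", "end", "n_cys")]
```

## Two matrices, two jobs

The package carries two substitution matrices. `blosum62()` is the
canonical BLOSUM62 table, embedded as a constant for bit-exact
reproducibility. `cysteine_anchored_matrix()` is BLOSUM62 with the cysteine
row and column overwritten: C/C scores **99**, C against anything else
scores **−4**. BLOSUM62's native C/C reward (9) lets an alignment trade a
cysteine pairing for a handful of good hydrophobic matches; the 99/−4
coefficients make cysteine pairing dominate every other consideration, so
alignments of scaffold-bearing proteins pin homologous cysteines into
shared columns.

The two matrices deliberately serve different stages:

* **Search uses BLOSUM62.** The Karlin–Altschul constants
  (λ = 0.267, K = 0.041, the values tabulated for BLOSUM62 with gap
  penalties 11/1) make bit scores and E-values meaningful only under that
  matrix. Under the anchored matrix, chance cysteine pairings in unrelated
  sequences score so highly that essentially every cysteine-containing
  decoy passes any E-value filter — we measured exactly this on uniform
  synthetic decoys. The anchored matrix is an alignment device, not a
  search statistic.
* **Distance, progressive alignment and similarity default to the anchored
  matrix**, where its column-pinning behavior is the point.

Ambiguity codes are accepted on input and scored conservatively as the
minimum over their expansion (`B`→D/N, `Z`→E/Q, `J`→I/L, `U`→C, `O`→K),
with `X` a flat −4 against everything: an unknown residue can never inflate
a score.

## The search model

`smith_waterman()` is exact affine-gap local alignment: a gap of length
*L* costs `gap_open + L * gap_extend` (11 + *L* by default). It replaces a
heuristic word-seeded search with a computation that a brute-force
enumeration oracle can verify, which the test suite does exhaustively at
small lengths. Traceback ties are broken diagonal > up > left and the end
cell is the smallest (row, column) among maxima, so output is
deterministic to the byte.

Scores convert to bit scores and E-values by the standard Karlin–Altschul
form, `bit = (λS − ln K)/ln 2` and `E = m·n·2^(−bit)`, with the subject
size *n* equal to the total residue count of the proteome. Two documented
simplifications relative to BLAST: no finite-size ("edge") length
correction, and no composition-based score adjustment. Hits pass at
`E < 1e-5`, a strict inequality. Because the search is exact rather than
heuristic, hit counts on real genomes are expected to differ slightly from
BLASTP's.

```{r search}
hit <- smith_waterman("CASSC", "CASSC", cysteine_anchored_matrix())
hit[, c("raw_score", "bit_score", "evalue")]
```

## Guide tree and progressive alignment

Pairwise distances are `1 − identity` over the residue–residue columns of
the optimal global alignment (terminal gaps penalized like internal ones,
for simplicity and symmetry of the score). `neighbor_joining()` applies
the canonical Saitou–Nei agglomeration; negative branch lengths — an
artifact of NJ on non-additive inputs — are clamped to zero. The unrooted
topology is what `to_newick()` preserves (six decimal places, quoted
labels where needed); rendering and the order of profile merges use a
midpoint-rooted copy, purely for determinism of display and merge order.

`progressive_align()` merges profiles in post-order over the guide tree.
A profile–profile column score is the mean of all cross-pair residue
scores (pairs involving an existing gap contribute zero); new gaps cost
`gap_open + gap_extend` on the first column and `gap_extend` after, with
ClustalW-scale defaults 10/0.2. Sequence weighting, delayed alignment of
divergent sequences and iterative refinement — refinements of the full
ClustalW pipeline — are deliberately not reproduced: the guide tree's job
here is to group homologs for visual inspection, and on scaffold-bearing
families the 99/−4 anchoring alone keeps scaffold cysteines in all-cysteine
columns (the acceptance suite requires ≥ 95% anchoring at 30% mutation; in
practice it measures 100%).

## Grouped-residue similarity

Relatedness between aligned sequences is reported as the percentage of
alignment columns in which both residues fall in the same physicochemical
group:

```{r groups}
residue_group_scheme() |> split(~group) |> lapply(function(x) x$residue)
```

Gap conventions, chosen to keep the statistic defined and bounded on
ragged alignments: gap–gap columns leave the denominator entirely; a
residue opposite a gap stays in the denominator and counts as a
non-coincidence. Identity implies group coincidence, so the statistic is
never below percent identity. It can be computed from the rows of one
multiple alignment (`similarity_matrix()`, the default in the pipeline) or
from fresh pairwise global alignments (`pairwise_similarity_matrix()`);
published percentages can come from either convention, so both are exposed
and the pipeline records its choice in the run manifest.

## Mass and PCR sanity checks

`average_mass()` returns the average (not monoisotopic) chain mass — the
quantity an ESI/MALDI deconvolution of a ~10 kDa protein reports — minus
exactly two hydrogen masses (2 × 1.00794 Da) per closed disulfide bond.
`insilico_pcr()` locates exact, unique binding sites of a primer pair on a
transcript and returns the delimited product; matching is deliberately
exact because the use case is verifying designed primers on their own
template. Product melting temperature uses the empirical duplex formula
`81.5 + 0.41·%GC − 675/N + 16.6·log10([Na+])` at 50 mM monovalent salt,
valid for products of ≥ 50 bp; predicted values are indicative (the
formula's ~77 °C for a 184 bp half-GC product is the right scale, but no
claim is made that any particular lab calculator would agree to the
degree).

The package bundles the two qPCR primer pairs designed against the
starfish transcript XM_033772626.1 (`qpcr_primer_pairs()`). The native
transcript itself cannot be redistributed, so `synthetic_lu_transcript()`
builds a clearly-labelled synthetic stand-in with the real primer binding
sites embedded at spacings that reproduce the theoretical product lengths
of 184 and 200 bp; site uniqueness is verified at build time.

```{r pcr}
tx <- synthetic_lu_transcript()
primers <- qpcr_primer_pairs()
insilico_pcr(tx, primers$forward[1], primers$reverse[1])[, c("length", "predicted_tm")]
```

## What the synthetic generator does and does not emulate

`generate_family()` radiates members from one random ancestor that honors
a `scaffold_spec()`: 8–10 cysteines, loop spacers drawn to keep the domain
in the 60–190-residue band, and the C-terminal `CC-x(4)-C-N` signature.
Mutations hit only non-cysteine positions — mirroring the family's
invariant disulfide core — and a configurable fraction of them cross
physicochemical groups, the rest staying within group (invisible to the
similarity statistic by construction). `generate_proteome()` surrounds
planted members with random flanks and adds decoys drawn i.i.d. from a
uniform background over the 20 residues (a natural-frequency table can be
supplied via `background`). Flanks avoid cysteine so a planted scaffold
stays its record's only cysteine structure. Loops also avoid cysteine for
the same reason. Both generators are deterministic given their seed and
record ground truth (coordinates, cysteine positions, ancestor).

Deliberate non-features, which bound what passing tests demonstrate about
real data: no indels within families (loop-length variation between
families only), no rate heterogeneity or tree-structured evolution, no
natural amino-acid composition by default, and no paralog structure. Real
proteomes have biased composition, cysteine-rich non-TFP proteins
(protease inhibitors, EGF repeats) that can carry look-alike motifs, and
domains embedded in multidomain architectures. Recovery of 5/5 planted
homologs with zero decoy false positives at 1,000 decoys therefore shows
the machinery is correct and calibrated on its stated null — not that
real-genome searches are error-free.

## Reproducibility and problem sizes

Every random operation takes an explicit seed; a pipeline run writes a
manifest (tool version, input checksums, full configuration, seed) from
which a re-run reproduces the bundle byte for byte. Logging carries no
timestamps for exactly this reason, and the output directory is not part
of the manifest so bundles written to different directories compare
identical.

The test and acceptance suites use desk-scale study sizes chosen to
exercise every code path while keeping a full run in minutes: reference
families of 5–10 members at mutation rates up to 0.5, planted-recovery
proteomes of 1,000 decoys of 100–500 residues with 5 planted homologs at
mutation rate 0.3 across 10 seeds, 10-seed cysteine-anchoring checks,
20 random 6-taxon trees for NJ consistency, and exhaustive
DP-versus-brute-force equality at small lengths over a reduced alphabet.

## Known limitations

* E-values ignore BLAST's edge correction; at very short subject lengths
  they are conservative in the wrong direction (slightly too large `m·n`).
* The scaffold rule requires the C-terminal signature; genuine LU-domains
  with unusual terminal spacing (the spacer range is configurable) or
  fewer than eight cysteines will be missed, as will GPI-anchor and signal
  peptide context, which the package deliberately does not predict.
* The progressive aligner has no iterative refinement; column quality away
  from the anchored cysteines is ordinary progressive-alignment quality.
* `insilico_pcr()` is exact-match only; primers with mismatches or
  degenerate bases find no site.
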