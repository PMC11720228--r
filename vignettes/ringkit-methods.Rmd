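---
title: "Methods: RING-domain grammar scanning, Ka/Ks and salt-stress DEG logic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: RING-domain grammar scanning, Ka/Ks and salt-stress DEG logic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ringkit)
library(dplyr)
```

# The problem

RING (Really Interesting New Gene) E3 ubiquitin ligases are the largest
class of E3 ligases in plants, and genome-wide surveys of *RING* gene
families — in cotton, Arabidopsis, tomato, flax and others — follow a
recurring analysis pattern: find the RING zinc-finger domains in a
proteome, classify them by the residues and spacing at their eight
metal-ligand (ml) positions, characterize the proteins (MW, pI, exon
structure), test duplicate gene pairs for selective constraint with Ka/Ks,
and intersect the family with stress-response expression data. `ringkit`
implements that pattern as a reusable, fully tested pipeline whose every
stage can be exercised on synthetic data with known ground truth.

# The metal-ligand grammar

A RING domain coordinates two zinc ions in a cross-brace arrangement:
ml1/ml2 and ml5/ml6 bind one ion, ml3/ml4 and ml7/ml8 the other. A domain
is therefore described by eight constrained residue positions and seven
spacer lengths, written `C-X2-C-X(11-28)-C-X1-H-...` in the field's
notation. `ring_grammar()` encodes eight type specifications:

```{r grammar}
g <- ring_grammar()
tibble::tibble(
  type = g$type,
  residues = sapply(g$residues, function(r) paste(sapply(r, paste, collapse = "/"), collapse = "-")),
  gaps = sapply(g$gaps, function(x) paste(sapply(x, function(v)
    if (length(v) > 2) paste0(min(v), "-", max(v)) else paste(v, collapse = ",")),
    collapse = ", "))
)
```

Structural constants shared by all types: two residues between ml1–ml2,
one between ml3–ml4, two between ml5–ml6. Type-diagnostic features: His at
both ml4 and ml5 for RING-H2 (C3H2C3); His at ml4 only for RING-HC
(C3HC4), split into HCa and HCb by the ml7–ml8 spacer; RING-v with His
shifted to ml5 and a fixed seven-residue ml4–ml5 loop; RING-C2 with all
eight positions Cys; and the rare RING-S/T, RING-D and RING-G variants.

Three design points deserve notice:

* **RING-HCb ml7–ml8 spacer.** We fix it at four residues — the feature
  that actually separates HCb from HCa. With a two-residue spacer the HCb
  specification would be a strict subset of HCa and could never be
  assigned. Users preferring a different convention can supply their own
  grammar as JSON (`read_grammar()`/`write_grammar()`).
* **RING-D.** The published consensus rows for this type show no
  aspartate; we implement it exactly as printed, i.e. as a fixed-gap
  special case lying inside RING-HCa's ranges. Precedence (below) decides
  the tie in its favor.
* **Precedence.** Types are matched most-constrained-first (G, D, S/T,
  C2, v, HCb, H2, HCa) so that a broad ranged specification never absorbs
  a special case during overlap resolution.

# Scanning and overlap resolution

`enumerate_ring_matches()` returns *every* (type, 8-tuple) match — it is
provably equivalent to brute-force enumeration of all increasing position
tuples, and the test suite asserts that equivalence against an independent
relational-join oracle on a thousand random sequences. Spacer residues are
deliberately unconstrained (real loops contain Cys/His), and the
nonstandard letters X/B/Z/U/* never satisfy an ml constraint but are legal
in spacers. A domain may start at residue 1 or end at the last residue.

Because exhaustive matching can emit overlapping or doubly-labelled hits,
`resolve_ring_hits()` partitions each protein's hits into clusters of
(transitively) overlapping intervals and keeps one hit per cluster: highest
precedence, then leftmost ml1, then smallest span. The `"all"` policy
returns raw matches for anyone wanting the unresolved superset.

# Spacing profiles

`spacing_profile()` tabulates spacer-length distributions per type and
pooled (`"ALL"`), with exact counts and within-stratum fractions — the
numbers behind the familiar per-gap distance-variation panels. Fractions
are kept raw; rounding to percentages is a presentation concern.
`modal_spacing()` reports the most frequent length per stratum, breaking
ties toward the smaller length (an arbitrary but documented and
deterministic convention).

# Molecular weight and isoelectric point

MW is the sum of average (not monoisotopic) residue masses plus one water,
matching how whole-protein MW is conventionally reported. The theoretical
pI uses a Bjellqvist-style pK set (the family of values behind the common
Compute pI/MW service): side chains D 4.05, E 4.45, C 9.0, Y 10.0, H 5.98,
K 10.0, R 12.0; C-terminus 3.55; N-terminus 7.5 with residue-specific
overrides. The net Henderson–Hasselbalch charge is strictly decreasing in
pH and positive at pH 0, so bisection on [0, 14] converges
unconditionally; we iterate to a residual charge below 1e-9. The pK table
is an explicit, swappable argument — we document our parameterization
rather than claim bit-equality with any web service. Nonstandard residues
are an error by default; `permissive = TRUE` substitutes the mean residue
mass and excludes them from charge.

# Ka/Ks estimation

The selection analysis uses Nei–Gojobori (1986) counting with equal
pathway weighting and the Jukes–Cantor correction — the minimal, fully
specifiable standard for near-identical within-genome duplicate pairs.
Per codon, each position contributes the fraction of its three possible
single-base changes that are synonymous, with changes to stop codons
excluded from the denominator, so sites always sum to three per codon.
For codons differing at several positions, differences are averaged over
all orderings of single-step pathways, excluding pathways through stop
codons; in the rare case that every pathway is blocked the codon is
dropped and reported in `n_skipped`, as are codon columns containing `N`,
gaps, or stop codons. Proportions are corrected with
`d = -3/4 * log(1 - 4p/3)`; a proportion at or beyond 3/4 is a saturation
error rather than a silent NaN. The selection call is `purifying` for
ratios below 1, `positive` above 1 (including the `ks = 0, ka > 0`
infinite-ratio case), `neutral` only at exact equality, and `undefined`
for identical sequences. Model-averaged tools (KaKs_Calculator-style) will
give somewhat different values; alignment construction is out of scope —
input is assumed codon-aligned, which is the realistic situation for
recently duplicated gene pairs from one genome.

# Duplication modes and expression logic

`classify_tandem()` calls a pair tandem when both genes are on the same
chromosome within `max_gap` intervening genes (default 0, i.e. strictly
adjacent in gene order) — an MCScanX-like convention; segmental/collinear
block assignments are accepted as external input rather than recomputed.

DEG calling is the exact inclusive rule |log2FC| >= 1 and adjusted
p <= 0.05, applied to externally produced fold changes (typically DESeq2
output; we do not reimplement its shrinkage — `naive_log2fc()` exists for
FPKM-only tables and is labelled non-equivalent). `bh_adjust()` exposes
Benjamini–Hochberg adjustment for tables carrying raw p-values.
`multi_timepoint_sets()` counts DEG time points per gene; direction-mixed
genes count toward the "at least k time points" set but belong to neither
directional all-time-point set. Pair concordance is direction agreement at
every time point where *both* genes are DEGs; pairs never co-DE at any
time point are vacuously concordant and flagged `untested` so they can be
excluded from summaries. `livak()` is the 2^-ddCt closed form.

# Synthetic data: what it does and does not emulate

All fixtures are generated by seeded, side-effect-free generators
returning ground truth alongside the data:

* `simulate_ring_cohort()` plants domains with spacer lengths drawn
  uniformly from each type's grammar range. In the default non-ligand
  mode, spacers and flanks avoid C/H/S/T/G so the planted hits are
  *provably* the only matches; full-alphabet mode stress-tests overlap
  resolution. Two guarantees keep recovery exact: a sampled domain that
  would also satisfy a higher-precedence type (e.g. an HCa draw landing on
  RING-D's fixed gaps) is redrawn, and inter-domain linkers exceed the
  widest grammar gap (45), so no spurious match can straddle two planted
  domains and fuse their overlap clusters.
* `simulate_codon_pairs()` evolves a descendant from a uniform-sense-codon
  ancestor; each site mutates with probability `p_sub`, stop-creating
  proposals are redrawn, nonsynonymous changes are accepted with
  probability `min(1, omega)` and synonymous ones with `min(1, 1/omega)`
  (the latter only bites for `omega > 1`, where damping the synonymous
  rate is what lets the realized dN/dS exceed one).
* `simulate_expression()` plants an exact DEG incidence structure — the
  defaults reproduce the shape of a cotton salt-stress root time course:
  914 genes, time points 1/3/12/48 h, 107/153/273/90 DEGs per time point,
  393 DEG genes with 144 at two or more time points, 13 at all four
  (10 up, 3 down), and 45 direction-concordant duplicate pairs. DEG cells
  receive |log2FC| in [1.1, 6] and adjusted p in [1e-6, 0.04]; every other
  cell violates at least one threshold with margin.

These generators validate the *logic* of each stage, not its behaviour on
real data: they use uniform amino-acid and codon compositions, no codon
usage bias, independent sites, no alignment error, and DEG effect sizes
with a margin around the thresholds. Passing tests therefore demonstrate
correctness of the grammar matching, counting, and set logic — not
robustness to HMM-boundary ambiguity, assembly artifacts, or shrinkage
estimators, which are inherited from the upstream tools a real analysis
would use.

# Validation scale and numerical choices

The test suite and the acceptance script validate at sizes chosen to make
stochastic checks tight while remaining quick on a laptop: oracle
equivalence on 1,000 random 300-residue sequences plus planted
full-alphabet cohorts; exact recovery of 800 planted domains spanning all
eight types (with nine two-domain and two three-domain proteins); dN/dS
recovery on 200 pairs of 10,000 codons at `p_sub = 0.02` for each of
omega = 1 (mean ratio expected in [0.9, 1.1]) and omega = 0.2 (mean in
[0.15, 0.25]); the full 914-gene expression fixture; and the charge
residual |Q(pI)| < 1e-3 over 1,000 random proteins. Ties, degenerate
inputs and error paths (empty files, duplicate IDs, internal stop codons,
saturated distances, infeasible planted structures) are exercised
explicitly.

# Known limitations

* The grammar scanner is not an HMM: it has no position-specific scores or
  E-values and will not find degraded domains outside the literal
  consensus ranges.
* NG86+JC underestimates distances at high divergence and assumes equal
  base frequencies and no transition/transversion bias.
* The pI is "theoretical" in the usual sense: free termini, no
  modifications, context-free pK values.
* Exon counts are taken from the first-listed mRNA of each gene; genes
  with multiple isoforms are summarised by that transcript only.
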