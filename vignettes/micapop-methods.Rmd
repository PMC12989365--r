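---
title: "micapop: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{micapop: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micapop)
```

# The problem

MICA is a polymorphic, stress-inducible NKG2D ligand encoded in the MHC next
to *HLA-B*. High-throughput donor-registry genotyping covers exons 2–5 only,
which has three consequences that this package models explicitly:

1. **Reporting ambiguity.** Some allele sets cannot be distinguished by the
   assay at all; they are reported by one *representative* allele marked
   with `#` (an *ambiguity group* or hash group).
2. **Phasing ambiguity.** Other calls are compatible with more than one
   allele *pair*; the caller emits a candidate set of genotypes.
3. **Copy-number artifacts.** Haplotypes with a *MICA* deletion are reported
   as homozygous (the surviving allele twice); duplication carriers are
   reported with three alleles.

On top of these call-level models, the package provides population-level
analyses: frequency estimation, cross-population ratio tables, *HLA-B*
linkage by co-occurrence, protein variant matrices with MICA-129
classification and null-allele detection, and a hamming/neighbor-joining
phylogeny.

# The frequency estimator

Frequencies are estimated at first-field (protein) resolution over
group-resolved allele labels, in two passes:

* **Pass 1** counts the alleles of unambiguously typed samples and derives
  base frequencies $g$.
* **Pass 2** weights each ambiguous call's candidate multiset $M$ by its
  Hardy–Weinberg genotype probability under $g$ — $2 g_a g_b$ for a
  heterozygous pair, $g_a^2$ for a homozygous pair, the multinomial
  generalization for duplication triples — renormalizes the weights within
  the candidate set, and adds weight × allele multiplicity to the counts.

Design choices worth stating:

* **Single pass by default.** The base frequencies come from unambiguous
  samples only. `em_iterations` can repeat pass 2 with updated frequencies,
  but the default of 0 reflects the original procedure's wording.
* **Genotype, not allele-product, weighting.** "The probability of each
  possible result" is interpreted as the Hardy–Weinberg genotype
  probability including the heterozygote multiplicity factor. The
  brute-force oracle used in the tests enumerates ordered allele tuples and
  therefore arrives at the same multiplicity independently.
* **Renormalization is over the candidate set**, not over all genotypes;
  the procedure description does not say which, and candidate-set
  renormalization is the natural reading of "counts were added according to
  these probabilities".
* **Zero-weight candidate sets** (every candidate contains an allele never
  seen unambiguously, and `smoothing = 0`) are allocated uniformly and
  counted in `zero_weight_calls` rather than dropped or crashed on: alleles
  observed only in ambiguous calls must not abort a run. With
  `smoothing = ε` the base frequencies get `ε` pseudo-counts over the union
  of all alleles seen in any candidate set; 0.5 is a reasonable choice when
  novel alleles occur only ambiguously.
* **Conservation.** Each call contributes exactly its allele cardinality (2,
  or 3 for duplication carriers) to the denominator, so frequencies always
  sum to 1.
* **Determinism.** Ambiguous calls are processed in a canonical order (by
  candidate-set content), which makes the result bit-for-bit invariant
  under permutations of the input rows.

Populations below `min_samples` (default 1000, the reporting cutoff used
for the published tables) are refused unless the caller overrides the
threshold, so that small strata do not silently produce noisy tables.

# What the synthetic cohort generator emulates — and what it does not

`simulate_cohort()` draws, per sample, two haplotypes i.i.d. from the
configured frequency vector (Hardy–Weinberg equilibrium), then applies the
call-level distortions in this order: duplication (extra third allele,
probability `duplication_rate`), deletion (drop one haplotype, report the
survivor twice, probability `deletion_rate`; realistic rates are 0.3% for
European and 2.5% for Chilean cohorts), hash-group masking (every reported
allele replaced by its group representative), and phasing ambiguity
(probability `ambiguity_rate`; the true masked pair is wrapped into a
candidate set of size 2 or 3). Each haplotype carries a deterministic
*HLA-B* partner when its MICA allele is in `linkage_map`, otherwise a draw
from `hla_b_background_freqs`.

**The decoy rule.** Real phasing ambiguity arises from sequence
compatibility and is not described quantitatively in the genotyping
literature, so the decoy topology is a modeling choice: each decoy swaps
one allele of the true pair for a replacement drawn **uniformly** from the
allele universe. Uniform replacement is deliberate. If replacements were
drawn from the population frequencies, the probability of proposing a decoy
would be proportional to exactly the factor by which the Hardy–Weinberg
weighting favors it, the true posterior over the candidate set would become
(near-)uniform, and the estimator — which is fixed by the published
procedure — would be systematically biased toward common alleles. With
uniform replacement, candidate-set membership is approximately
uninformative about which member is true, which is the implicit assumption
of the estimator. A residual factor-2 asymmetry remains for
heterozygous-versus-homozygous candidate pairs (a swap can turn a
heterozygote into a homozygote in one way, but the reverse move has two
starting points); its net effect is a small residual bias, visible in the
recovery suite as errors of roughly one standard error at n = 10,000, and
is accepted.

Simplifications relative to real data, which a green test therefore does
not rule out: no read- or sequence-level error model, no linkage
disequilibrium between MICA alleles beyond the deterministic *HLA-B* map,
no population substructure within a labeled population, duplication
carriers are never additionally ambiguity-masked, and deletion carriers
lose a haplotype uniformly at random.

# Cross-population comparison

`ratio_table()` computes per-allele frequency ratios against a reference
population over the union of both allele sets (absent alleles count as 0).
Flags use strict inequalities — `over` for ratio > 2, `under` for
ratio < 0.5 — evaluated on the *unrounded* ratio; the display column rounds
half-up to 2 decimals, matching the published table's convention. Ratios
with a zero reference frequency are reported as the marker `"-"`, never as
infinity. The packaged frequency fixture reproduces every printed ratio
cell for the ten most frequent alleles; low-frequency rows are excluded
from that check because the published ratios were evidently computed from
unrounded frequencies and cannot be reproduced from the rounded printed
columns.

# Linkage by co-occurrence

`infer_linkage()` implements the published rule verbatim: a MICA allele is
linked to an *HLA-B* allele if it was carried by at least `min_count`
(default 10) samples and **all** of them carried that *HLA-B* allele
("carrying" means at least one copy; a homozygous *HLA-B* pair counts
once). Ambiguous MICA calls are excluded from carrier counts, since without
phased data a candidate-set call does not establish carriage. Ties for the
maximal partner are all reported and never linked. No LD statistics (D′,
r²) are computed — the rule is intentionally the simple co-occurrence
criterion.

# Protein variation

`build_alignment()` is a reference-anchored star alignment: each sequence
is globally aligned to the reference (default `MICA*002`) with BLOSUM62
scoring, gap open 10 / extend 1 (integer constants), and the pairwise
alignments are merged on reference coordinates. This replaces the
proprietary MSA tool used originally; for near-identical-length MICA
proteins the star merge keeps mature-position numbering exact, which is
what the downstream position-indexed analyses (AA129, variant positions)
require. Positions are numbered on the mature protein, AA1 being the first
residue encoded by exon 2; inputs with a leader peptide can declare a
`leader_length` to strip. Insertion columns are tagged `"<pos>+<i>"`.

`X` is treated as an unknown residue, not a wildcard: it mismatches every
other residue. It is allowed to match itself — the alternative (X ≠ X)
would contradict the invariant that the reference has an empty variant
list whenever its own row contains an X.

`detect_null()` aligns a CDS to the reference CDS and reports `frameshift`
for any indel of length ≢ 0 (mod 3) with the exon harboring it,
`premature_stop` for an in-frame stop upstream of the reference stop
(standard nuclear code), and `none` otherwise. Frameshift takes precedence:
a frameshifted sequence almost always also contains a spurious stop, and
the frameshift is the causal mechanism.

`group_by_nearest_frequent()` replaces the original manual similarity
sorting with an automated stand-in: assignment to the hamming-nearest
frequent allele, ties to the lexicographically smallest with a flag. It is
deliberately not a reproduction of the published figure's manual ordering.

# Phylogeny

Distances are raw hamming counts over alignment rows (gap-vs-residue is a
difference, gap-vs-gap is not, no length normalization — complete-coverage
sequences make gaps rare true deletions). `neighbor_joining()` is a
deterministic Saitou–Nei implementation: Q-criterion agglomeration,
ties broken toward the lowest index pair, negative branch lengths clamped
to zero with the deficit recorded in an attribute. It is exact on additive
matrices, which the test suite verifies on 100 random additive matrices
against path-distance recovery and against the independent `ape::nj`
implementation. `midpoint_root()` places the root at the midpoint of the
longest leaf-to-leaf path (ties again to the lowest leaf index pair) by
splitting the containing edge with a new root node; rooting always uses raw
branch lengths. `sqrt_branch_transform()` is display-only and flagged as
such; it never feeds back into rooting.

Numerical conventions: Newick is written with 6 significant digits and a
write–parse–write cycle is byte-stable; an all-zero tree is rooted on an
arbitrary edge with a warning.

# Known limitations

* Absolute published population frequencies are not reproducible without
  the donor cohort; the package reproduces the printed *ratio* cells from
  the printed frequency columns and validates the estimator by parameter
  recovery on synthetic cohorts instead.
* The submission ledger is plain arithmetic over category counts; it does
  not model per-allele submission records.
* The ambiguity-group fixture freezes the published five groups; group
  membership under other database releases is out of scope.
* G-group *HLA-B* labels are opaque tokens (the trailing `G` parses as a
  suffix); no G-group expansion is attempted.
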