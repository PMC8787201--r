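---
title: "Full-length hybridization scanning: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Full-length hybridization scanning: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xenoscan)
```

## The scoring model and its assumptions

`xenoscan` scores a candidate binding site — an mRNA window equal in
length to the miRNA — by pairing it antiparallel against the *full*
miRNA and summing fixed per-pair free-energy magnitudes: G–C
6.37 kJ/mol (3 hydrogen bonds), A–U 4.25 (2), and the non-canonical
wobbles G–U and A–C at 2.12 kJ/mol (1 bond each). All other pairs,
and any pair involving the ambiguity base N, contribute nothing.

This is deliberately a *per-pair additive* model. Three assumptions
follow:

* **No gaps or bulges.** The duplex is colinear over the miRNA length;
  site position *i* always pairs miRNA position *L* + 1 − *i*.
* **No stacking or nearest-neighbour terms.** Stacking stabilizes real
  duplexes, but the model scores hydrogen bonding only; consequently
  ΔG values are comparable *within* this model, not with
  nearest-neighbour folding energies (no secondary-structure
  prediction of the target is attempted).
* **Mismatches cost nothing beyond the lost bond.** A non-bonding pair
  contributes 0 kJ/mol; there is no explicit penalty term.

Energies are stored as negative ΔG values; "greater binding energy"
throughout the package means larger |ΔG|. The model is overridable via
a flat TSV (`read_energy_model()`), with the invariants (symmetry,
energy/bond-count ordering) re-validated on construction.

The site-quality statistic is the complementarity ratio
100·ΔG/ΔGm, where ΔGm — the energy of the miRNA against its exact
complement — depends only on miRNA composition. The ratio is computed
unrounded and, by construction of the summation order, equals exactly
100 when and only when every position pairs canonically, so a 100%
threshold selects perfect complements without numerical slack.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| ratio threshold | 90 | % | the lowest value the reproduced site tables print; the cutoff the original analysis used for its supplementary lists is not stated, so this is exposed rather than fixed |
| window step | 1 | nt | scanning starts at the first transcript nucleotide and misses nothing |
| N tolerance | 10 | % of window | windows on masked/ambiguous sequence are skipped instead of generating spurious low-ratio calls |
| cluster gap | 0 | nt | clusters are runs of *overlapping or abutting* sites; a positive gap relaxes this |
| min cluster sites | 14 | sites | the published selection rule for the repeated-site cluster report |
| repeat tolerance | 0 | triplets | exact (GCC)^k detection; interrupted repeats can be admitted explicitly |

Rounding is confined to the report layer (ΔG and ratio to integers,
compaction to the nearest integer, ΔG ranges in `low÷high` notation);
every filter operates on unrounded values. Whether the published
ratios were computed before or after rounding ΔG is not stated; the
unrounded convention is adopted because it is the only
order-independent choice.

## Coordinates and cluster metrics

All coordinates are 1-based and inclusive on the mRNA, with the
5′UTR/CDS/3′UTR partition given by the last positions of the 5′UTR and
CDS; a site belongs to the region containing its *start* (printed site
tables assign exactly one region per site, and starts are the printed
anchor). Cluster spans use the convention end = start + length, which
reproduces the printed spans (for example, 21-nt sites covering
276–306 span 30 nt); this differs by one from a fully inclusive
convention and is stated here once rather than silently mixed.
Compaction is total member-site length divided by span — about 10 for
the densest reproduced cluster (281 nt of sites across 28 nt).

Overlap resolution between *different* miRNAs (keep the larger |ΔG|,
applied transitively by removing the weakest member of any
cross-miRNA overlap; ties broken toward the 5′-most start, then the
lexicographically smaller miRNA id, making the operation a pure
function of the site set) is exposed as an optional stage and is **off
by default**: the reproduced tables themselves print both members of
at least one cross-miRNA overlapping pair, so resolution evidently was
not applied to them. Same-miRNA overlaps are tandem repeats — the
phenomenon the cluster metrics quantify — and are never removed.

## GCC repeats and homopolymers

The repeat detector finds the maximal contiguous (GCC)^k substring
(leftmost on ties), classifies run lengths into the printed classes
(18, 21, 24, ≥27 nt; shorter runs carry no class), and translates CDS
runs to their frame-determined homopolymer: GCC codons give polyA,
CCG polyP, CGC polyR. Note that a run may *re-phase* through flanking
cytosines: `…CCG CCG CCC…` contains (GCC)×2 even though no triplet
boundary shows it — the detector (and its regex oracle) search all
phases, which is why classification of the packaged 5′UTR table
reproduces the published 18/11/14/9 split exactly. A tolerant variant
admits a bounded number of interior non-GCC triplets for interrupted
repeats; with tolerance 0 it coincides with the exact detector, and it
is monotone in the tolerance. The classifier is guaranteed (and
tested) against the 5′UTR table; the printed CDS table groups at least
one sequence by binding extent rather than pure repeat length, so its
block structure is validated from the fixture grouping, not
recomputed.

## The synthetic-data generator

`generate_study()` emulates the statistical structure the scan is
meant to detect, with exact ground truth:

* background transcripts of 1.5–3 kb with i.i.d. bases at a configured
  GC fraction (default 0.5) and a 15% 5′UTR / 55% CDS geometry —
  typical mRNA proportions;
* planted sites written as the miRNA's reverse complement with a
  chosen number of mRNA-side wobble substitutions (C→U opposite G,
  U→C opposite A), so the expected ratio is analytic:
  100·(|ΔGm| − Σ losses)/|ΔGm|. Substituting on the mRNA side mirrors
  the real setting of fixed reference miRNAs against variable
  transcripts;
* tandem runs written as overlapping sites at a fixed start spacing,
  which is only self-consistent when the site sequence is periodic
  with that spacing — inconsistent requests are refused rather than
  silently corrupted;
* (GCC)^k clusters planted in a designated region with a known
  reading-frame offset.

Every planted feature is flanked by 3 guard bases chosen to form *no*
bond with the miRNA base that would face them (for repeats: to break
the GCC phase), so detectors report exactly the planted feature and
windows hanging over a tandem edge fall below threshold. Randomness
comes from per-transcript streams derived from (seed, transcript
index), so planting one feature never perturbs another transcript, and
identical configurations are byte-identical across runs.

The default demonstration study (seed 42) has 20 transcripts, 5
miRNAs and 30 planted features: 15 single sites with 0–2 wobbles, 5
tandem runs at spacings 2 and 3 (mirroring repeated sites located
"through" one and three nucleotides, including a 14-copy run), and 10
GCC clusters (5 per region, all three CDS frames). What recovery on
this study shows — and does not show: the generator plants sites into
i.i.d. background, so it validates the scanner, the analytic ratio
accounting, the cluster metrics and the repeat caller, but it says
nothing about real transcriptome composition, isoform structure,
expression weighting or target-site accessibility, which are outside
the model.

A false-positive control is part of the test suite: on pure 50%-GC
background, a random 20-mer produces essentially no sites at the 90%
threshold (≤1 per 10⁵ windows at fixed seeds), so recovered sites in
generated studies are attributable to planting.

## Numerical and degenerate-input choices

* Threshold comparison uses a 10⁻⁹ slack so a ratio mathematically
  equal to the threshold is never lost to floating-point summation
  order; the window sum follows the same accumulation order as ΔGm so
  perfect windows hit 100 exactly.
* A miRNA longer than the transcript yields an empty result with a
  warning, not an error — at corpus scale this is data, not a bug.
* Empty miRNA sets, empty site tables and zero-cluster reports
  propagate as valid empty objects; a degenerate ΔGm of 0 (impossible
  for a non-empty miRNA) is rejected.
* Fixture tables are integrity-checked by md5 before use.
* Problem sizes in the test suite (1000 random scan pairs up to 2 kb,
  500 random repeat strings, a 20-transcript demonstration study) were
  chosen to exercise every code path at desk scale; the full published
  corpus scan (≈17,500 mRNAs × 1025 miRNAs) is supported through the
  same `scan_all()`/`run_pipeline()` interface but requires the user
  to supply the downloaded sequence sets.

## Known limitations

* The energy model is bond-counting, not thermodynamic: no stacking,
  no initiation terms, no temperature dependence. Rankings are
  meaningful within the model only.
* Region classification depends entirely on the supplied annotation;
  unannotated transcripts are scanned but report region `"unknown"`
  and are excluded from region counts.
* The repeat machinery targets the GCC family specifically (the family
  the reproduced analysis concerns); it is not a general tandem-repeat
  finder.
* Printed coordinates in the packaged fixtures refer to unspecified
  GenBank mRNA versions and are treated as opaque integers; they
  cannot be re-derived without the exact sequence versions.
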