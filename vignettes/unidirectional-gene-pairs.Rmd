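---
title: "Unidirectional gene pairs: distances, overlap phases, and complex enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unidirectional gene pairs: distances, overlap phases, and complex enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(overlapscan)
```

## The coordinate model

Every gene is stored as `(replicon_id, start, stop, strand)` with
`start < stop` unconditionally. On the forward strand, `start` is the first
base of the start codon and `stop` the last base of the stop codon; on the
reverse strand the roles are mirrored (`start` = last base of the stop
codon, `stop` = first base of the start codon). The payoff of this format is
that one formula covers both strands: for a serially encoded pair ordered by
coordinate, the intergenic distance is

```
d = second_start − first_stop − 1
```

Negative values are overlaps. The formula is anchored by boundary motifs
rather than by verbal convention: the `ATGA` motif (downstream ATG
overlapping upstream TGA by 4 nt) must give −4, `TAATG` must give −1,
abutting genes give 0, one spacer nucleotide gives +1. The test suite pins
all four anchors.

Coordinates are 1-based inclusive throughout (the GFF3 convention); any
half-open arithmetic is internal. Replicons are treated as linear: no pair
is formed across a circular origin. This loses at most one pair per
replicon and avoids inventing a junction distance the annotation does not
state.

## Cleanup before pairing

Three cleanup rules are applied, in this order:

1. **Stable-RNA genes are excluded** before pairing, so a distance spanning
   an excluded rRNA/tRNA gene is larger than the physical spacing. The
   number of such genes is small and large distances are not the object of
   interest, so no correction is attempted.
2. **Gene-internal transposases are removed**: when a transposon disrupts a
   gene, the host gene's two fragments flank the transposase; removing the
   flagged transposase record makes the fragments adjacent again.
3. **Pairs with truncated distance-defining termini are dropped**: a serial
   pair is removed iff the upstream gene lacks its stop codon or the
   downstream gene lacks its start codon. Truncation of the *other* two
   termini does not affect the distance and does not remove the pair. This
   is an interpretive choice — one could drop a pair on any truncation — but
   only the distance-defining termini make the distance meaningless.

Truncation and transposase flags are caller-supplied inputs (a `key=value`
attributes column); the curation that produces them is genome-specific and
outside the package's scope.

Ties in start coordinate are broken by `(stop, locus_tag)`, matching a
stable sort, so pair extraction is deterministic. Duplicate records are an
error rather than a silent merge.

Same-strand overlaps longer than 60 nt are almost always start/stop
misannotations, so distances below −60 are flagged `anomalous_overlap` in
the output — but never dropped, since flagging is auditable and dropping is
not.

## Phase and the codon algebra of short overlaps

The overlap phase is the nonnegative residue of the distance mod 3,
implemented by the two-branch form `p = k − 3⌊k/3⌋` for k ≥ 0 and
`p = k + 3⌈−k/3⌉` for k < 0; a property test verifies both branches equal
`((k %% 3) + 3) %% 3` on every integer in [−1000, 1000]. Phase matters
because a phase-0 overlap would put the two genes in the same reading
frame — the upstream stop codon would sit in-frame inside the downstream
ORF — so phase-0 overlaps cannot exist at all, and long overlaps split into
phase-1 and phase-2 populations with different evolutionary escape routes
toward the favored −4/−1 configurations.

For overlaps of −5..−1 nt the downstream start codon and the upstream stop
codon share bases, and `overlap_feasibility()` enumerates the compatible
boundary motifs by placing both codons at their implied offsets and keeping
the consistent assignments. With canonical codon sets
(ATG/GTG/TTG × TAA/TAG/TGA):

```{r feasibility}
for (k in -5:-1) print(overlap_feasibility(k))
```

−2 is infeasible (an NTG start forces an NNT "stop"; a TRR stop forces an
RRN "start") and −5 is infeasible (starts end in G, stops begin with T).
−3 is also empty: there the start codon would have to coincide
base-for-base with the stop codon, the pointwise manifestation of the
phase-0 impossibility. The non-canonical start ATT rescues −5
(`ATTGA`, `ATTAG`, `ATTAA`). Tests verify the enumeration against
brute force over all 4^L strings at each motif length. Outside −5..−1 the
codons cannot collide and the function returns an `"unconstrained"`
sentinel with a template such as `ATGNNTGA` for −8.

## Distance distributions

`distance_histogram()` counts pairs per integer distance over a window and
tallies (rather than discards) out-of-range pairs, so
`sum(counts) + out_of_range = total` always holds and totals stay
auditable. `window_fraction()` reports the count and fraction in any
window, e.g. the −8..+6 region where termination–reinitiation is
plausible. `phase_split_histogram()` returns one histogram per phase class;
their bin-wise sum equals the plain histogram by construction, and a test
asserts it. Plotting is intentionally a thin TSV layer
(`write_histogram_tsv()`); no figure machinery lives in the package.

## The two-factor distance model

Distances observed for the same COG pair across phyla are modeled
additively:

```
d_k[i, j] = C_i + P_j + e_k
```

with `C_i` a COG-pair effect, `P_j` a phylum effect pinned to 0 for a
reference phylum (the pinning resolves the obvious gauge freedom: adding a
constant to all `C` and subtracting it from all `P` leaves every fitted
value unchanged). Only COG pairs seen in at least `min_phyla` distinct
phyla (default 25) enter the fit, so pair effects are estimated across a
broad taxonomic sample; the threshold is a parameter, not a constant.

The default solver is alternating minimization with *exact* coordinate
updates — each `C_i` is set to the mean residual over its observations,
then each `P_j` likewise, then the reference is re-pinned (a pure gauge
shift that cannot change the sse). Every update is an exact block
minimizer, so the sse is non-increasing across sweeps (asserted by a
test). By default the solver iterates to the floating-point fixed point
(the sweep at which the sse stops improving), because stopping on a loose
relative-improvement threshold can leave the *effects* several orders of
magnitude less converged than the sse; a relative threshold remains
available via `tol`. A direct sparse least-squares solve of the dummy-coded
system (`method = "direct"`) exists as an independent route, and tests
require the two to agree to 1e-6 on unbalanced random instances.

Identifiability requires the COG-pair/phylum incidence graph to be
connected; a disconnected design raises an error listing the components
instead of returning an arbitrary gauge. Unbalanced designs (COG pairs
missing from phyla) are handled naturally by the observation-level loss; no
imputation.

The default reference phylum is the one with the most observations — the
natural generalization of choosing the dominant phylum as the baseline.
`adjust_distances()` subtracts `P[phylum]` from each observation;
`summarize_cog_pair()` reports per-pair means or medians. Both statistics
are exposed because binning decisions downstream use the median (robust to
the long positive tail) while effect interpretation uses means; the
enrichment module defaults to medians.

## Complex enrichment and the double-resampling bootstrap

Pairs (or COG pairs, by median adjusted distance) are binned as **short**
(−8..+10 nt, predictive of coupled translation), **long** (> +20 nt,
predictive of independent translation), or **excluded** (+11..+20, where
coupling is highly gene-specific; and distances below −8, i.e. long
overlaps). Complex membership comes either from a curated per-pair flag
column or from the shared-stem name heuristic: `xyzA`/`xyzB` with equal
non-empty stems and different single trailing capitals. The heuristic is
deliberately strict — a missing name, a lowercase suffix, or identical
letters all yield `FALSE`.

The 2×2 table (complex status × bin) yields the short/long complex
fractions, their ratio (the enrichment factor), and a Pearson χ² test
without continuity correction — at genome-scale counts the correction is
negligible. The test statistic is `stats::chisq.test(correct = FALSE)`
under the hood, verified in tests against the textbook Σ(O−E)²/E.

Because gene pairs within a COG pair are not independent, significance of
the genome-collection enrichment uses a bootstrap that resamples at both
levels: each replicate (1) includes every COG pair independently with
probability 1 − e⁻¹ ≈ 0.63 (the asymptotic inclusion probability of an
ordinary bootstrap draw), then (2) redraws the full number of gene pairs
with replacement from the included COG pairs, weighted by their gene-pair
counts, and (3) recomputes the enrichment ratio. The z-score is
`mean(log ratios) / sd(log ratios)` — natural logs, though the base cancels
in the ratio — and the p-value is the one-sided upper-tail normal
probability, appropriate for a directional enrichment hypothesis.
Replicates whose resampled table has no complex pairs in a group (log-ratio
undefined) are dropped and counted rather than mapped to ±∞, keeping the
replicate distribution finite; a warning fires when more than 10% of
replicates are degenerate. The replicate log-ratios are treated as
approximately normal descriptively; no formal normality test is imposed.

## Reporter-efficiency arithmetic

`translational_efficiency()` implements
`(specific_activity − control_activity) / transcript_level`: the
empty-vector control mean is subtracted from activities only (transcript
levels are already relative quantities normalized to 16S rRNA), and
below-control values are reported as negative rather than clipped.
`normalize_to_wildtype()` divides by the wildtype mean and reports
per-construct means and sample standard deviations over biological
replicates (three in the standard design). The whole module is scale
invariant: rescaling all raw inputs by a common factor is a no-op after
normalization.

## What the synthetic generator emulates — and what it does not

`simulate_genome_annotation()` lays genes along a replicon with:

- strand runs from a Markov switch (default switch probability 0.25), so
  serial, convergent and divergent pairs all occur in realistic runs;
- consecutive spacings drawn i.i.d. from a configurable mixture; the
  default mixture mimics the observed genome-wide shape — point masses at
  −4 (dominant), −1 and −8, a 0..+6 run, a narrow +9..+12 component, a
  broad +50..+150 component, a +13..+49 shoulder, a long remainder, and
  long-overlap tails placed only on phase-1/phase-2 distances;
- gene lengths uniform on 300–3,000 nt in whole codons (annotation-realistic
  but irrelevant to the distance statistics);
- shared-stem complex names planted on serial pairs with probability 0.355
  at short distances and 0.225 elsewhere (the genome-wide complex fractions
  used as study conditions), each planted pair receiving a unique stem so
  no accidental pairs arise;
- optionally, replicon sequences in which every gene terminus carries a
  start/stop codon and every constrained boundary (−5..−1) carries a motif
  drawn uniformly from its feasibility set (reverse-complemented on the
  reverse strand). A mixture putting mass on an infeasible overlap with
  sequence emission on is rejected at spec validation.

`simulate_multi_phylum_dataset()` is the generative twin of the factor
model: true effects `C*` (default mean 5, sd 38.2 nt) and `P*` (sd 2.9 nt,
reference pinned to exactly 0) are drawn and **rounded to whole
nucleotides** — annotated distances are integral — and observations are
`round(C* + P* + Normal(0, noise_sd))`. Rounding the truth makes noise-free
recovery exact to solver tolerance; rounding observations after noise is
added slightly biases dispersion recovery at very small noise sd, which is
why recovery tests use noise sd 10. Per-COG-pair complex flags are drawn
with bin-dependent probability based on the *true* effect's bin, planting a
known enrichment.

What the generator does **not** emulate: real codon usage and GC content,
operon length structure (spacings are independent across boundaries,
whereas real operons correlate them), annotation error, gene-content
phylogenetics, or the phylogenetic correlation of phyla. Passing the
closed-loop tests therefore demonstrates that the pipeline measures what it
claims on data with the assumed structure — not that real genomes satisfy
those assumptions.

## Problem sizes and numerical choices

The test suite and analysis drivers use desk-scale problem sizes chosen to
make sampling error small relative to the tolerances they assert: 10,000
serial pairs for mixture-recovery checks (component frequencies within 4
binomial standard deviations), 200 COG pairs × 30 phyla × 20 observations
per cell for dispersion recovery (within 15%), and 1,000 bootstrap
replicates (the standard replicate count for this analysis). Genome-wide
tallies that depend on the real annotations — absolute pair counts at
specific distances, the empirical 38.2/2.9 nt effect dispersions of the
full cross-species dataset — are inputs the package consumes, not outputs
it can reproduce, and are deliberately not asserted anywhere.

Other numerical choices, collected: χ² without continuity correction;
one-sided normal p for the bootstrap z; natural-log replicate ratios;
degenerate replicates dropped and counted; alternating solver iterated to
its sse fixed point with a 10,000-sweep cap; direct solver via sparse
normal equations; distances and effects on the integer nucleotide scale.

## Known limitations

- Multi-exon (joined) CDS are rejected rather than spliced; the analysis
  targets prokaryotic single-span annotations.
- Stable-RNA exclusion inflates a small number of distances (by design,
  documented above).
- The shared-stem heuristic under- and over-calls complex membership in
  ways that curation would not; curated flags override it where available.
- The factor model is additive and tree-blind: phyla enter as exchangeable
  labels, not as leaves of a phylogeny.
- Circular replicons lose the origin-spanning pair.
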