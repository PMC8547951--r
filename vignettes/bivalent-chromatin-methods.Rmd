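---
title: "Methods: detecting bivalent chromatin on metabolic pathways"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting bivalent chromatin on metabolic pathways}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kairoscan)
```

## The analysis problem

Specialized metabolic pathways in plants — camalexin biosynthesis in
*Arabidopsis* being the canonical example — can carry both a repressive
histone mark (H3K27me3) and an activating one (H3K18ac) on the same genes.
Such *bivalent* chromatin is thought to hold defence genes in a poised
state: repressed at baseline, rapidly inducible on a pathogen signal, with
the two marks tuning the timing and amplitude of induction.

`kairoscan` implements the computational side of detecting and validating
this state:

1. aggregate binned, rank-normalized genome-wide signal tracks over gene
   windows and compute per-gene-set signal densities;
2. call per-(set, mark) enrichment or depletion against a metabolic-gene
   background (density fold change + Fisher's exact test + BH FDR);
3. quantify co-occurrence of two marks and attribute their cross-mark
   correlation to a candidate gene subset;
4. provide the qPCR calculators used for wet-lab validation: ChIP-qPCR
   percent input and relative abundance, sequential-ChIP percent of first
   ChIP, delta-delta-Cq expression kinetics, and three-way factorial ANOVA.

A seeded synthetic-data module generates every input with planted ground
truth, so the full pipeline is testable end to end without external data.

## Signal model and densities

Input tracks are binned genome signals (bedGraph), one per mark.  Because
different profiling experiments have incomparable dynamic ranges, each track
is first **rank-normalized**: bin values are replaced by genome-wide
fractional ranks $r_i = \mathrm{rank}(v_i)/N \in (0,1]$ with average ranks
for ties.  This is order-preserving and invariant to monotone rescaling, so
marks profiled at different depths become comparable.

Each gene is extended to its **window**: the transcribed region plus 1 kb
upstream of the TSS and 500 bp downstream of the transcription end.  The
extension is strand-aware — upstream of a minus-strand gene is genomically to
the right.  Whether the original analyses were strand-aware is not something
the input tracks can tell us; we chose the biologically meaningful
convention and expose both extents as parameters (`upstream_bp`,
`downstream_bp`).  Windows are clipped at chromosome bounds and flagged.

The **window signal** of gene $g$ is
$S_g = \sum_b r_b \cdot \frac{\mathrm{overlap}(b, w_g)}{\mathrm{len}(b)}$,
i.e. bins contribute proportionally to their overlap, which equals a per-bp
accumulation of $r_b/\mathrm{len}(b)$ and is therefore robust to bin size
(an exhaustive per-bp oracle test enforces this).  The **density** of a gene
is $S_g / \mathrm{len}(w_g)$; the density of a gene set is the pooled
$\sum_g S_g / \sum_g \mathrm{len}(w_g)$ (length-weighted, not a mean of
per-gene densities).  The **background** is the set density of the full
metabolic gene universe.  Overlapping windows of neighbouring genes
double-count shared bins deliberately: per-gene sums must be gene-local.

## Enrichment calls

For each gene set (pathway or metabolic domain) and mark:

* effect size: density fold change $FC = d_{set} / d_{background}$, with
  log2FC reported in the heatmap matrix;
* significance: Fisher's exact test on a 2×2 table of **marked-gene**
  counts.  A gene is "marked" when its density reaches the $q$-th empirical
  quantile (type-7, default $q = 0.75$) of the universe densities; the table
  is marked/unmarked × in-set/out-of-set.  A density fold change needs a
  count-valued complement to admit an exact test, and marked-gene counts are
  the natural gene-level reading; the marking quantile is exposed because
  the marked-gene criterion is an analysis choice, not a law;
* multiplicity: BH step-up across the entire set × mark family (a per-mark
  mode is available);
* call: `enriched` when $FC \ge 1.5$ (inclusive) and $q \le 0.01$;
  `depleted` symmetrically at $FC \le 1/1.5$; otherwise `none`.  The raw-p
  rule ($p < \alpha$, default 0.05) used by some published heatmaps is
  available via `use_raw_p`.

Domain-level analyses use only genes whose pathways map to exactly one
domain, so multi-domain genes cannot blur domain contrasts.  Pathway-level
analyses keep statistical power by requiring at least 10 member genes
(inclusive), a tunable filter.

## Bivalency

Two complementary views:

* **Co-occurrence**: the count and fraction of universe genes marked by both
  modifications (percentages reported rounded to integer percent, so
  324 of 887 prints as 37%).
* **Correlation attribution**: Pearson $r$ between the two marks' per-gene
  densities over the universe, with the standard
  $t = r\sqrt{(n-2)/(1-r^2)}$ significance transform, recomputed after
  removing a candidate subset.  A drop in $r$ attributes part of the
  cross-mark correlation to the subset.  Densities rather than raw window
  sums are correlated so gene length does not confound $r$.

`dual_enriched_sets()` intersects the per-mark `enriched` calls, yielding
candidate bivalent pathways.

## qPCR calculators

All quantities assume 100% amplification efficiency (base 2).

* **Percent input**: $100 \cdot 2^{(Cq_{input} - \log_2(1/f)) - Cq_{IP}}$
  with input fraction $f$ (default 1%).  The dilution adjustment is the
  standard convention; downstream treated/mock ratios cancel it entirely.
* **Relative abundance**: treated-replicate percent inputs divided by the
  mock mean, keeping replicate spread for error bars and testing.
* **SeqChIP percent of first ChIP**: $100 \cdot 2^{(Cq_{2nd} - Cq_{1st})}$,
  implemented exactly as conventionally printed.  Note the sign convention
  gives values above 100% when the second pull-down recovers *less*
  material; `sign_corrected = TRUE` computes $2^{(Cq_{1st} - Cq_{2nd})}$
  for the physically intuitive reading.
* **Expression fold change**: per replicate $\Delta Cq = Cq_{target} -
  Cq_{reference}$; $FC = 2^{-(\overline{\Delta Cq}_{treated} -
  \overline{\Delta Cq}_{mock})}$ against the same-time untreated control,
  with a pooled-variance Student t on the replicate $\Delta Cq$ values.
  Adding a constant to every Cq (a plate offset) cannot change the result.
* **Earliest induction**: the first time point with $p \le \alpha$ and
  $FC > $ `min_fc` (defaults 0.05 and 1).  Published kinetics figures state
  conclusions, not the decision rule, so both knobs are explicit.

## Three-way ANOVA

`anova3()` fits the fixed-effects factorial genotype × treatment × duration
by least squares with sequential (Type I) sums of squares in that term
order.  Only fully crossed, balanced designs (equal replication, ≥ 2 per
cell) are accepted: under balance the factors are orthogonal, Type I/II/III
coincide, and the sequential table is order-invariant (verified by a test
that permutes the term order).  Unbalanced data are refused with an explicit
error rather than silently committing to a sums-of-squares type.  Duration
is categorical.  The response for expression ANOVA is per-replicate
linearized relative expression $2^{-\Delta Cq}$ — our reading of analysing
"raw transcript" levels — with the $\Delta Cq$ scale available via
`response_scale = "dcq"`.

## What the synthetic data emulates

`sim_config()` defaults define the simulated study:

* genome: 1000 genes, 2 × 2.5 Mb chromosomes, gene lengths 1–3 kb, placed
  in slots so bodies are disjoint and every window fits;
* annotation: 20 pathways × 20 genes (10 in a `specialized` domain, the
  rest spread over three other domains); genes belong to one pathway unless
  `multi_pathway_fraction` plants multi-domain genes to exercise the
  unique-domain filter;
* tracks: 200 bp bins; baseline value per bin drawn lognormal(0, 0.75) —
  nonnegative and right-skewed like ChIP coverage, with a spread that keeps
  a 3× planted multiplier clearly above background after rank-normalization
  while leaving real overlap between the distributions; planted effects are
  multiplicative on the raw scale, so a pathway's multiplier maps directly
  onto the density fold-change scale after ranking;
* qPCR: two genotypes (wild type inducing from 30 min, a mutant inducing
  earlier and higher, mirroring the reduced-repression phenotype), three
  target genes, the 5/30/60/180/360-minute grid, 6 replicates, additive
  Gaussian Cq noise (sd 0.2 cycles);
* metabolite: base 50 nM with late accumulation in the wild type and
  earlier accumulation in the mutant, multiplicative lognormal noise.

Every planted effect is recorded in a truth table written beside the data;
recovery tests read truth only from there.  The generators are deterministic
given the seed — identical config and seed give a byte-identical file set.

The generator plants block effects on whole gene windows with independent
baseline bins.  Real chromatin has autocorrelated coverage, domain-scale
marks spanning neighbouring genes, mappability artefacts and copy-number
structure — none of which are modelled.  Passing recovery tests therefore
demonstrate correctness of the statistical machinery under the stated
generative model, not detection power on real epigenomes.

## Numerical choices

* Fisher's exact test: conditional two-sided, summing hypergeometric
  probabilities not exceeding the observed table's with relative tie
  tolerance $10^{-7}$; any zero margin is degenerate and returns $p = 1$
  with a message.
* BH: the step-up closed form, checked element-wise against an independent
  implementation at $10^{-12}$.
* Quantile marking: `stats::quantile` type 7 (linear interpolation).
* Degenerate t-tests (zero pooled variance): $p = 1$ with equal means,
  $p = 0$ otherwise, logged.
* Correlation requires $n \ge 3$ and nonzero variance in both vectors.
* Coordinates are 0-based half-open internally; GFF3 converts at the
  boundary; bedGraph is native.  Overlapping bins in an input track are an
  error, never silently merged.

## Problem sizes used in the checks

The bundled statistical checks run the generator at the default study size
(1000 genes, 20 pathways, 2 marks) for 100–200 seeds per property, and the
qPCR recovery at 500 seeds; unit-level oracles enumerate all 2×2 tables with
$n \le 30$ and 500 mixed-bin-size window fixtures.  These sizes give
two-sided binomial standard errors comfortably below the margins asserted.

## Known limitations

* The marked-gene criterion (quantile threshold) is a modelling choice; the
  co-occurrence fraction depends on it directly.
* Fisher's test on marked-gene counts treats genes as exchangeable units;
  base-pair- or bin-level alternatives would weight long genes differently.
* Balanced-only ANOVA is deliberate; use mixed models elsewhere for
  unbalanced designs.
* The qPCR calculators assume perfect (2-fold per cycle) amplification;
  primer-efficiency calibration is out of scope.
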