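---
title: "Directional HWE departure: model, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directional HWE departure: model, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hweqc)
```

## The model

In a large random-mating population a biallelic locus with allele-A
frequency $m$ has genotype proportions $m^2$, $2m(1-m)$, $(1-m)^2$.
`hweqc` tests observed genotype counts $(n_{AA}, n_{AB}, n_{BB})$ against
these proportions, with $m$ estimated by allele counting from the same
counts, using the three-category Pearson goodness-of-fit statistic

$$\chi^2 = \sum_{g} \frac{(O_g - E_g)^2}{E_g}.$$

The directional part is the heterozygote observed/expected ratio
$\mathrm{O/E} = n_{AB} / 2nm(1-m)$: a significant departure with
$\mathrm{O/E} < 1$ is classified **LoH** (loss of heterozygosity), with
$\mathrm{O/E} > 1$ **GoH** (gain). The package's central claim, which the
synthetic generators make testable, is that the two directions have
different causes: LoH arises from deletion polymorphisms, stratification
and inbreeding (real biology), GoH from genotyping error (paralog
cross-hybridization, indel miscalls, allelic artifacts correlated with
missingness).

### Degrees of freedom

The default reference distribution is $\chi^2_2$, i.e. the three genotype
categories with only the sum constrained, which gives the closed form
$p = e^{-\chi^2/2}$. This is a deliberate reporting convention: it is the
convention under which every checkable cell of the package's reference
tables (18 genotype distributions over three worked-example variants)
reproduces at print precision, and the test suite pins all of them.

It is *not* the calibrated frequentist test. Because $m$ is estimated from
the data, the statistic is asymptotically $\chi^2_1$; with `dof = 2` the
reported p-values are conservative (at a nominal 0.01 the realized type-I
error is about 0.002). Analyses that need a calibrated error rate — e.g.
the type-I calibration in `analysis/02_simulation_calibration.R`, which
checks the flagged fraction is $0.01 \pm 0.003$ over $10^5$ equilibrium
cohorts — use `dof = 1`. Both are exposed on every testing function.

### Thresholds and conventions

- Departure significance: $\alpha = 10^{-5}$ (configurable). The written
  form "10 E-05" in the source material is read as $1\times10^{-5}$.
- No continuity correction anywhere (the reference p-values reproduce
  without one).
- A significant test with O/E exactly 1 is `UNDEFINED`, not forced into a
  direction; the dichotomy presumes a direction.
- Monomorphic-in-population variants return `UNDEFINED` with `NA`
  p-values, so they can never be counted as "in equilibrium" controls.
- Report files round expected counts to integers, frequencies and O/E to
  2 decimals and p to 2 significant figures; full precision is retained in
  memory.

### Inclusion filters

A variant is excluded when its pooled call rate is below 80% of the cohort
or its pooled folded MAF is below 1%; an included variant is not analyzed
in populations where its folded MAF is below 0.001. `strict = TRUE` raises
the call-rate bar to 98% — the re-analysis mode in which error-driven GoH
departures are expected to vanish while biological LoH departures persist.

## The five explanatory features

Per variant: missing-genotype fraction (denominator: the full cohort
size), SNP vs indel type (equal-length multi-base substitutions are
`OTHER`, excluded from the contrast rather than silently binned), overall
folded MAF, cross-population allele-frequency SD, and CNV loss/gain
overlap (point-in-interval on the variant's VCF POS against 0-based
half-open intervals; deletion-spanning logic for long indels is out of
scope).

**MAF-SD convention.** The cross-population SD uses *unfolded* allele-A
frequencies with the population (divisor-$N$) formula. The source tables
do not state either choice; this pair is reverse-engineered from two
printed values (0.12 and 0.23), which folding (0.08) or the $N-1$ divisor
(0.13 / 0.26) fail to reproduce. Treat the convention as validated against
those two values only. On the report scale MAF-SD and missingness are
multiplied by 100.

**Unit of analysis.** Group comparisons treat each variant × population
genotype distribution as one observation, matching the reference
denominators (a six-population variant contributes six observations).
Variant-level features are therefore replicated across that variant's
populations — deliberate pseudo-replication that mirrors the analysis
being reproduced; p-values for variant-level features are anti-
conservative to that extent.

**Test battery.** Continuous features: two-sided Mann-Whitney, exact for
groups of ≤ 20 without ties, normal approximation with tie correction
otherwise. Categorical features: Pearson chi-square without continuity
correction when all expected cells ≥ 5, else two-sided Fisher.
Heterogeneity across populations: chi-square on the 2×K
departure-vs-control table. No multiple-testing correction, matching
per-feature reporting.

## Region scans

`scan_region()` applies the MAF > 0.01 filter, tests every variant, and
emits a sorted track with $-\log_{10} p$ capped at 320 so that p-values
that underflow double precision stay plottable (the cap is recorded in the
output). A `missingness_usable` attribute flags tracks whose variants all
report complete genotyping — such datasets carry no missingness signal, so
that feature cannot be used on them.

`detect_clusters()` greedily merges significant variants closer than
`window_bp` and reports clusters with at least `min_cluster_size`
significant members and their direction. The defaults (10 kb, 5) are
scaled to dense real-data tracks, where a paralog peak packs ~11 variants
into a few kb; on sparse simulated tracks the window should be set to a
few times the mean inter-variant spacing (the packaged region analysis
uses 100 kb at a mean spacing of 16 kb). There is no canonical algorithm
being reproduced here — the source describes the observation, not a
procedure — so the clustering is intentionally the simplest disjoint
greedy merge: output spans never overlap and direction purity is a filter,
not a merge criterion.

## The mechanism generators

Each generator draws one variant's genotype counts for $n$ individuals
from a single seeded RNG stream and has a closed-form expected O/E, which
the tests verify within 3 Monte-Carlo SE:

| mechanism | model | expected O/E |
|---|---|---|
| equilibrium | multinomial $(p^2, 2pq, q^2)$ | 1 |
| inbreeding $F$ | $(p^2+Fpq,\; 2pq(1-F),\; q^2+Fpq)$ | $1-F$ |
| stratification | mixture of HWE subpopulations | $\sum_k w_k 2p_kq_k / 2\bar p\bar q$ |
| deletion, del/del missing | hemizygotes called homozygous | $(1-d)/(1+d)$ |
| deletion, del/del forced | plus imputed homozygous calls | $(1-d)^2$ |
| paralog collapse | fraction $h$ constitutively het | 2 at $h=1$ |
| allelic dropout $e$ | per-allele failure | enumerated |

Design choices worth knowing:

- **Deletion overlay**: the deletion allele and the SNP allele are drawn
  independently. Linkage between them is real biology but unmodelled; the
  inverse relation between deletion frequency and O/E is reproduced
  qualitatively. The two `delmode`s emulate the two dataset styles
  encountered in practice: exome databases report del/del individuals as
  missing; some reference panels report everyone genotyped, forcing a
  homozygous call.
- **Allelic dropout** is applied per allele, not per genotype: each allele
  fails independently with rate $e$; a heterozygote losing one allele is
  called homozygous for the survivor, losing both is missing, and a
  homozygote losing one allele keeps its correct call (a single band is
  indistinguishable). This literal process *reduces* observed
  heterozygosity — it produces LoH, not GoH. The verbal argument that
  dropout inflates apparent heterozygosity concerns per-locus error-rate
  estimation, not the genotype distribution itself; in this package's
  framing, GoH is attributed to cross-hybridization and indel miscalls,
  and the dropout generator is documented as an LoH mechanism. The exact
  per-genotype call distribution is enumerable, and the test suite pins
  the simulator to that enumeration.
- **`sim_region()`** places variants uniformly over a region and overrides
  those inside non-overlapping mechanism intervals, drawing individual
  genotypes so the emitted VCF is exactly consistent with the counts. It
  emulates the geometry of a local departure scan (an LoH block over a
  deletion, a GoH peak over a paralog segment) — not coalescent history,
  LD, or realistic site-frequency spectra. Background allele frequencies
  are uniform on (0.1, 0.9) so essentially all background variants pass
  the MAF filter; 10% of variants are written with indel-type alleles.

What passing these tests shows is that the pipeline recovers each
mechanism's signature *when the mechanism is the generating process*; real
data add LD, population history, and error processes correlated in ways
the generators do not model, so simulated power and calibration are
optimistic relative to field conditions.

## Problem sizes and numerics

The packaged analyses and tests use desk-scale sizes chosen to leave
Monte-Carlo error well below the assertion tolerances: $10^5$ replicates
for type-I calibration (binomial SE $3\times10^{-4}$ at 0.01), 20
replicates of $n = 2\times10^4$ per closed-form grid point (SE
$\approx 0.0015$ on O/E), and a 500-variant / 5,000-individual region for
end-to-end mechanism recovery (in-deletion O/E $= 1/3$ at $d = 0.5$ gives
per-variant $\chi^2$ far beyond the $10^{-5}$ threshold, so "all
in-deletion variants called LoH" is a power statement with effectively no
slack). Genotype counts are validated as non-negative integers; expected
counts always sum to the called total within $10^{-6}n$; categories with
zero expectation (only possible for monomorphic draws, which are flagged)
contribute nothing to the statistic.

## Known limitations

Biallelic autosomal loci only: no exact (enumeration) HWE test, no
multi-allelic or X-chromosome/hemizygote-aware testing. CNV annotation is
point overlap on the anchor position. The MAF-SD convention rests on two
printed values. The group-comparison unit of analysis pseudo-replicates
variant-level features by design. The generators are single-locus and
LD-free; cluster detection is a greedy heuristic with scale-dependent
parameters, not an inferential procedure.
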