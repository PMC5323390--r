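---
title: "Methods: carbon budgets and community responses of detritus-pulse sediment incubations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: carbon budgets and community responses of detritus-pulse sediment incubations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sedipulse)
```

## The experimental system

`sedipulse` analyses *ex situ* feeding experiments in which deep-sea
sediment is diluted into a slurry, amended with a pulse of particulate
organic carbon (chitin or algal detritus), sealed into gas-permeable
polyethylene bags without headspace, and incubated cold for several weeks.
Four measurement streams describe the community response:

* direct epifluorescence cell counts at the start and end of the
  incubation,
* end-point oxygen concentrations read by optode inside each bag,
* fluorogenic (MUF) extracellular enzyme assays at saturating substrate,
* 16S amplicon OTU tables for the total (rDNA) and active (rRNA)
  community.

The package turns these into a treatment-level carbon mass balance, a
bag-resolved respiration estimate, potential hydrolysis rates, and a
compositional screen for opportunistic "responder" taxa — plus a synthetic
generator that produces all four streams with known ground truth, so every
stage is testable without any sequencing archive.

## Carbon budget

Cell counts $N$ (cells per mL undiluted sediment) convert to biomass
carbon using an average cell volume $v$ (default 0.07 µm³) and a carbon
density $\rho$ (default $3\times10^{-13}$ g C µm⁻³ biovolume):

$$B = N\, v\, \rho \cdot 10^{6} / M_C \quad [\mu\text{mol C mL}^{-1}],$$

with $M_C = 12.011$ g mol⁻¹. The added carbon pool, $m = 0.2$ mg C per mL
sediment, equals $m \cdot 1000 / M_C \approx 16.65$ µmol C mL⁻¹. Per
treatment the budget derives:

* **net biomass yield**: day-23 biomass minus the unfed control's day-23
  biomass (negative yields are reported, not clipped — the experimental
  design never produces them, synthetic data can);
* **net C respired**: the oxygen uptake excess over the control times the
  respiratory quotient, fixed at 1.0 mol C per mol O₂ by default. This
  choice is deliberate: with RQ = 1 the respired-carbon column equals the
  oxygen difference, which is how the printed budgets behave; it is a
  configurable constant of `budget_constants()`;
* **total C used** = yield + respired (an exact identity in every row);
* the same three as percent of the added pool;
* **bacterial growth efficiency** = yield / total used × 100, undefined
  (flagged `n/a`) for the control;
* **duplication time** $T \ln 2 / \ln(N_{23}/N_0)$, infinite when counts
  did not change.

Technical replicates are averaged per biological replicate before
treatment means; dispersion of derived differences uses first-order error
propagation. A scale check worth knowing: doubling the added-carbon mass
halves every percentage column and leaves all absolute columns unchanged.

Published budget tables of this kind are printed rounded, and their biomass
columns are typically computed from unrounded counts; re-deriving biomass
from the rounded printed counts can therefore disagree with the printed
biomass by several percent. When reproducing such a table, feed the
printed biomass column (supported via the optional
`biomass_umol_per_ml` input column) rather than re-converting rounded
counts.

## Oxygen in a permeable bag

A sealed bag exchanges oxygen with the surrounding oxygenated water by
diffusion across the foil. With constant volumetric respiration $R$
(µmol O₂ L⁻¹ slurry d⁻¹) and volumetric conductance
$k' = D A / (L V)$ (d⁻¹; $D$ foil diffusion coefficient, default
$2.65\times10^{-12}$ m² s⁻¹, $A$ foil area, $L$ foil thickness, $V$ bag
volume), the concentration obeys

$$\frac{dC}{dt} = k'(C_{amb} - C) - R
  \;\Rightarrow\;
  C(t) = C_{amb} - \frac{R}{k'}\left(1 - e^{-k't}\right),$$

starting air-saturated at the ambient concentration (default 300
µmol L⁻¹). After a few multiples of $1/k'$ the bag is in steady state and
the deficit inverts directly to the respiration rate,
$R = k'(C_{amb} - C_{end})$ — this is the estimator used on end-point
optode readings. Readings above ambient yield a flagged negative rate; a
reading of zero only bounds the rate from below (anoxia-limit flag), and
forward-model concentrations that would be negative are floored at zero
with an anoxia flag.

Respiration is assumed constant over the incubation when inverting (only
an end-point reading is available); the forward model exists so the
synthetic module can probe sensitivity to that assumption. Foil area and
thickness are experiment-specific and enter only through $k'$; the
defaults (150 cm² of 50-µm foil on a 50-mL bag, $k' \approx 1.37$ d⁻¹)
are documented placeholders that keep bags at realistic respiration rates
well oxic, and no published-value comparison in this package depends on
them. Total uptake per mL of undiluted sediment over the incubation is
$R \cdot T \cdot f / 1000$ with $f$ the slurry dilution factor (default
3.5): a 3.5-fold diluted slurry contains $1/3.5$ sediment by volume.

## Enzyme kinetics

Fluorescence is calibrated against MUF standards (0–6 nmol mL⁻¹) by
ordinary least squares; readings mapping outside the standard range warn
about extrapolation but are still converted (linear calibration). With
substrate at saturation the hydrolysis time course is zero order, so the
slope between the two readings (1 h and 3 h by default) is the maximum
velocity. The unit chain is nmol mL⁻¹ h⁻¹ → µmol mL⁻¹ d⁻¹ (×24/1000) →
per mL sediment (×dilution). Two timepoints rather than a single endpoint
make the estimate invariant to any constant background fluorescence.
Decreasing fluorescence (quenching, drift) is clipped to rate zero with a
flag, mirroring sterile-control behaviour.

The total hydrolysis potential over the incubation sums both enzymes,
scales by the duration, and converts monomers to carbon with 6 C atoms per
released monomer (glucose-equivalent for both the glucosidase and the
chitobiase substrate), a configurable constant chosen because it
reproduces the printed potential set from the printed rates.

## Community statistics

**Filtering.** OTUs classified as chloroplasts, mitochondria or Archaea,
OTUs without a domain-level classification, and OTUs with a dataset-wide
total of one read are removed before any statistic. Note the singleton
rule is dataset-wide: one read in each of two samples is kept.

**Alpha diversity** uses repeated random subsampling without replacement
to a fixed depth (default 26,712, the minimum library size of the original
dataset), averaging observed richness and inverse Simpson
($1/\sum p_i^2$) over 100 repeats; the Monte-Carlo mean richness agrees
with the hypergeometric closed form, which the tests assert within three
Monte-Carlo standard errors.

**Beta diversity** is Bray–Curtis on relative abundances, embedded by
non-metric multidimensional scaling (Kruskal stress-1, random restarts,
seeded), with similarity hulls obtained by cutting an average-linkage tree
at fixed dissimilarity (0.70 for major community types, 0.32 for
replicate clusters — average linkage because the hull construction is
otherwise unspecified). Congruence between distance matrices (e.g. rDNA
vs rRNA) uses the Mantel permutation test.

**The responder screen** is a Monte-Carlo Dirichlet clr procedure. For
each of 128 instances, per-sample proportions are drawn from
Dirichlet(counts + 0.5) — the Jeffreys-style prior replaces zeros — and
clr-transformed in **log base 2**, so one clr unit is one duplication and
the decision threshold "more than one duplication or less than half" is
simply $|\text{difference}| > 1$. Per instance and taxon the
between-group difference is the difference of group mean clr values; the
within-group dispersion is the larger of the two within-group
interquartile ranges (dimensionless, conservative — the published
procedure delegates the estimator to its citation without formulas, so
this package fixes and documents its own); the effect size is the median
over instances of difference/dispersion, the reported difference the
median difference. A Welch t-test p (averaged over instances, then
Benjamini–Hochberg adjusted across taxa) and a rank-sum p (mid-rank,
tie-corrected normal approximation, averaged, unadjusted) accompany the
effect sizes, mirroring the adjusted-parametric / unadjusted-nonparametric
convention. Zero dispersion produces a signed-infinite, flagged effect.

A replicated (rDNA) taxon is a **responder** when it is present in at
least 2 of 3 replicate bags, $|\text{effect}| > 4$ and
$|\text{difference}| > 1$. The unreplicated (rRNA) screen admits taxa
reaching 1% relative abundance in one of the two samples and reports
those changing at least twofold; a taxon absent at day 0 that reaches the
screen at day 23 is a flagged "new appearance" counted as an increase.
Family-level reporting aggregates counts per family, grouping OTUs
unclassified at family rank under "unclassified &lt;next resolved
rank&gt;", and restricts discussion to families above 2% in some sample.

**ANOVA.** Rate and count measurements are square-root transformed, fitted
by one-way ANOVA with all-pairs Tukey HSD at α = 0.05, and summarised as a
compact letter display (letters are maximal cliques of the
non-significance graph; groups sharing no letter differ). The original
mixed-model treatment of technical replicates is simplified to
replicate-mean ANOVA — a documented deviation; a full nested model is out
of scope. Zero within-group variance everywhere is flagged degenerate
rather than fitted.

## The synthetic experiment

`sim_config()` defines the ground truth; its defaults emulate the
magnitudes of the 23-day experiment the package targets:

| parameter | default | why |
|---|---|---|
| treatments | unfed + CHI, TWEI, EHUX, BCLA, MARC | control + five amendments |
| growth rates | ln(ratio)/23 d⁻¹ from end/start count ratios 2.3/1.4 … 4.0/1.3 | observed day-23 counts |
| respiration | 36–76 µmol O₂ L⁻¹ slurry d⁻¹ | printed 2.9–6.1 µmol O₂ mL⁻¹ sediment totals |
| Vmax | 0.005–0.25 µmol mL⁻¹ d⁻¹ per enzyme | printed rate ranges |
| counting CV | 0.07 | printed ± magnitudes of count columns |
| fluorescence CV | 0.05 | typical spectrofluorometer repeatability |
| optode sd | 2 µmol L⁻¹ | optode accuracy at the working range |
| community | 150 taxa, log-normal (sdlog 2) | long-tailed sediment communities |
| planted responders | 16 opportunists, folds 6–32, baseline 0.4% each | copiotrophs start rare (<1%) but present, then bloom |
| library size | 30,000 reads | order of the real minimum library |
| overdispersion θ | 5000 | see below |

Counting and fluorescence noise are multiplicative log-normal with unit
mean; optode noise is additive Gaussian truncated at zero — the simplest
models consistent with the reported ± magnitudes. Sequencing noise is
Dirichlet-multinomial with a single concentration θ: replicate bags of a
well-homogenised slurry are compositionally close, and θ = 5000 gives
replicate-level proportion CVs of roughly 1–2% for dominant taxa and
~20% for taxa at the planted 0.4% baseline; much smaller θ (say, a few
hundred) would make the effective per-sample information ~θ reads, far
noisier than slurry replicates plausibly are. θ = ∞ selects the plain
multinomial limit used for exact-recovery checks. The rRNA analog is a
single replicate per condition, mirroring the n = 1 rRNA design; optional
contaminant OTUs (chloroplast, mitochondria, Archaea, unclassified
domain, one dataset-wide singleton) are spiked by relabelling reads of
the most abundant taxon so per-sample totals stay exactly at the library
size.

One global seed feeds fixed per-table seed offsets, so generating an
additional table never perturbs the earlier ones, and identical
configurations produce byte-identical outputs.

What the generator does **not** emulate: raw reads (no FASTQ, chimeras or
primer artifacts — clustering and classification are upstream of this
package), pressure effects, phylogenetic correlation among taxa,
time-resolved dynamics within the incubation, or compositional shifts in
non-planted taxa. Passing tests on synthetic data therefore demonstrate
the correctness of the estimators under the stated generative model, not
the biological fidelity of that model to any particular sediment.

## Numerical choices and degenerate inputs

* All stochastic functions take explicit seeds; the pipeline derives
  per-stage seeds from one configuration seed and logs them.
* Concentrations, rates and abundances are validated non-negative at the
  reading layer, with errors naming the offending file, row and column.
* Floors and flags instead of silent clipping: anoxic bags, supersaturated
  readings, quenched assays, infinite duplication times, infinite effect
  sizes, "new appearance" ratios.
* Rank tests use mid-ranks; BH adjustment applies to the parametric p
  only.
* The test suite exercises reduced problem sizes chosen for precision per
  unit time: 20–150 taxa, depths 10³–10⁵, 16–128 Dirichlet instances,
  200–400 rarefaction repeats.

## Known limitations

* The steady-state inversion cannot see non-constant respiration; only
  the forward model can represent it.
* With three replicates per group the rank-sum p has a coarse support;
  it accompanies, but does not drive, the responder decision.
* The effect-size estimator (IQR-based dispersion, median-over-instances
  ratio) is one defensible choice among several; absolute effect values
  are therefore not comparable across tools, though the decision
  thresholds were chosen on the same scale.
* Family aggregation trusts the provided lineage strings; no reference
  re-classification is attempted.
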