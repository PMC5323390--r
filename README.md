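# sedipulse

Analysis of detritus-pulse feeding experiments with deep-sea sediment
slurries: what happens to a benthic bacterial community, and to the carbon
it is fed, when a pulse of chitin or algal detritus arrives at the
seafloor?

The package is written for benthic microbial ecologists running *ex situ*
incubations in gas-permeable bags. It implements four connected analyses:

1. **Carbon budget** — direct cell counts convert to biomass carbon
   (`B = N·v·ρ·10⁶/M_C`, with cell volume `v = 0.07 µm³` and carbon
   density `ρ = 3×10⁻¹³ g C µm⁻³`), and together with oxygen uptake yield
   per-treatment net biomass yield, net C respired (respiratory quotient
   1.0), total C used, their shares of the added carbon pool
   (0.2 mg C mL⁻¹ ≈ 16.65 µmol C mL⁻¹), bacterial growth efficiency
   `BGE = yield/(yield+respired)`, and duplication times
   `T·ln2/ln(N₂₃/N₀)`.
2. **Bag oxygen model** — a sealed permeable bag obeys
   `dC/dt = k'(C_amb − C) − R` with conductance `k' = DA/(LV)`; at the end
   of the incubation the bag is in steady state, so the optode deficit
   inverts to the respiration rate `R = k'(C_amb − C_end)`.
3. **Enzyme kinetics** — MUF-standard calibration by OLS, two-timepoint
   Vmax at saturating substrate, and the total hydrolysis potential
   `(v₁+v₂)·T·6` µmol C mL⁻¹ over the incubation.
4. **Community response** — OTU filtering (organelles, Archaea,
   domain-unclassified, dataset singletons), rarefied richness and inverse
   Simpson, Bray–Curtis/NMDS/Mantel with threshold hulls, and a
   Monte-Carlo Dirichlet clr screen (128 instances, prior 0.5, log₂ clr):
   a replicated taxon responds at effect size > 4 and
   |clr difference| > 1 (one duplication) with presence in ≥ 2 of 3
   replicates; unreplicated rRNA profiles are screened at ≥ 1% abundance
   and ≥ twofold change.

A synthetic-experiment generator (`sim_config()`,
`simulate_experiment()`) produces all measurement streams with known
ground truth — treatment-specific exponential growth, constant-respiration
bag oxygen, zero-order fluorescence accumulation, Dirichlet-multinomial
OTU tables with planted opportunist blooms — so the whole pipeline is
testable offline.

## Worked example

Feed a published-style budget table — per-treatment day-0/day-23 cell
abundance, day-23 biomass and 23-day oxygen uptake — and derive the
carbon balance:

```r
library(sedipulse)

treatments <- c("unfed", "CHI")
counts <- rbind(
  data.frame(sample = c("u0", "c0"), treatment = treatments, day = 0,
             cells_per_ml = c(1.4e9, 1.3e9),
             biomass_umol_per_ml = biomass_from_cells(c(1.4e9, 1.3e9))),
  data.frame(sample = c("u23", "c23"), treatment = treatments, day = 23,
             cells_per_ml = c(2.3e9, 4.0e9),
             biomass_umol_per_ml = c(3.9, 6.7)))
o2 <- data.frame(sample = c("ub", "cb"), treatment = treatments,
                 o2_umol_per_ml = c(2.9, 6.1))
tab <- build_budget_table(counts, o2)
tab[tab$treatment == "CHI",
    c("net_yield", "net_C_respired", "total_C_used", "total_pct",
      "growth_efficiency", "duplication_time")]
#>   net_yield net_C_respired total_C_used total_pct growth_efficiency
#> 2       2.8            3.2            6    36.033          46.66667
#>   duplication_time
#> 2          14.1845
```

The chitin-fed community assimilated 2.8 and respired 3.2 µmol C per mL
sediment — 36% of the added carbon pool used in 23 days at a growth
efficiency of 47%, doubling every ~14 days while the unfed control
doubled in ~32.

The same functions drive the full workflow on synthetic data:

```sh
Rscript analysis/01_simulate.R   # generate the experiment (+ ground truth)
Rscript analysis/02_oxygen.R     # respiration from optode readings
Rscript analysis/03_enzymes.R    # calibration, Vmax, hydrolysis potential
Rscript analysis/04_budget.R     # the carbon budget table
Rscript analysis/05_community.R  # diversity, NMDS, responder screens
```

Each stage prints its summary and writes tab-separated tables under
`results/`.

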