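#!/usr/bin/env Rscript
# Stage 2: invert end-point optode readings to respiration rates.
#
# Each gas-permeable bag reaches a steady state in which microbial
# respiration is balanced by diffusive oxygen influx across the foil, so
# the end-point concentration deficit gives the volumetric respiration
# rate, and integration over the incubation the per-sediment oxygen uptake.

library(sedipulse)

readings <- read_measurements("results/synthetic/oxygen_readings.tsv",
                              "oxygen")
geom <- bag_geometry()
tab <- oxygen_uptake_table(readings, geom, duration = 23,
                           dilution_factor = 3.5)
write_measurements(tab, "results/oxygen_uptake.tsv")

agg <- aggregate(cbind(respiration_umol_l_day, o2_umol_per_ml) ~ treatment,
                 tab, mean)
cat("Per-treatment respiration (umol O2 / L slurry / d) and",
    "23-day uptake (umol O2 / mL sediment):\n")
print(agg, digits = 3)
cat("Bag conductance k' =", round(geom$conductance, 3), "per day\n")
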