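# Shared fixtures, all generated in code.

# Printed Table-1 measured quantities: day-23 biomass (µmol C/mL) and
# 23-day O2 uptake (µmol O2/mL sediment), plus day-0/day-23 cell counts.
table1_inputs <- function() {
  list(
    biomass_d23 = c(unfed = 3.9, CHI = 6.7, TWEI = 4.5, EHUX = 4.6,
                    BCLA = 4.3, MARC = 4.6),
    o2_uptake = c(unfed = 2.9, CHI = 6.1, TWEI = 4.9, EHUX = 4.7,
                  BCLA = 4.7, MARC = 4.4),
    cells_d0 = c(unfed = 1.4e9, CHI = 1.3e9, TWEI = 1.3e9, EHUX = 1.4e9,
                 BCLA = 1.4e9, MARC = 1.4e9),
    cells_d23 = c(unfed = 2.3e9, CHI = 4.0e9, TWEI = 2.7e9, EHUX = 2.8e9,
                  BCLA = 2.6e9, MARC = 2.8e9))
}

# Counts/o2 data.frames from the printed Table-1 means (one "replicate").
table1_frames <- function() {
  t1 <- table1_inputs()
  trs <- names(t1$biomass_d23)
  counts <- rbind(
    data.frame(sample = paste0(trs, "_d0"), treatment = trs, day = 0,
               cells_per_ml = t1$cells_d0,
               biomass_umol_per_ml = NA_real_),
    data.frame(sample = paste0(trs, "_d23"), treatment = trs, day = 23,
               cells_per_ml = t1$cells_d23,
               biomass_umol_per_ml = t1$biomass_d23))
  counts$biomass_umol_per_ml[counts$day == 0] <-
    biomass_from_cells(counts$cells_per_ml[counts$day == 0])
  o2 <- data.frame(sample = paste0(trs, "_bag"), treatment = trs,
                   o2_umol_per_ml = t1$o2_uptake)
  list(counts = counts, o2 = o2)
}

# Small OTU fixture with known filtering outcomes.
toy_otu_fixture <- function() {
  counts <- rbind(
    s1 = c(OTU_A = 10L, OTU_B = 5L, OTU_chl = 4L, OTU_arc = 3L,
           OTU_single = 1L, OTU_pair = 1L),
    s2 = c(OTU_A = 8L, OTU_B = 0L, OTU_chl = 2L, OTU_arc = 1L,
           OTU_single = 0L, OTU_pair = 1L))
  taxonomy <- c(
    OTU_A = "Bacteria;Proteobacteria;Gammaproteobacteria;Alteromonadales;Colwelliaceae;Colwellia",
    OTU_B = "Bacteria;Bacteroidetes;Flavobacteriia;Flavobacteriales;Flavobacteriaceae;",
    OTU_chl = "Bacteria;Cyanobacteria;Chloroplast;;;",
    OTU_arc = "Archaea;Thaumarchaeota;;;;",
    OTU_single = "Bacteria;Planctomycetes;;;;",
    OTU_pair = "Bacteria;Chloroflexi;;;;")
  list(counts = counts, taxonomy = taxonomy)
}

# Dirichlet-multinomial community fixture with planted fold changes:
# returns counts for two groups of n_rep samples plus the truth. Planted
# taxa start at the rare-but-sequenceable baseline (0.4%) the generator
# uses for opportunists; the background community is log-normal.
screen_fixture <- function(n_taxa = 60, n_planted = 10, fold = 8,
                           n_rep = 3, depth = 1e5, theta = 5000,
                           seed = 42) {
  set.seed(seed)
  ids <- sprintf("T%03d", seq_len(n_taxa))
  base <- rlnorm(n_taxa, 0, 1.5)
  p0 <- base / sum(base)
  p0[seq_len(n_planted)] <- 0.004
  p0 <- p0 / sum(p0)
  planted <- ids[seq_len(n_planted)]
  p1 <- p0
  p1[seq_len(n_planted)] <- p1[seq_len(n_planted)] * fold
  p1 <- p1 / sum(p1)
  draw <- function(p, n) {
    t(vapply(seq_len(n), function(i) {
      g <- rgamma(length(p), shape = theta * p)
      as.integer(rmultinom(1, depth, g / sum(g)))
    }, integer(length(p))))
  }
  g0 <- draw(p0, n_rep); rownames(g0) <- paste0("ref", seq_len(n_rep))
  g1 <- draw(p1, n_rep); rownames(g1) <- paste0("trt", seq_len(n_rep))
  counts <- rbind(g1, g0)
  colnames(counts) <- ids
  list(counts = counts, planted = planted, ids = ids,
       groupA = rownames(g1), groupB = rownames(g0))
}
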