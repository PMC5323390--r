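#' Configuration of a synthetic detritus-pulse incubation
#'
#' Defines the ground truth of a simulated incubation experiment: one unfed
#' control plus carbon-amended treatments, per-treatment exponential growth
#' rates of the cell population, constant volumetric respiration rates
#' (driving the bag oxygen model), saturated-enzyme hydrolysis rates, and a
#' log-normal baseline community in which selected "opportunist" taxa bloom
#' treatment-specifically by a known fold change.
#'
#' The default parameter set emulates the magnitudes of a 23-day deep-sea
#' sediment slurry experiment: starting abundance 1.4e9 cells per mL
#' sediment, end-point oxygen uptakes of 2.9-6.1 µmol O2 per mL sediment,
#' chitobiase/beta-glucosidase maximum velocities of 0.005-0.25 µmol per mL
#' sediment per day, and a 150-taxon community sequenced at 30,000 reads.
#'
#' @param treatments treatment labels; the first is the unfed control.
#' @param n_replicates incubation bags per treatment (oxygen, enzymes).
#' @param n_count_replicates bags subsampled for cell counts and rDNA
#'   sequencing.
#' @param duration incubation length, days (must be non-negative).
#' @param n0_cells starting abundance, cells per mL undiluted sediment.
#' @param growth_rate named vector, 1/day per treatment.
#' @param respiration named vector, µmol O2 per L slurry per day per
#'   treatment.
#' @param vmax named list per treatment of c(chitobiase=, betaglucosidase=)
#'   µmol MUF per mL sediment per day.
#' @param n_taxa baseline community size.
#' @param lognormal_meanlog,lognormal_sdlog log-normal parameters of the
#'   baseline abundance distribution.
#' @param planted_responders data.frame(treatment, taxon, fold): taxa whose
#'   day-23 relative abundance is multiplied by \code{fold} (> 0) in that
#'   treatment before renormalisation.
#' @param library_size sequencing depth per sample.
#' @param overdispersion Dirichlet-multinomial concentration scalar
#'   (\code{Inf} gives the plain multinomial limit).
#' @param count_cv,fluor_cv multiplicative log-normal noise CVs for cell
#'   counts and fluorescence readings.
#' @param optode_sd additive Gaussian noise sd of optode readings,
#'   µmol L⁻¹.
#' @param dilution_factor slurry dilution factor.
#' @param include_contaminants add chloroplast/mitochondria/Archaea/
#'   unclassified-domain OTUs and one dataset-wide singleton, to exercise
#'   table filters.
#' @param seed global seed; each generated table derives its own fixed
#'   offset seed from it, so adding a table does not perturb earlier ones.
#' @return object of class \code{sim_config}.
#' @export
sim_config <- function(treatments = c("unfed", "CHI", "TWEI", "EHUX",
                                      "BCLA", "MARC"),
                       n_replicates = 5,
                       n_count_replicates = 3,
                       duration = 23,
                       n0_cells = 1.4e9,
                       growth_rate = NULL,
                       respiration = NULL,
                       vmax = NULL,
                       n_taxa = 150,
                       lognormal_meanlog = 0,
                       lognormal_sdlog = 2,
                       planted_responders = NULL,
                       library_size = 30000,
                       overdispersion = 5000,
                       count_cv = 0.07,
                       fluor_cv = 0.05,
                       optode_sd = 2,
                       dilution_factor = 3.5,
                       include_contaminants = TRUE,
                       seed = 1) {
  if (duration < 0) stop("duration must be non-negative")
  stopifnot(n_replicates >= 1, n_count_replicates >= 1,
            library_size >= 1, n_taxa >= 2, overdispersion > 0)
  control <- treatments[1]
  if (is.null(growth_rate)) {
    # end/start abundance ratios emulating observed day-23 counts
    ratio <- c(unfed = 2.3 / 1.4, CHI = 4.0 / 1.3, TWEI = 2.7 / 1.3,
               EHUX = 2.8 / 1.4, BCLA = 2.6 / 1.4, MARC = 2.8 / 1.4)
    growth_rate <- log(ratio[treatments]) / max(duration, 1)
    names(growth_rate) <- treatments
  }
  if (is.null(respiration)) {
    uptake <- c(unfed = 2.9, CHI = 6.1, TWEI = 4.9, EHUX = 4.7,
                BCLA = 4.7, MARC = 4.4)  # µmol O2 per mL sediment, total
    respiration <- uptake[treatments] * 1000 /
      (max(duration, 1) * dilution_factor)
    names(respiration) <- treatments
  }
  if (is.null(vmax)) {
    chito <- c(unfed = 0.016, CHI = 0.16, TWEI = 0.10, EHUX = 0.125,
               BCLA = 0.25, MARC = 0.083)
    bglu <- c(unfed = 0.005, CHI = 0.04, TWEI = 0.10, EHUX = 0.15,
              BCLA = 0.127, MARC = 0.04)
    vmax <- lapply(treatments, function(tr)
      c(chitobiase = unname(chito[tr]), betaglucosidase = unname(bglu[tr])))
    names(vmax) <- treatments
  }
  if (is.null(planted_responders)) {
    planted_responders <- .default_planting(treatments)
  }
  stopifnot(all(planted_responders$fold > 0))
  if (any(growth_rate < 0) || any(!is.finite(growth_rate)))
    stop("growth rates must be finite and non-negative")
  if (any(respiration < 0)) stop("respiration rates must be non-negative")
  if (any(unlist(vmax) < 0)) stop("vmax values must be non-negative")
  ids <- sprintf("OTU_%04d", seq_len(n_taxa))
  bad <- setdiff(planted_responders$taxon, ids)
  if (length(bad))
    stop("planted responder taxon not in community: ",
         paste(bad, collapse = ", "))
  structure(list(treatments = treatments, control = control,
                 n_replicates = n_replicates,
                 n_count_replicates = n_count_replicates,
                 duration = duration, n0_cells = n0_cells,
                 growth_rate = growth_rate, respiration = respiration,
                 vmax = vmax, n_taxa = n_taxa, taxon_ids = ids,
                 lognormal_meanlog = lognormal_meanlog,
                 lognormal_sdlog = lognormal_sdlog,
                 planted_responders = planted_responders,
                 library_size = library_size,
                 overdispersion = overdispersion,
                 count_cv = count_cv, fluor_cv = fluor_cv,
                 optode_sd = optode_sd,
                 dilution_factor = dilution_factor,
                 include_contaminants = include_contaminants,
                 seed = seed),
            class = "sim_config")
}

# Default opportunist planting: a few taxa per treatment blooming 8- to
# 32-fold, plus a modest bloomer in the unfed control.
.default_planting <- function(treatments) {
  plan <- list(
    unfed = data.frame(taxon = "OTU_0016", fold = 6),
    CHI = data.frame(taxon = sprintf("OTU_%04d", 1:3),
                     fold = c(32, 16, 8)),
    TWEI = data.frame(taxon = sprintf("OTU_%04d", 4:6),
                      fold = c(16, 8, 8)),
    EHUX = data.frame(taxon = sprintf("OTU_%04d", 7:9),
                      fold = c(16, 8, 8)),
    BCLA = data.frame(taxon = sprintf("OTU_%04d", 10:12),
                      fold = c(16, 8, 8)),
    MARC = data.frame(taxon = sprintf("OTU_%04d", 13:15),
                      fold = c(16, 8, 8)))
  out <- do.call(rbind, lapply(intersect(treatments, names(plan)),
                               function(tr)
                                 cbind(treatment = tr, plan[[tr]])))
  rownames(out) <- NULL
  out
}

# Multiplicative log-normal noise with unit mean and given CV.
.ln_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

#' Simulate treatment-specific exponential cell growth
#'
#' Each counted replicate receives a day-0 and a day-23 cell count: the
#' expected day-23 count is the day-0 expectation times
#' exp(rate * duration), with multiplicative log-normal counting noise of
#' unit mean at the configured CV.
#'
#' @param config a \code{\link{sim_config}}.
#' @return data.frame: sample, treatment, day, replicate, cells_per_ml.
#' @export
simulate_growth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 101L)
  rows <- list()
  for (tr in config$treatments) {
    r <- config$growth_rate[[tr]]
    n <- config$n_count_replicates
    d0 <- config$n0_cells * .ln_noise(n, config$count_cv)
    d23 <- config$n0_cells * exp(r * config$duration) *
      .ln_noise(n, config$count_cv)
    rows[[tr]] <- data.frame(
      sample = c(sprintf("%s_d0_r%d", tr, seq_len(n)),
                 sprintf("%s_d23_r%d", tr, seq_len(n))),
      treatment = tr,
      day = rep(c(0, config$duration), each = n),
      replicate = rep(seq_len(n), 2),
      cells_per_ml = c(d0, d23),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate end-point optode readings for permeable incubation bags
#'
#' The end-point concentration of each bag is the analytic solution of the
#' bag oxygen balance at the configured respiration rate, plus additive
#' Gaussian optode noise, truncated at 0. Bags whose analytic steady state
#' is negative are flagged hypoxic/anoxic.
#'
#' @param config a \code{\link{sim_config}}.
#' @param geometry a \code{\link{bag_geometry}}.
#' @return data.frame: sample, treatment, day, o2_umol_per_l, anoxic.
#' @export
simulate_bag_oxygen <- function(config, geometry = bag_geometry()) {
  stopifnot(inherits(config, "sim_config"),
            inherits(geometry, "bag_geometry"))
  set.seed(config$seed + 102L)
  k <- geometry$conductance
  rows <- lapply(config$treatments, function(tr) {
    R <- config$respiration[[tr]]
    n <- config$n_replicates
    true_end <- as.numeric(forward_bag_model(R, geometry, config$duration))
    anoxic <- geometry$ambient_O2 - R / k < 0
    obs <- pmax(0, true_end + stats::rnorm(n, 0, config$optode_sd))
    data.frame(sample = sprintf("%s_bag%d", tr, seq_len(n)),
               treatment = tr, day = config$duration,
               o2_umol_per_l = obs, anoxic = anoxic,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate MUF enzyme assays with standards
#'
#' Builds a MUF standard series (0-6 nmol per mL, instrument gain 1000 a.u.
#' per nmol/mL) and, for each bag and enzyme, fluorescence readings at 1 h
#' and 3 h of a saturated (zero-order) hydrolysis time course whose slope
#' corresponds to the configured sediment-basis Vmax. Readings carry
#' multiplicative log-normal noise; a constant background offset is added
#' to both time points (the rate estimator is offset-invariant).
#'
#' @param config a \code{\link{sim_config}}.
#' @param gain instrument gain, a.u. per nmol MUF per mL.
#' @param background constant background fluorescence, a.u.
#' @return list with \code{assays} and \code{standards} data.frames.
#' @export
simulate_enzyme_assays <- function(config, gain = 1000, background = 50) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 103L)
  standards <- data.frame(conc_nmol_per_ml = 0:6,
                          fluorescence = gain * (0:6))
  rows <- list()
  for (tr in config$treatments) {
    for (enz in names(config$vmax[[tr]])) {
      v_sed <- config$vmax[[tr]][[enz]]
      # µmol/mL sediment/day -> nmol/mL slurry/hour
      rate <- v_sed * 1000 / (24 * config$dilution_factor)
      for (b in seq_len(config$n_replicates)) {
        tt <- c(1, 3)
        fl <- (gain * rate * tt + background) *
          .ln_noise(length(tt), config$fluor_cv)
        rows[[length(rows) + 1L]] <- data.frame(
          sample = sprintf("%s_bag%d", tr, b), treatment = tr,
          enzyme = enz, time_h = tt, fluorescence = fl,
          stringsAsFactors = FALSE)
      }
    }
  }
  assays <- do.call(rbind, rows)
  rownames(assays) <- NULL
  list(assays = assays, standards = standards)
}

# Dirichlet-multinomial sample of given depth around proportions p.
.dirmult_sample <- function(p, depth, theta) {
  if (is.finite(theta)) {
    g <- stats::rgamma(length(p), shape = theta * p, rate = 1)
    if (sum(g) == 0) g[which.max(p)] <- 1
    p <- g / sum(g)
  }
  as.integer(stats::rmultinom(1, depth, p))
}

.opportunist_lineages <- c(
  "Bacteria;Proteobacteria;Gammaproteobacteria;Alteromonadales;Colwelliaceae;Colwellia",
  "Bacteria;Proteobacteria;Gammaproteobacteria;Alteromonadales;Psychromonadaceae;Psychromonas",
  "Bacteria;Proteobacteria;Gammaproteobacteria;Oceanospirillales;Oceanospirillaceae;Marinomonas",
  "Bacteria;Bacteroidetes;Flavobacteriia;Flavobacteriales;Flavobacteriaceae;Ulvibacter",
  "Bacteria;Proteobacteria;Gammaproteobacteria;Alteromonadales;Moritellaceae;Moritella",
  "Bacteria;Proteobacteria;Deltaproteobacteria;Desulfobacterales;Desulfobacteraceae;Desulfobacter",
  "Bacteria;Bacteroidetes;Bacteroidia;Bacteroidales;Marinilabiaceae;Marinilabilia",
  "Bacteria;Proteobacteria;Gammaproteobacteria;Alteromonadales;;",
  "Bacteria;Proteobacteria;Deltaproteobacteria;Desulfuromonadales;Geobacteraceae;Geobacter",
  "Bacteria;Proteobacteria;Deltaproteobacteria;Desulfuromonadales;Desulfuromonadaceae;Desulfuromonas",
  "Bacteria;Proteobacteria;Gammaproteobacteria;Alteromonadales;Shewanellaceae;Shewanella",
  "Bacteria;Proteobacteria;Epsilonproteobacteria;Campylobacterales;Campylobacteraceae;Arcobacter",
  "Bacteria;Proteobacteria;Gammaproteobacteria;Alteromonadales;Pseudoalteromonadaceae;Pseudoalteromonas",
  "Bacteria;Bacteroidetes;Flavobacteriia;Flavobacteriales;Flavobacteriaceae;Polaribacter",
  "Bacteria;Proteobacteria;Gammaproteobacteria;Alteromonadales;Colwelliaceae;Thalassomonas",
  "Bacteria;Proteobacteria;Gammaproteobacteria;Oceanospirillales;Oceanospirillaceae;Neptunomonas")

# Synthetic SILVA-style lineages: the first 16 taxa carry realistic
# opportunist family names (used by the default planting), the remainder
# generic background families.
.make_taxonomy <- function(ids) {
  n <- length(ids)
  phyla <- c("Proteobacteria", "Bacteroidetes", "Planctomycetes",
             "Chloroflexi", "Acidobacteria", "Actinobacteria",
             "Verrucomicrobia", "Gemmatimonadetes")
  lin <- character(n)
  k <- min(n, length(.opportunist_lineages))
  lin[seq_len(k)] <- .opportunist_lineages[seq_len(k)]
  if (n > k) {
    idx <- (k + 1):n
    ph <- phyla[(idx %% length(phyla)) + 1]
    fam <- sprintf("Family_%03d", ((idx * 7) %% 40) + 1)
    lin[idx] <- sprintf("Bacteria;%s;Class_%s;Order_%s;%s;Genus_%03d",
                        ph, ph, ph, fam, idx)
  }
  stats::setNames(lin, ids)
}

#' Simulate rDNA and rRNA OTU tables with planted responders
#'
#' Draws a log-normal baseline community, multiplies the planted responder
#' taxa of each treatment by their fold change (renormalised) to obtain the
#' day-23 composition, and samples counts by Dirichlet-multinomial at the
#' configured depth and overdispersion. The rDNA analog has
#' \code{n_count_replicates} replicates per condition; the rRNA analog is a
#' single replicate per condition. Optionally appends contaminant OTUs
#' (chloroplast, mitochondria, Archaea, unclassified domain) and one
#' dataset-wide singleton, for which one read of the most abundant taxon in
#' the first sample is relabelled so that per-sample totals stay exactly at
#' the library size.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{counts_rdna}, \code{counts_rrna} (samples x OTUs
#'   integer matrices), \code{taxonomy}, \code{metadata} and
#'   \code{ground_truth} (baseline proportions, day-23 target proportions,
#'   planted responder table).
#' @export
simulate_otu_tables <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 104L)
  ids <- config$taxon_ids
  base <- stats::rlnorm(config$n_taxa, config$lognormal_meanlog,
                        config$lognormal_sdlog)
  p0 <- base / sum(base)
  names(p0) <- ids
  # planted opportunists start rare but present (<1%), as observed for
  # copiotrophs in oligotrophic sediment before a detritus pulse
  planted_ids <- unique(config$planted_responders$taxon)
  if (length(planted_ids)) {
    p0[planted_ids] <- 0.004
    p0 <- p0 / sum(p0)
  }
  target <- list()
  for (tr in config$treatments) {
    p <- p0
    pl <- config$planted_responders[config$planted_responders$treatment == tr, ]
    if (nrow(pl)) {
      j <- match(pl$taxon, ids)
      if (anyNA(j)) stop("planted responder taxon not in community")
      p[j] <- p[j] * pl$fold
      p <- p / sum(p)
    }
    target[[tr]] <- p
  }

  draw_table <- function(n_rep, molecule) {
    conds <- c(list(list(label = "day0", p = p0, day = 0,
                         treatment = "day0")),
               lapply(config$treatments, function(tr)
                 list(label = tr, p = target[[tr]], day = config$duration,
                      treatment = tr)))
    mats <- list(); meta <- list()
    for (cn in conds) {
      for (r in seq_len(n_rep)) {
        nm <- sprintf("%s_%s_%s_r%d", molecule, cn$label,
                      ifelse(cn$day == 0, "d0", "d23"), r)
        mats[[nm]] <- .dirmult_sample(cn$p, config$library_size,
                                      config$overdispersion)
        meta[[nm]] <- data.frame(sample = nm, treatment = cn$treatment,
                                 day = cn$day, molecule = molecule,
                                 replicate = r, stringsAsFactors = FALSE)
      }
    }
    counts <- do.call(rbind, mats)
    colnames(counts) <- ids
    list(counts = counts, meta = do.call(rbind, meta))
  }

  rdna <- draw_table(config$n_count_replicates, "rdna")
  rrna <- draw_table(1L, "rrna")
  taxonomy <- .make_taxonomy(ids)

  if (config$include_contaminants) {
    extra <- c(OTU_C001 = "Bacteria;Cyanobacteria;Chloroplast;;;",
               OTU_C002 = paste0("Bacteria;Proteobacteria;",
                                 "Alphaproteobacteria;Rickettsiales;",
                                 "Mitochondria;"),
               OTU_C003 = "Archaea;Thaumarchaeota;;;;",
               OTU_C004 = ";;;;;",
               OTU_C005 = paste0("Bacteria;Proteobacteria;",
                                 "Gammaproteobacteria;Order_X;Family_X;"))
    add_contaminants <- function(counts) {
      pad <- matrix(0L, nrow(counts), length(extra),
                    dimnames = list(rownames(counts), names(extra)))
      counts <- cbind(counts, pad)
      # relabel a few reads of the most abundant taxon of sample 1 so
      # per-sample totals are preserved exactly
      top <- which.max(counts[1, seq_along(ids)])
      take <- c(OTU_C001 = 3L, OTU_C002 = 3L, OTU_C003 = 3L,
                OTU_C004 = 3L, OTU_C005 = 1L)
      stopifnot(counts[1, top] > sum(take))
      counts[1, names(take)] <- take
      counts[1, top] <- counts[1, top] - sum(take)
      counts
    }
    rdna$counts <- add_contaminants(rdna$counts)
    taxonomy <- c(taxonomy, extra)
  }

  list(counts_rdna = rdna$counts, counts_rrna = rrna$counts,
       taxonomy = taxonomy,
       metadata = rbind(rdna$meta, rrna$meta),
       ground_truth = list(baseline = p0, target = target,
                           planted = config$planted_responders))
}

#' Generate a complete synthetic incubation dataset
#'
#' Runs all four simulators under one global seed (each table uses its own
#' fixed seed offset) and returns the tables together with the ground-truth
#' record. When \code{dir} is given, all tables are written as
#' tab-separated text plus a JSON manifest listing the files and the ground
#' truth.
#'
#' @param config a \code{\link{sim_config}}.
#' @param geometry a \code{\link{bag_geometry}}.
#' @param dir optional output directory.
#' @return object of class \code{synthetic_experiment}: list with
#'   \code{cell_counts}, \code{oxygen}, \code{enzymes} (assays +
#'   standards), \code{otu} (tables + taxonomy + metadata),
#'   \code{ground_truth}, \code{config}, \code{geometry}.
#' @export
simulate_experiment <- function(config = sim_config(),
                                geometry = bag_geometry(), dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  cells <- simulate_growth(config)
  oxy <- simulate_bag_oxygen(config, geometry)
  enz <- simulate_enzyme_assays(config)
  otu <- simulate_otu_tables(config)
  truth <- list(growth_rate = config$growth_rate,
                respiration = config$respiration,
                vmax = config$vmax,
                planted = config$planted_responders,
                baseline = otu$ground_truth$baseline)
  out <- structure(list(cell_counts = cells, oxygen = oxy, enzymes = enz,
                        otu = otu[c("counts_rdna", "counts_rrna",
                                    "taxonomy", "metadata")],
                        ground_truth = truth, config = config,
                        geometry = geometry),
                   class = "synthetic_experiment")
  if (!is.null(dir)) write_synthetic_experiment(out, dir)
  out
}

#' Write a synthetic experiment to delimited-text files
#'
#' Emits the same formats the analysis readers consume, plus a JSON
#' manifest with the file list and ground truth.
#'
#' @param experiment a \code{\link{simulate_experiment}} result.
#' @param dir output directory (created if absent).
#' @return invisibly, the manifest path.
#' @export
write_synthetic_experiment <- function(experiment, dir) {
  stopifnot(inherits(experiment, "synthetic_experiment"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_measurements(experiment$cell_counts, p("cell_counts.tsv"))
  write_measurements(experiment$oxygen, p("oxygen_readings.tsv"))
  write_measurements(experiment$enzymes$assays, p("enzyme_assays.tsv"))
  write_measurements(experiment$enzymes$standards, p("muf_standards.tsv"))
  write_otu_table(experiment$otu$counts_rdna, p("otu_rdna.tsv"))
  write_otu_table(experiment$otu$counts_rrna, p("otu_rrna.tsv"))
  write_taxonomy(experiment$otu$taxonomy, p("taxonomy.tsv"))
  write_measurements(experiment$otu$metadata, p("sample_metadata.tsv"))
  files <- c("cell_counts.tsv", "oxygen_readings.tsv", "enzyme_assays.tsv",
             "muf_standards.tsv", "otu_rdna.tsv", "otu_rrna.tsv",
             "taxonomy.tsv", "sample_metadata.tsv")
  manifest <- list(files = files,
                   seed = experiment$config$seed,
                   ground_truth = list(
                     growth_rate = as.list(experiment$ground_truth$growth_rate),
                     respiration = as.list(experiment$ground_truth$respiration),
                     vmax = experiment$ground_truth$vmax,
                     planted = experiment$ground_truth$planted))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(p("manifest.json"))
}
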