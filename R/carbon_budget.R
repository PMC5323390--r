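#' Conversion constants for the sediment carbon budget
#'
#' Bundles the fixed conversion factors used throughout the carbon mass
#' balance: the per-cell biovolume and carbon density used to convert direct
#' cell counts into biomass carbon, the mass of organic carbon added per mL
#' of undiluted sediment, the molar mass of carbon, the incubation duration,
#' the respiratory quotient used to convert oxygen consumption into respired
#' carbon, and the slurry dilution factor.
#'
#' The derived field \code{added_C_molar} (µmol C per mL sediment, equal to
#' mmol per L) is computed from \code{added_C_mass} and \code{molar_mass_C}.
#'
#' @param cell_volume average cell volume, µm³ per cell.
#' @param carbon_density biomass carbon per biovolume, g C per µm³.
#' @param molar_mass_C molar mass of carbon, g per mol.
#' @param added_C_mass organic carbon amendment, mg C per mL undiluted
#'   sediment.
#' @param duration incubation duration in days.
#' @param respiratory_quotient mol C respired per mol O2 consumed.
#' @param dilution_factor volumetric dilution of sediment into slurry
#'   (slurry volume per sediment volume).
#' @return An object of class \code{budget_constants}: a named list of the
#'   above plus \code{added_C_molar}.
#' @examples
#' const <- budget_constants()
#' const$added_C_molar  # ~16.65 umol C per mL sediment
#' @export
budget_constants <- function(cell_volume = 0.07,
                             carbon_density = 3e-13,
                             molar_mass_C = 12.011,
                             added_C_mass = 0.2,
                             duration = 23,
                             respiratory_quotient = 1,
                             dilution_factor = 3.5) {
  vals <- c(cell_volume = cell_volume, carbon_density = carbon_density,
            molar_mass_C = molar_mass_C, added_C_mass = added_C_mass,
            duration = duration, respiratory_quotient = respiratory_quotient,
            dilution_factor = dilution_factor)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all budget constants must be finite and strictly positive")
  out <- as.list(vals)
  out$added_C_molar <- added_C_molar(added_C_mass, molar_mass_C)
  class(out) <- "budget_constants"
  out
}

#' Molar concentration of the carbon amendment
#'
#' Converts a carbon amendment given as mg C per mL undiluted sediment into
#' mmol C per L (numerically equal to µmol per mL).
#'
#' @param mass mg C per mL.
#' @param molar_mass g per mol.
#' @return mmol C per L.
#' @examples
#' added_C_molar(0.2, 12.011)  # 16.65
#' @export
added_C_molar <- function(mass, molar_mass = 12.011) {
  stopifnot(is.numeric(mass), all(mass >= 0), molar_mass > 0)
  mass * 1000 / molar_mass
}

#' Convert cell counts to biomass carbon
#'
#' Cells per mL sediment are converted to µmol C per mL sediment using the
#' average cell biovolume and the carbon-per-biovolume conversion factor.
#'
#' @param cells cells per mL undiluted sediment (vectorised).
#' @param const a \code{\link{budget_constants}} object.
#' @return µmol C per mL undiluted sediment.
#' @examples
#' biomass_from_cells(1e9)  # 1.748
#' @export
biomass_from_cells <- function(cells, const = budget_constants()) {
  stopifnot(is.numeric(cells))
  if (any(cells < 0, na.rm = TRUE)) stop("cell counts must be non-negative")
  # g C per mL -> µg (1e6) -> µmol (/ molar mass)
  cells * const$cell_volume * const$carbon_density * 1e6 / const$molar_mass_C
}

#' Stimulated net biomass yield
#'
#' Difference between day-23 biomass in a carbon-amended treatment and in the
#' unfed control, in µmol C per mL sediment. Negative values (possible in
#' synthetic data) are reported as-is.
#'
#' @param biomass_treat,biomass_unfed day-23 biomass, µmol C per mL.
#' @return µmol C per mL.
#' @export
net_biomass_yield <- function(biomass_treat, biomass_unfed) {
  stopifnot(all(biomass_treat >= 0, na.rm = TRUE),
            all(biomass_unfed >= 0, na.rm = TRUE))
  biomass_treat - biomass_unfed
}

#' Net carbon respired over the incubation
#'
#' Converts the excess oxygen uptake of a treatment over the unfed control
#' into respired carbon via the respiratory quotient.
#'
#' @param o2_treat,o2_unfed total O2 uptake, µmol O2 per mL sediment over the
#'   incubation.
#' @param const a \code{\link{budget_constants}} object.
#' @return µmol C per mL sediment.
#' @export
net_C_respired <- function(o2_treat, o2_unfed, const = budget_constants()) {
  stopifnot(all(o2_treat >= 0, na.rm = TRUE), all(o2_unfed >= 0, na.rm = TRUE))
  (o2_treat - o2_unfed) * const$respiratory_quotient
}

#' Express a carbon amount as percent of the added carbon
#'
#' @param amount µmol C per mL sediment.
#' @param const a \code{\link{budget_constants}} object.
#' @return percent of the added carbon pool.
#' @export
pct_of_added_C <- function(amount, const = budget_constants()) {
  stopifnot(const$added_C_molar > 0)
  amount / const$added_C_molar * 100
}

#' Bacterial growth efficiency
#'
#' Fraction of the total carbon used (assimilated + respired) that was
#' converted into biomass, in percent. Undefined (NA with attribute
#' \code{"not_available"}) when total carbon used is not positive, mirroring
#' "n/a" entries for controls.
#'
#' @param net_yield net biomass yield, µmol C per mL.
#' @param total_used total carbon used, µmol C per mL.
#' @return percent, or NA flagged not-available.
#' @export
growth_efficiency <- function(net_yield, total_used) {
  out <- ifelse(total_used > 0, net_yield / total_used * 100, NA_real_)
  if (any(!is.na(total_used) & total_used <= 0)) {
    attr(out, "not_available") <- which(!is.na(total_used) & total_used <= 0)
  }
  out
}

#' Community duplication time from two cell counts
#'
#' Assuming exponential growth between the start and end of the incubation,
#' the doubling time is \code{duration * log(2) / log(n_end/n_start)}.
#' Equal counts give +Inf (no net growth), flagged via attribute.
#'
#' @param n0,n23 cell counts at the start and end (cells per mL).
#' @param duration days between the two counts.
#' @return doubling time in days.
#' @examples
#' duplication_time(1.4e9, 2.3e9, 23)  # ~32 days
#' @export
duplication_time <- function(n0, n23, duration) {
  if (any(n0 <= 0) || any(n23 <= 0))
    stop("cell counts must be strictly positive for duplication time")
  if (any(duration < 0)) stop("duration must be non-negative")
  out <- duration * log(2) / log(n23 / n0)
  out[n23 == n0] <- Inf
  if (any(n23 == n0)) attr(out, "no_growth") <- which(n23 == n0)
  out
}

#' Assemble the treatment carbon-budget table
#'
#' Combines per-replicate cell counts (day 0 and day 23) and per-replicate
#' total oxygen uptake into one budget row per treatment: mean cell
#' abundance, biomass, stimulated net biomass yield relative to the unfed
#' control, oxygen uptake, net carbon respired, total carbon used, the
#' percent-of-added-carbon versions of each, bacterial growth efficiency,
#' and the duplication time. The unfed control row carries NA for the
#' treatment-relative columns.
#'
#' Derived columns are computed from treatment means; the dispersion columns
#' (\code{*_sd}) are replicate standard deviations for measured quantities
#' and first-order error propagation for differences.
#'
#' @param counts data.frame with columns \code{sample}, \code{treatment},
#'   \code{day} (0 or the end day) and either \code{cells_per_ml} (cells per
#'   mL undiluted sediment, converted via \code{const}) or
#'   \code{biomass_umol_per_ml} (used directly when present).
#' @param o2 data.frame with columns \code{treatment} and
#'   \code{o2_umol_per_ml} (total uptake per mL undiluted sediment over the
#'   incubation), one row per replicate bag.
#' @param const a \code{\link{budget_constants}} object.
#' @param control name of the unfed control treatment.
#' @return data.frame, one row per treatment, class \code{budget_table}.
#' @export
build_budget_table <- function(counts, o2, const = budget_constants(),
                               control = "unfed") {
  stopifnot(is.data.frame(counts), is.data.frame(o2))
  need <- c("treatment", "day")
  if (!all(need %in% names(counts)))
    stop("counts must have columns treatment and day")
  if (!all(c("treatment", "o2_umol_per_ml") %in% names(o2)))
    stop("o2 must have columns treatment and o2_umol_per_ml")
  if (!control %in% counts$treatment[counts$day > 0])
    stop("missing unfed control rows for day 23: treatment '", control,
         "' not found")

  if ("biomass_umol_per_ml" %in% names(counts)) {
    counts$.biomass <- counts$biomass_umol_per_ml
    counts$.cells <- if ("cells_per_ml" %in% names(counts))
      counts$cells_per_ml else NA_real_
  } else {
    if (!"cells_per_ml" %in% names(counts))
      stop("counts needs cells_per_ml or biomass_umol_per_ml")
    counts$.cells <- counts$cells_per_ml
    counts$.biomass <- biomass_from_cells(counts$cells_per_ml, const)
  }

  msd <- function(df, value) {
    m <- tapply(df[[value]], df$treatment, mean, na.rm = TRUE)
    s <- tapply(df[[value]], df$treatment, stats::sd, na.rm = TRUE)
    list(mean = m, sd = s)
  }

  d0 <- counts[counts$day == 0, ]
  d23 <- counts[counts$day > 0, ]
  treatments <- unique(d23$treatment)
  treatments <- c(control, setdiff(treatments, control))

  b23 <- msd(d23, ".biomass")
  c23 <- msd(d23, ".cells")
  c0 <- if (nrow(d0)) msd(d0, ".cells") else NULL
  o2m <- msd(o2, "o2_umol_per_ml")

  bu <- b23$mean[[control]]
  bu_sd <- b23$sd[[control]]
  ou <- o2m$mean[[control]]
  ou_sd <- o2m$sd[[control]]

  rows <- lapply(treatments, function(tr) {
    bt <- b23$mean[[tr]]
    ot <- if (tr %in% names(o2m$mean)) o2m$mean[[tr]] else NA_real_
    is_ctrl <- identical(tr, control)
    yield <- if (is_ctrl) NA_real_ else net_biomass_yield(bt, bu)
    resp <- if (is_ctrl) NA_real_ else net_C_respired(ot, ou, const)
    total <- yield + resp
    n0 <- if (!is.null(c0) && tr %in% names(c0$mean)) c0$mean[[tr]] else NA_real_
    dup <- if (is.finite(n0) && n0 > 0 && isTRUE(c23$mean[[tr]] > 0))
      duplication_time(n0, c23$mean[[tr]], const$duration) else NA_real_
    data.frame(
      treatment = tr,
      cell_abundance_d0 = n0,
      cell_abundance_d23 = unname(c23$mean[[tr]]),
      cell_biomass = bt,
      cell_biomass_sd = b23$sd[[tr]],
      net_yield = yield,
      net_yield_sd = if (is_ctrl) NA_real_ else
        sqrt(b23$sd[[tr]]^2 + bu_sd^2),
      assimilation_pct = pct_of_added_C(yield, const),
      o2_uptake = ot,
      o2_uptake_sd = if (tr %in% names(o2m$sd)) o2m$sd[[tr]] else NA_real_,
      net_C_respired = resp,
      net_C_respired_sd = if (is_ctrl) NA_real_ else
        sqrt(o2m$sd[[tr]]^2 + ou_sd^2) * const$respiratory_quotient,
      respired_pct = pct_of_added_C(resp, const),
      total_C_used = total,
      total_pct = pct_of_added_C(total, const),
      growth_efficiency = as.numeric(growth_efficiency(yield, total)),
      duplication_time = as.numeric(dup),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("budget_table", "data.frame")
  out
}
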