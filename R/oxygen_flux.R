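#' Geometry and transport properties of a gas-permeable incubation bag
#'
#' A sealed polyethylene bag holding sediment slurry exchanges oxygen with
#' fully oxygenated surrounding water by diffusion across the foil. The
#' volumetric conductance k' (per day) summarises how fast the bag
#' re-equilibrates: k' = D * A / (L * V).
#'
#' Foil area and thickness are experiment-specific; the defaults describe a
#' flat 50-mL bag with ~150 cm² of 50-µm foil and are placeholders to be
#' overridden with measured values.
#'
#' @param diffusion_coefficient oxygen diffusion coefficient of the foil,
#'   m² s⁻¹.
#' @param foil_thickness foil thickness, m.
#' @param foil_area total exchange area, m².
#' @param slurry_volume bag volume, mL.
#' @param ambient_O2 oxygen concentration of the surrounding water,
#'   µmol L⁻¹ (bags start air-saturated at this value).
#' @return object of class \code{bag_geometry} with derived
#'   \code{conductance} in day⁻¹.
#' @examples
#' bag_geometry()$conductance  # ~1.37 per day
#' @export
bag_geometry <- function(diffusion_coefficient = 2.65e-12,
                         foil_thickness = 5e-5,
                         foil_area = 0.015,
                         slurry_volume = 50,
                         ambient_O2 = 300) {
  vals <- c(diffusion_coefficient, foil_thickness, foil_area,
            slurry_volume, ambient_O2)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all bag geometry parameters must be finite and strictly positive")
  volume_m3 <- slurry_volume * 1e-6
  k_per_s <- diffusion_coefficient * foil_area / (foil_thickness * volume_m3)
  out <- list(diffusion_coefficient = diffusion_coefficient,
              foil_thickness = foil_thickness,
              foil_area = foil_area,
              slurry_volume = slurry_volume,
              ambient_O2 = ambient_O2,
              conductance = k_per_s * 86400)
  class(out) <- "bag_geometry"
  out
}

#' Oxygen concentration in a permeable bag under constant respiration
#'
#' Solves the bag oxygen balance dC/dt = k'(C_amb - C) - R for a bag that
#' starts air-saturated (C(0) = C_amb):
#' C(t) = C_amb - (R/k')(1 - exp(-k' t)).
#' As t grows the concentration approaches the steady state C_amb - R/k',
#' where diffusive influx balances respiration. Concentrations that would be
#' negative are floored at 0 and flagged anoxic (attribute \code{"anoxic"}).
#'
#' @param R volumetric respiration rate, µmol O2 per L slurry per day
#'   (non-negative).
#' @param geom a \code{\link{bag_geometry}}.
#' @param t time in days (vectorised).
#' @return oxygen concentration µmol L⁻¹ at time t, with logical attribute
#'   \code{anoxic} marking floored values.
#' @export
forward_bag_model <- function(R, geom = bag_geometry(), t) {
  stopifnot(inherits(geom, "bag_geometry"))
  if (any(R < 0)) stop("respiration rate must be non-negative")
  if (any(t < 0)) stop("time must be non-negative")
  k <- geom$conductance
  conc <- geom$ambient_O2 - (R / k) * (1 - exp(-k * t))
  anoxic <- conc < 0
  conc[anoxic] <- 0
  attr(conc, "anoxic") <- anoxic
  conc
}

#' Invert an end-point oxygen reading to a respiration rate
#'
#' At the end of a long incubation the bag is in steady state: respiration is
#' balanced by diffusive influx, so R = k'(C_amb - C_end). Readings above
#' ambient produce a negative rate with a warning and flag; a reading of 0
#' only bounds the rate from below (flag \code{"anoxia_limit"}).
#'
#' @param C_end measured end-point concentration, µmol L⁻¹ (vectorised).
#' @param geom a \code{\link{bag_geometry}}.
#' @return respiration rate, µmol O2 per L slurry per day, with attributes
#'   \code{supersaturated} and \code{anoxia_limit}.
#' @export
invert_respiration <- function(C_end, geom = bag_geometry()) {
  stopifnot(inherits(geom, "bag_geometry"))
  if (any(C_end < 0)) stop("oxygen concentration must be non-negative")
  R <- geom$conductance * (geom$ambient_O2 - C_end)
  super <- C_end > geom$ambient_O2
  if (any(super))
    warning("end-point above ambient oxygen: negative respiration reported")
  attr(R, "supersaturated") <- super
  attr(R, "anoxia_limit") <- C_end == 0
  R
}

#' Total oxygen uptake over the incubation, per mL undiluted sediment
#'
#' Converts a volumetric respiration rate (per L of slurry per day) into
#' total consumption over the incubation per mL of undiluted sediment:
#' the slurry contains 1/dilution_factor sediment by volume, so per-sediment
#' rates are the slurry rates times the dilution factor; the factor 1/1000
#' converts per-L to per-mL.
#'
#' @param R respiration, µmol O2 per L slurry per day.
#' @param duration incubation length, days.
#' @param dilution_factor slurry dilution (volume slurry per volume
#'   sediment).
#' @return µmol O2 per mL undiluted sediment over \code{duration}.
#' @export
integrated_uptake <- function(R, duration, dilution_factor = 3.5) {
  if (any(R < 0)) stop("respiration rate must be non-negative")
  stopifnot(duration >= 0, dilution_factor > 0)
  R * duration * dilution_factor / 1000
}

#' Per-bag respiration and per-treatment uptake from optode readings
#'
#' Applies the steady-state inversion to a table of end-point optode
#' readings and integrates to total per-sediment uptake, producing the
#' oxygen input needed by \code{\link{build_budget_table}}.
#'
#' @param readings data.frame with columns \code{sample}, \code{treatment},
#'   \code{o2_umol_per_l} (end-point concentration) and optionally
#'   \code{day}.
#' @param geom a \code{\link{bag_geometry}}.
#' @param duration incubation duration, days.
#' @param dilution_factor slurry dilution factor.
#' @return the readings with added columns \code{respiration_umol_l_day}
#'   and \code{o2_umol_per_ml} (total uptake per mL sediment).
#' @export
oxygen_uptake_table <- function(readings, geom = bag_geometry(),
                                duration = 23, dilution_factor = 3.5) {
  stopifnot(is.data.frame(readings))
  if (!all(c("treatment", "o2_umol_per_l") %in% names(readings)))
    stop("readings must have columns treatment and o2_umol_per_l")
  R <- invert_respiration(readings$o2_umol_per_l, geom)
  readings$respiration_umol_l_day <- as.numeric(R)
  readings$o2_umol_per_ml <- integrated_uptake(pmax(as.numeric(R), 0),
                                               duration, dilution_factor)
  readings
}
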