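#' Atom percent excess of 15N
#'
#' Measured 15N atom percent minus the natural abundance baseline
#' (0.36782%). Values below baseline (possible in unenriched controls
#' through measurement noise) are floored at zero with a warning.
#'
#' @param atom_percent measured 15N atom percent.
#' @param natural_abundance baseline atom percent (default 0.36782).
#' @return Atom percent excess (APE), same units.
#' @export
ape <- function(atom_percent, natural_abundance = 0.36782) {
  .check_positive(atom_percent, "atom_percent", strict = FALSE)
  out <- atom_percent - natural_abundance
  if (any(out < 0)) {
    warning("atom percent below natural abundance; APE floored at 0")
    out[out < 0] <- 0
  }
  out
}

#' N2 fixed per plant fraction from 15N enrichment
#'
#' For one plant fraction (shoot, root or nodule) incubated under a
#' `gas_fraction_15N2` atmosphere of 15N2, the classical working formula is
#' `(APE/100) * total_N * 5/4` at 20% gas; the correction factor scales as
#' `1/(4 * gas_fraction)`, i.e. inversely with the labeled-gas fraction.
#' `mode = "literal"` (default) returns exactly that quantity;
#' `mode = "strict"` additionally divides by the incubation time, making
#' the time normalization explicit and auditable rather than folded into
#' the constant.
#'
#' @param atom_percent measured 15N atom percent of the fraction.
#' @param total_N_ug total nitrogen in the fraction, micrograms.
#' @param gas_fraction_15N2 fraction of 15N2 in the incubation headspace
#'   (default 0.20).
#' @param incubation_h incubation time in hours (default 2; used in strict
#'   mode only).
#' @param mode `"literal"` or `"strict"`.
#' @return micrograms N fixed per hour.
#' @export
n2_fixed_per_fraction <- function(atom_percent, total_N_ug,
                                  gas_fraction_15N2 = 0.20,
                                  incubation_h = 2,
                                  mode = c("literal", "strict")) {
  mode <- match.arg(mode)
  if (any(gas_fraction_15N2 <= 0 | gas_fraction_15N2 > 1)) {
    stop("gas_fraction_15N2 must be in (0, 1]", call. = FALSE)
  }
  .check_positive(total_N_ug, "total_N_ug", strict = FALSE)
  out <- (ape(atom_percent) / 100) * total_N_ug / (4 * gas_fraction_15N2)
  if (mode == "strict") {
    .check_positive(incubation_h, "incubation_h")
    out <- out / incubation_h
  }
  out
}

#' Whole-plant N2 fixation rate
#'
#' Sums the per-fraction fixed-N rates of one plant (shoot + root + nodule)
#' and optionally converts micrograms N to micromoles of N2 using the
#' 28.0134 g/mol molar mass of dinitrogen.
#'
#' @param fractions data.frame with columns `fraction`, `atom_percent`,
#'   `total_N_ug` (one row per plant fraction; labels must be unique).
#' @param molar if `TRUE` (default) return umol N2/h, otherwise ug N/h.
#' @param ... passed to [n2_fixed_per_fraction()] (`mode`,
#'   `gas_fraction_15N2`, `incubation_h`).
#' @return Plant-level fixation rate.
#' @export
plant_fixation_rate <- function(fractions, molar = TRUE, ...) {
  needed <- c("fraction", "atom_percent", "total_N_ug")
  miss <- setdiff(needed, names(fractions))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(fractions) < 1) stop("need at least one fraction", call. = FALSE)
  if (anyDuplicated(fractions$fraction)) {
    stop("duplicate fraction labels", call. = FALSE)
  }
  ug_per_h <- sum(n2_fixed_per_fraction(fractions$atom_percent,
                                        fractions$total_N_ug, ...))
  if (molar) ug_per_h / unit_registry$N2_molar_mass else ug_per_h
}

#' Acetylene reduction rate
#'
#' Ethylene produced over the incubation, as umol C2H4/h.
#'
#' @param ethylene_nmol nmol ethylene produced.
#' @param incubation_h incubation time, hours (default 1).
#' @return umol C2H4/h.
#' @export
ara_rate <- function(ethylene_nmol, incubation_h = 1) {
  .check_positive(ethylene_nmol, "ethylene_nmol", strict = FALSE)
  .check_positive(incubation_h, "incubation_h")
  (ethylene_nmol / 1000) / incubation_h
}

#' Normalize a plant-level rate across the eight physiological scales
#'
#' Expresses one rate (umol/h/plant, from acetylene reduction or 15N2
#' fixation) per plant, per gram shoot dry weight, per nodule volume, per
#' nodule dry mass, per infected nodule volume, per bacteroid, per pg
#' bacteroid protein, and per um^3 bacteroid volume. All conversions use
#' exact factors, so the cascade identities hold to machine precision:
#' `per_bacteroid = per_bacteroid_volume * bacteroid_volume` and
#' `per_bacteroid_protein = per_bacteroid / protein_per_bacteroid`.
#'
#' @param rate_per_plant umol/h/plant.
#' @param sdw_g shoot dry weight per plant, g.
#' @param nodule_volume_cm3 total nodule volume per plant, cm^3.
#' @param nodule_dry_mass_ug total nodule dry mass per plant, ug.
#' @param infected_volume_mm3 total infected nodule volume per plant, mm^3.
#' @param bacteroid_count bacteroids per plant.
#' @param protein_per_bacteroid_pg pg protein per bacteroid.
#' @param bacteroid_volume_um3 mean bacteroid volume, um^3.
#' @return Named list: `per_plant` (umol/h), `per_g_SDW` (umol/h/g),
#'   `per_nodule_volume` (umol/h/cm^3), `per_nodule_dry_mass` (nmol/h/ug),
#'   `per_infected_volume` (nmol/h/mm^3), `per_bacteroid` (amol/h),
#'   `per_bacteroid_protein` (amol/h/pg), `per_bacteroid_volume`
#'   (amol/h/um^3).
#' @export
normalize_rate <- function(rate_per_plant, sdw_g, nodule_volume_cm3,
                           nodule_dry_mass_ug, infected_volume_mm3,
                           bacteroid_count, protein_per_bacteroid_pg,
                           bacteroid_volume_um3) {
  .check_positive(rate_per_plant, "rate_per_plant", strict = FALSE)
  for (nm in c("sdw_g", "nodule_volume_cm3", "nodule_dry_mass_ug",
               "infected_volume_mm3", "bacteroid_count",
               "protein_per_bacteroid_pg", "bacteroid_volume_um3")) {
    .check_positive(get(nm), nm)
  }
  u <- unit_registry
  per_bacteroid <- rate_per_plant * u$umol_to_amol / bacteroid_count
  list(
    per_plant            = rate_per_plant,
    per_g_SDW            = rate_per_plant / sdw_g,
    per_nodule_volume    = rate_per_plant / nodule_volume_cm3,
    per_nodule_dry_mass  = rate_per_plant * u$umol_to_nmol / nodule_dry_mass_ug,
    per_infected_volume  = rate_per_plant * u$umol_to_nmol / infected_volume_mm3,
    per_bacteroid        = per_bacteroid,
    per_bacteroid_protein = per_bacteroid / protein_per_bacteroid_pg,
    per_bacteroid_volume = per_bacteroid / bacteroid_volume_um3
  )
}
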