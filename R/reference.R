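#' Published reference means for the bean and pea symbioses
#'
#' Cohort means and standard errors for *Phaseolus vulgaris* (bean, strain
#' Rlp4292) and *Pisum sativum* (pea, strain RlvA34) harvested at flowering:
#' plant biomass and nodulation, nodule geometry and infection, bacteroid
#' morphology and packing from volume electron microscopy, bacteroid protein,
#' and acetylene-reduction / 15N2-fixation rates. These values parameterize
#' the default synthetic ground truth and serve as zero-noise inputs for the
#' derived-row closure of the comparison table.
#'
#' Sample sizes follow the published cohort design: 11 plants per host for
#' plant/nodule and acetylene-reduction rows, 8 nodules for infection and
#' packing, 240 (bean) / 246 (pea) bacteroids for morphology, 6 isolations
#' for bacteroid protein, 9/10 plants for 15N2 fixation.
#'
#' @return A data.frame with columns `parameter`, `unit`, `bean_mean`,
#'   `bean_se`, `pea_mean`, `pea_se`, `n_bean`, `n_pea`.
#' @export
#' @examples
#' ref <- reference_means()
#' ref[ref$parameter == "nodule_density", ]
reference_means <- function() {
  r <- function(parameter, unit, bm, bs, pm, ps, nb, np) {
    data.frame(parameter = parameter, unit = unit,
               bean_mean = bm, bean_se = bs, pea_mean = pm, pea_se = ps,
               n_bean = nb, n_pea = np, stringsAsFactors = FALSE)
  }
  do.call(rbind, list(
    r("shoot_dry_mass",            "mg/plant",          610,    50.2,  321,    33.2,  11, 11),
    r("plant_nodule_fresh_mass",   "mg/plant",          1445.3, 94.8,  251.40, 13.35, 11, 11),
    r("plant_nodule_dry_mass",     "mg/plant",          81.8,   9.4,   17.3,   1.85,  11, 11),
    r("nodule_number",             "nodules/plant",     125,    10.3,  88.6,   4.18,  11, 11),
    r("nodule_fresh_mass",         "mg/nodule",         5.54,   0.70,  2.56,   0.19,  11, 11),
    r("nodule_dry_mass",           "ug/nodule",         642,    25.1,  195,    18.4,  11, 11),
    r("plant_nodule_volume",       "mm3/plant",         709,    43,    400,    6.9,   11, 11),
    r("mean_nodule_volume",        "mm3/nodule",        6.07,   0.48,  4.61,   0.22,  11, 11),
    r("nodule_density",            "mg/cm3",            115,    13.3,  43.2,   4.64,  11, 11),
    r("ara_per_plant",             "umol/h/plant",      3.31,   0.39,  1.92,   0.20,  11, 11),
    r("ara_per_g_sdw",             "umol/h/g",          5.28,   0.25,  6.00,   0.13,  11, 11),
    r("ara_per_nodule_volume",     "umol/h/cm3",        4.67,   0.56,  4.81,   0.50,  11, 11),
    r("ara_per_nodule_dry_mass",   "nmol/h/ug",         40.7,   2.60,  124,    16.7,  11, 11),
    r("calculated_nodule_volume",  "mm3/nodule",        5.40,   1.45,  5.16,   0.59,  8,  8),
    r("infected_nodule_volume",    "mm3/nodule",        1.36,   0.40,  1.41,   0.23,  8,  8),
    r("proportion_infected",       "%",                 24.2,   1.52,  26.2,   2.19,  8,  8),
    r("bacteroid_volume",          "um3/bacteroid",     0.93,   0.02,  4.50,   0.09,  240, 246),
    r("bacteroid_surface_area",    "um2/bacteroid",     6.73,   0.14,  21.1,   0.36,  240, 246),
    r("bacteroid_sa_v",            "1/um",              7.44,   0.06,  4.78,   0.03,  240, 246),
    r("packing_fraction",          "%",                 36,     0.9,   52,     2.3,   6,  6),
    r("total_bacteroid_volume",    "mm3/nodule",        0.49,   0.14,  0.73,   0.12,  8,  8),
    r("protein_per_bacteroid",     "pg/bacteroid",      0.32,   0.02,  0.62,   0.03,  6,  6),
    r("bacteroids_per_nodule",     "1e8/nodule",        5.28,   1.56,  1.63,   0.26,  8,  8),
    r("protein_density_bacteroid", "pg/um3",            0.34,   0.02,  0.14,   0.01,  6,  6),
    r("protein_density_nodule",    "ug/mm3",            340,    20.5,  137,    6.53,  6,  6),
    r("fix_per_plant",             "umol/h/plant",      1.89,   0.22,  0.58,   0.05,  9,  10),
    r("fix_per_g_sdw",             "umol/h/g",          1.33,   0.11,  1.07,   0.12,  9,  10),
    r("fix_per_nodule_dry_mass",   "umol/h/ug",         9.76,   0.76,  15.6,   1.26,  9,  10),
    r("fix_per_nodule_volume",     "umol/h/cm3",        1.22,   0.14,  1.12,   0.09,  9,  10),
    r("fix_per_infected_volume",   "nmol/h/mm3",        5.15,   0.66,  4.10,   0.30,  9,  10),
    r("fix_per_bacteroid",         "amol/h",            13.3,   1.70,  35.4,   2.57,  9,  10),
    r("fix_per_bacteroid_protein", "amol/h/pg",         42.2,   5.4,   56.8,   4.1,   9,  10),
    r("fix_per_bacteroid_volume",  "amol/h/um3",        14.4,   1.83,  7.87,   0.57,  9,  10)
  ))
}

#' Published per-bacteroid fold changes for selected proteins (pea/bean)
#'
#' Per-bacteroid abundance fold changes (RlvA34 pea over Rlp4292 bean) for
#' nitrogenase, electron-transfer, ATP synthase, and dicarboxylate/TCA-cycle
#' proteins, used to exercise the scale-cascade arithmetic: fold changes at
#' the other four scales follow from these by exact constant ratios.
#'
#' @return data.frame with `locus_tag`, `protein`, `fc_per_bacteroid`.
#' @export
reference_protein_folds <- function() {
  data.frame(
    locus_tag = c("RHLv8088", "RHLv8087", "RHLv8086", "RHLv8128", "RHLv8126",
                  "RHL3232", "RHL3230", "RHL1472", "RHL3264", "RHL3615",
                  "RHL1075", "RHL3358", "RHL1435", "RHL3260", "RHL3258",
                  "RHL3263"),
    protein = c("NifH", "NifD", "NifK", "FixA", "FixC", "AtpA", "AtpD",
                "Dme", "Mdh", "PckA", "GltA", "AcnA", "Icd", "SucA",
                "SucB", "SucC"),
    fc_per_bacteroid = c(5.49, 6.42, 16.75, 4.99, 2.64, 3.88, 3.28,
                         3.24, 9.44, 1.43, 21.19, 16.86, 6.42, 13.39,
                         10.28, 8.93),
    stringsAsFactors = FALSE
  )
}
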