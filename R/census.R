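#' Summarize bacteroid morphology from 3-D segmentation
#'
#' Mean volume, surface area and surface-area:volume ratio over a set of
#' individually segmented bacteroids. The SA:V ratio is the mean of the
#' per-bacteroid ratios, not the ratio of the means: the two differ whenever
#' volumes vary, and the per-bacteroid convention matches how cohort
#' morphology tables are assembled.
#'
#' @param segs data.frame with columns `volume_um3` and `surface_um2`
#'   (one row per segmented bacteroid).
#' @return list with `mean_volume`, `se_volume`, `mean_surface`,
#'   `se_surface`, `mean_sa_v`, `se_sa_v`, `n`.
#' @export
summarize_morphology <- function(segs) {
  if (!is.data.frame(segs) || nrow(segs) < 1) {
    stop("need at least one segmentation record", call. = FALSE)
  }
  needed <- c("volume_um3", "surface_um2")
  miss <- setdiff(needed, names(segs))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  .check_positive(segs$volume_um3, "volume_um3")
  .check_positive(segs$surface_um2, "surface_um2")
  se <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0
  sav <- segs$surface_um2 / segs$volume_um3
  list(mean_volume = mean(segs$volume_um3), se_volume = se(segs$volume_um3),
       mean_surface = mean(segs$surface_um2), se_surface = se(segs$surface_um2),
       mean_sa_v = mean(sav), se_sa_v = se(sav),
       n = nrow(segs))
}

#' Bacteroid packing fraction from defined subvolumes
#'
#' Fraction of infected plant-cell volume occupied by bacteroids, averaged
#' over sampled subvolumes (typically 8 x 8 x 2 um blocks in which every
#' bacteroid was segmented).
#'
#' @param samples data.frame with columns `X_um`, `Y_um`, `Z_um` (subvolume
#'   dimensions) and `occupied_um3` (total segmented bacteroid volume).
#' @return Mean occupied fraction in `[0, 1]`.
#' @export
packing_fraction <- function(samples) {
  needed <- c("X_um", "Y_um", "Z_um", "occupied_um3")
  miss <- setdiff(needed, names(samples))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(samples) < 1) stop("need at least one packing sample", call. = FALSE)
  total <- samples$X_um * samples$Y_um * samples$Z_um
  .check_positive(total, "subvolume")
  .check_positive(samples$occupied_um3, "occupied_um3", strict = FALSE)
  if (any(samples$occupied_um3 > total)) {
    stop("occupied volume exceeds subvolume", call. = FALSE)
  }
  mean(samples$occupied_um3 / total)
}

#' Total bacteroid volume in a nodule
#'
#' The infected volume of a nodule times the packing fraction of its infected
#' cells gives the volume actually occupied by bacteroids.
#'
#' @param V_i infected nodule volume, mm^3.
#' @param packing packing fraction in `[0, 1]`.
#' @return mm^3 of bacteroid per nodule.
#' @export
total_bacteroid_volume <- function(V_i, packing) {
  .check_positive(V_i, "V_i", strict = FALSE)
  if (any(packing < 0 | packing > 1)) stop("packing must be in [0, 1]", call. = FALSE)
  V_i * packing
}

#' Number of bacteroids per nodule
#'
#' Total bacteroid volume (mm^3) divided by the mean single-bacteroid volume
#' (um^3), with the exact 1e9 um^3/mm^3 conversion.
#'
#' @param total_volume_mm3 total bacteroid volume per nodule, mm^3.
#' @param mean_volume_um3 mean volume of one bacteroid, um^3.
#' @return Count of bacteroids per nodule.
#' @export
#' @examples
#' bacteroids_per_nodule(0.49, 0.93)  # ~5.3e8
bacteroids_per_nodule <- function(total_volume_mm3, mean_volume_um3) {
  .check_positive(total_volume_mm3, "total_volume_mm3", strict = FALSE)
  .check_positive(mean_volume_um3, "mean_volume_um3")
  total_volume_mm3 * unit_registry$mm3_to_um3 / mean_volume_um3
}

#' Protein density of a bacteroid
#'
#' @param protein_per_bacteroid_pg protein content, pg/bacteroid.
#' @param mean_volume_um3 bacteroid volume, um^3.
#' @return pg protein per um^3 bacteroid.
#' @export
protein_density <- function(protein_per_bacteroid_pg, mean_volume_um3) {
  .check_positive(protein_per_bacteroid_pg, "protein_per_bacteroid_pg")
  .check_positive(mean_volume_um3, "mean_volume_um3")
  protein_per_bacteroid_pg / mean_volume_um3
}

#' Enumerate labeled bacteroids from flow-cytometry events
#'
#' Applies the standard gating sequence to an event table: forward scatter
#' strictly above `fsc_min` and side-scatter aspect ratio strictly above
#' `aspect_min` define singlets; fluorescence strictly above `yellow_min`
#' defines the labeled ("yellow") population. All gates are strict
#' inequalities, so boundary events are excluded. Returns the labeled-event
#' concentration.
#'
#' @param events data.frame with columns `FSC`, `SSC_aspect_ratio`,
#'   `FI_yellow`.
#' @param volume_analyzed_ul volume of sample analyzed, microlitres.
#' @param fsc_min,aspect_min,yellow_min gate thresholds (defaults 0, 0.4,
#'   3000).
#' @return list with `yellow_events`, `singlet_events`, `total_events`,
#'   `events_per_ml`.
#' @export
count_bacteroids_flow <- function(events, volume_analyzed_ul,
                                  fsc_min = 0, aspect_min = 0.4,
                                  yellow_min = 3000) {
  needed <- c("FSC", "SSC_aspect_ratio", "FI_yellow")
  miss <- setdiff(needed, names(events))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  .check_positive(volume_analyzed_ul, "volume_analyzed_ul")
  singlet <- events$FSC > fsc_min & events$SSC_aspect_ratio > aspect_min
  yellow <- singlet & events$FI_yellow > yellow_min
  list(yellow_events = sum(yellow),
       singlet_events = sum(singlet),
       total_events = nrow(events),
       events_per_ml = sum(yellow) / (volume_analyzed_ul / 1000))
}

#' Full bacteroid census for one host
#'
#' Combines segmentation morphology, packing samples and geometry into the
#' cohort summary: mean morphology, packing fraction, total bacteroid volume,
#' bacteroids per nodule, and protein densities.
#'
#' @param segs segmentation data.frame (see [summarize_morphology()]).
#' @param packing_samples packing data.frame (see [packing_fraction()]).
#' @param V_i mean infected nodule volume, mm^3.
#' @param protein_per_bacteroid_pg protein content, pg/bacteroid (optional).
#' @return list of census quantities.
#' @export
bacteroid_census <- function(segs, packing_samples, V_i,
                             protein_per_bacteroid_pg = NULL) {
  morph <- summarize_morphology(segs)
  pf <- packing_fraction(packing_samples)
  tot <- total_bacteroid_volume(V_i, pf)
  out <- c(morph, list(
    packing_fraction = pf,
    total_bacteroid_volume = tot,
    bacteroids_per_nodule = bacteroids_per_nodule(tot, morph$mean_volume)
  ))
  if (!is.null(protein_per_bacteroid_pg)) {
    out$protein_per_bacteroid <- protein_per_bacteroid_pg
    out$protein_density <- protein_density(protein_per_bacteroid_pg,
                                           morph$mean_volume)
  }
  out
}
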