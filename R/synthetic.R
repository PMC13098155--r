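#' Ground-truth parameter set for one host
#'
#' Bundles the per-host means and coefficients of variation from which every
#' synthetic measurement table is drawn. Continuous quantities use a
#' lognormal noise model (strictly positive measurements); counts are
#' Poisson. A CV of zero makes the corresponding draw degenerate at the
#' mean, which is what the zero-noise round-trip tests rely on.
#'
#' @param host `"bean"` or `"pea"`.
#' @param means named list of positive means: `shoot_dry_mass_mg`,
#'   `nodule_count`, `nodule_fresh_mass_mg` and `nodule_dry_mass_mg` (per
#'   plant), `plant_nodule_volume_mm3`, `section_nodule_volume_mm3` (per
#'   nodule, as recovered from sections), `infected_fraction`,
#'   `colonization_density`, `packing_fraction`, `bacteroid_volume_um3`,
#'   `bacteroid_surface_um2`, `protein_per_bacteroid_pg`,
#'   `fixation_per_plant_umol_h`, `ara_per_plant_umol_h`.
#' @param cv named list of coefficients of variation (>= 0) for the same
#'   fields (fractions and counts have their own handling).
#' @return A `ground_truth` list.
#' @export
ground_truth <- function(host, means, cv) {
  stopifnot(host %in% c("bean", "pea"))
  for (nm in names(means)) .check_positive(means[[nm]], nm)
  if (means$infected_fraction >= 1 || means$colonization_density > 1 ||
      means$packing_fraction >= 1) {
    stop("fractions must lie in (0, 1)", call. = FALSE)
  }
  if (any(unlist(cv) < 0)) stop("CVs must be >= 0", call. = FALSE)
  structure(list(host = host, means = means, cv = cv),
            class = "ground_truth")
}

#' Default ground truth for both hosts
#'
#' Parameterized from the published cohort means (see [reference_means()]),
#' with CVs recovered from the published standard errors and sample sizes
#' (`cv = se * sqrt(n) / mean`). The colonization density `f_c` (infected
#' area per infected-zone area) is not published; defaults of 0.65 (bean)
#' and 0.80 (pea) reflect the denser colonization of indeterminate nodules
#' and cancel out of every downstream identity.
#'
#' @param protein_panel a data.frame describing the protein panel for the
#'   synthetic peptide tables; default [default_protein_panel()].
#' @return list with elements `bean`, `pea` (each a [ground_truth()]) and
#'   `protein_panel`.
#' @export
default_ground_truth <- function(protein_panel = default_protein_panel()) {
  ref <- reference_means()
  g <- function(p, col) ref[ref$parameter == p, col]
  mk <- function(host) {
    mcol <- paste0(host, "_mean"); scol <- paste0(host, "_se")
    ncol <- paste0("n_", host)
    v <- function(p) g(p, mcol)
    cv_of <- function(p) g(p, scol) * sqrt(g(p, ncol)) / g(p, mcol)
    means <- list(
      shoot_dry_mass_mg        = v("shoot_dry_mass"),
      nodule_count             = v("nodule_number"),
      nodule_fresh_mass_mg     = v("plant_nodule_fresh_mass"),
      nodule_dry_mass_mg       = v("plant_nodule_dry_mass"),
      plant_nodule_volume_mm3  = v("plant_nodule_volume"),
      section_nodule_volume_mm3 = v("calculated_nodule_volume"),
      infected_fraction        = v("proportion_infected") / 100,
      colonization_density     = if (host == "bean") 0.65 else 0.80,
      packing_fraction         = v("packing_fraction") / 100,
      bacteroid_volume_um3     = v("bacteroid_volume"),
      bacteroid_surface_um2    = v("bacteroid_surface_area"),
      protein_per_bacteroid_pg = v("protein_per_bacteroid"),
      fixation_per_plant_umol_h = v("fix_per_plant"),
      ara_per_plant_umol_h     = v("ara_per_plant")
    )
    cv <- list(
      shoot_dry_mass_mg        = cv_of("shoot_dry_mass"),
      nodule_fresh_mass_mg     = cv_of("plant_nodule_fresh_mass"),
      nodule_dry_mass_mg       = cv_of("plant_nodule_dry_mass"),
      plant_nodule_volume_mm3  = cv_of("plant_nodule_volume"),
      section_nodule_volume_mm3 = cv_of("calculated_nodule_volume"),
      infected_fraction        = cv_of("proportion_infected"),
      packing_fraction         = cv_of("packing_fraction"),
      bacteroid_volume_um3     = cv_of("bacteroid_volume"),
      bacteroid_shape          = 0.10,
      protein_per_bacteroid_pg = cv_of("protein_per_bacteroid"),
      fixation_per_plant_umol_h = cv_of("fix_per_plant"),
      ara_per_plant_umol_h     = cv_of("ara_per_plant")
    )
    ground_truth(host, means, cv)
  }
  list(bean = mk("bean"), pea = mk("pea"), protein_panel = protein_panel)
}

#' Default synthetic protein panel
#'
#' One row per protein with true copies per bacteroid in each host. Bean
#' copy numbers are plausible bacteroid abundances; pea copies are bean
#' copies times the published per-bacteroid fold change, so planted fold
#' changes are recoverable ground truth.
#'
#' @return data.frame with `protein`, `copies_bean`, `copies_pea`,
#'   `mw_kda`, `n_peptides`.
#' @export
default_protein_panel <- function() {
  folds <- reference_protein_folds()
  copies_bean <- c(32000, 21000, 20500, 15000, 4200, 26000, 24000,
                   9000, 6000, 21000, 3000, 3500, 8000, 2500, 2600, 4200)
  data.frame(
    protein = folds$protein,
    copies_bean = copies_bean,
    copies_pea = copies_bean * folds$fc_per_bacteroid,
    mw_kda = c(32.7, 55.3, 59.7, 28.3, 47.9, 55.1, 50.5, 84.1, 34.9,
               59.0, 48.2, 97.5, 45.9, 105.1, 43.5, 41.4),
    n_peptides = 4L,
    stringsAsFactors = FALSE
  )
}

# internal: lognormal draw with exact target mean; degenerate at cv = 0
.rlnorm_mean <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a per-plant measurement table
#'
#' One row per plant with biomass, nodulation, acetylene-reduction and
#' 15N2-assay readings drawn from the ground-truth lognormal model
#' (Poisson for nodule counts; deterministic `round(mean)` when all CVs are
#' zero, so the zero-noise table is exactly reproducible). Isotope columns
#' are constructed so that [plant_fixation_rate()] (literal mode, molar)
#' recovers the plant's sampled fixation rate exactly: the plant rate is
#' split over shoot/root/nodule fractions (55/15/30%), fraction nitrogen
#' pools follow tissue mass, and atom percent is back-computed from the
#' fraction rate.
#'
#' @param gt a [ground_truth()].
#' @param n_plants number of plants (>= 2).
#' @param seed integer seed.
#' @param gas_fraction_15N2 15N2 fraction of the incubation headspace.
#' @return data.frame, one row per plant.
#' @export
generate_plants <- function(gt, n_plants = 11, seed = 1,
                            gas_fraction_15N2 = 0.20) {
  if (n_plants < 2) stop("n_plants must be >= 2", call. = FALSE)
  set.seed(seed)
  m <- gt$means; cv <- gt$cv
  zero_noise <- all(unlist(cv) == 0)
  shoot <- .rlnorm_mean(n_plants, m$shoot_dry_mass_mg, cv$shoot_dry_mass_mg)
  count <- if (zero_noise) rep(round(m$nodule_count), n_plants) else
    stats::rpois(n_plants, m$nodule_count)
  fix <- .rlnorm_mean(n_plants, m$fixation_per_plant_umol_h,
                      cv$fixation_per_plant_umol_h)
  ara <- .rlnorm_mean(n_plants, m$ara_per_plant_umol_h,
                      cv$ara_per_plant_umol_h)
  nod_dry <- .rlnorm_mean(n_plants, m$nodule_dry_mass_mg, cv$nodule_dry_mass_mg)
  # fraction nitrogen pools: ~4% N in shoot dry matter, roots half the
  # shoot mass at 2% N, nodules 6% N
  totN <- cbind(shoot = shoot * 1000 * 0.04,
                root = shoot * 0.5 * 1000 * 0.02,
                nodule = nod_dry * 1000 * 0.06)
  share <- c(shoot = 0.55, root = 0.15, nodule = 0.30)
  # invert the literal-mode formula:
  # APE = ug N/h * 100 * 4 * gas_fraction / totN
  atom <- sapply(names(share), function(fr) {
    ug_h <- fix * unit_registry$N2_molar_mass * share[[fr]]
    0.36782 + ug_h * 100 * 4 * gas_fraction_15N2 / totN[, fr]
  })
  data.frame(
    plant_id = paste0(gt$host, "_p", seq_len(n_plants)),
    host = gt$host,
    shoot_dry_mass_mg = shoot,
    nodule_count = count,
    nodule_fresh_mass_mg = .rlnorm_mean(n_plants, m$nodule_fresh_mass_mg,
                                        cv$nodule_fresh_mass_mg),
    nodule_dry_mass_mg = nod_dry,
    plant_nodule_volume_mm3 = .rlnorm_mean(n_plants, m$plant_nodule_volume_mm3,
                                           cv$plant_nodule_volume_mm3),
    ethylene_nmol = ara * 1000,
    ara_incubation_h = 1,
    shoot_atom_pct = atom[, "shoot"], shoot_total_N_ug = totN[, "shoot"],
    root_atom_pct = atom[, "root"], root_total_N_ug = totN[, "root"],
    nodule_atom_pct = atom[, "nodule"], nodule_total_N_ug = totN[, "nodule"],
    stringsAsFactors = FALSE
  )
}

# internal: cap height for target cap volume at base radius a
# (pi h (3 a^2 + h^2) / 6 is strictly increasing in h)
.cap_height <- function(V_c, a) {
  stats::uniroot(function(h) (pi * h / 6) * (3 * a^2 + h^2) - V_c,
                 lower = 1e-9, upper = 10 * a + (6 * V_c / pi)^(1/3),
                 tol = 1e-12)$root
}

#' Generate section-measurement tables
#'
#' Draws per-nodule whole volumes from the ground truth and constructs 2-D
#' section measurements that are exactly geometrically consistent with the
#' drawn solid, so the geometry module inverts them without error:
#'
#' * bean: a sphere of the drawn volume gives `A = pi r^2`, Feret diameters
#'   `2r`; the infected zone is a smaller concentric sphere holding
#'   `infected_fraction / f_c` of the nodule volume; `A_i = f_c * A_iz`.
#' * pea: 8% of the volume forms a spherical cap (base radius equal to the
#'   body radius), the rest a cylinder of aspect ratio length = 6 radius;
#'   the infected zone is an inner cylinder spanning 90% of the body length.
#'
#' @param gt a [ground_truth()].
#' @param n_nodules number of sectioned nodules.
#' @param seed integer seed.
#' @return data.frame of section measurements for the host's model.
#' @export
generate_sections <- function(gt, n_nodules = 8, seed = 1) {
  if (n_nodules < 1) stop("n_nodules must be >= 1", call. = FALSE)
  set.seed(seed)
  m <- gt$means
  V <- .rlnorm_mean(n_nodules, m$section_nodule_volume_mm3,
                    gt$cv$section_nodule_volume_mm3)
  f_i <- m$infected_fraction
  f_c <- m$colonization_density
  V_iz <- V * f_i / f_c
  if (gt$host == "bean") {
    r <- (3 * V / (4 * pi))^(1/3)
    r_iz <- (3 * V_iz / (4 * pi))^(1/3)
    A_iz <- pi * r_iz^2
    data.frame(
      nodule_id = paste0("bean_n", seq_len(n_nodules)),
      A_nod = pi * r^2, F_dmax = 2 * r, F_dmin = 2 * r,
      A_iz = A_iz, F_dmax_iz = 2 * r_iz, F_dmin_iz = 2 * r_iz,
      A_i = f_c * A_iz, stringsAsFactors = FALSE
    )
  } else {
    cap_frac <- 0.08
    V_b <- (1 - cap_frac) * V
    rho <- (V_b / (6 * pi))^(1/3)   # length L = 6 rho
    L <- 6 * rho
    h <- mapply(.cap_height, cap_frac * V, rho)
    l_iz <- 0.9 * L
    rho_iz <- sqrt(V_iz / (pi * l_iz))
    A_iz <- 2 * rho_iz * l_iz
    data.frame(
      nodule_id = paste0("pea_n", seq_len(n_nodules)),
      c = 2 * rho, h = h, A_body = 2 * rho * L, l_c = L,
      A_iz = A_iz, l_iz = l_iz, A_i = f_c * A_iz,
      stringsAsFactors = FALSE
    )
  }
}

#' Generate a per-bacteroid segmentation table
#'
#' Volumes are lognormal around the ground-truth mean. Surface areas are
#' built as `shape * (36 pi V^2)^(1/3)` — the sphere-minimum surface for the
#' drawn volume times a shape factor >= 1 — so the isoperimetric inequality
#' holds for every record and the expected cohort mean surface equals the
#' ground-truth mean (the lognormal moment `E[V^(2/3)]` is corrected
#' analytically).
#'
#' @param gt a [ground_truth()].
#' @param n_bacteroids number of segmented bacteroids.
#' @param seed integer seed.
#' @param dataset_id label for the source volume (default host name).
#' @return data.frame with `bacteroid_id`, `volume_um3`, `surface_um2`,
#'   `host`, `dataset_id`.
#' @export
generate_segmentation <- function(gt, n_bacteroids = 240, seed = 1,
                                  dataset_id = gt$host) {
  if (n_bacteroids < 1) stop("n_bacteroids must be >= 1", call. = FALSE)
  set.seed(seed)
  m <- gt$means; cv <- gt$cv
  V <- .rlnorm_mean(n_bacteroids, m$bacteroid_volume_um3, cv$bacteroid_volume_um3)
  sphere_sa <- (36 * pi * V^2)^(1/3)
  sdlog2 <- log(1 + cv$bacteroid_volume_um3^2)
  # E[V^(2/3)] = mean^(2/3) * exp(-(1/9) sdlog^2) for the lognormal
  e_sa_sphere <- (36 * pi)^(1/3) * m$bacteroid_volume_um3^(2/3) *
    exp(-sdlog2 / 9)
  shape_mean <- m$bacteroid_surface_um2 / e_sa_sphere
  shape <- pmax(.rlnorm_mean(n_bacteroids, shape_mean, cv$bacteroid_shape), 1)
  data.frame(
    bacteroid_id = paste0(dataset_id, "_b", seq_len(n_bacteroids)),
    volume_um3 = V,
    surface_um2 = shape * sphere_sa,
    host = gt$host,
    dataset_id = dataset_id,
    stringsAsFactors = FALSE
  )
}

#' Generate packing subvolume samples
#'
#' Occupied bacteroid volume inside 8 x 8 x 2 um blocks, lognormal around
#' the ground-truth packing fraction (clipped below full occupancy).
#'
#' @param gt a [ground_truth()].
#' @param n_samples number of subvolumes.
#' @param seed integer seed.
#' @param dims subvolume dimensions in um, `c(X, Y, Z)`.
#' @return data.frame with `sample_id`, `X_um`, `Y_um`, `Z_um`,
#'   `occupied_um3`, `host`.
#' @export
generate_packing <- function(gt, n_samples = 6, seed = 1, dims = c(8, 8, 2)) {
  if (n_samples < 1) stop("n_samples must be >= 1", call. = FALSE)
  set.seed(seed)
  frac <- pmin(.rlnorm_mean(n_samples, gt$means$packing_fraction,
                            gt$cv$packing_fraction), 0.999)
  total <- prod(dims)
  data.frame(
    sample_id = paste0(gt$host, "_pk", seq_len(n_samples)),
    X_um = dims[1], Y_um = dims[2], Z_um = dims[3],
    occupied_um3 = frac * total,
    host = gt$host, stringsAsFactors = FALSE
  )
}

#' Generate a flow-cytometry event table with planted truth
#'
#' Events carry `FSC`, `SSC`, `SSC_aspect_ratio` and `FI_yellow` columns.
#' The labeled population (aspect ratio in (0.6, 1), fluorescence well above
#' the 3,000 FI gate) is planted at a known concentration; a dim unlabeled
#' contaminant population and an aggregate ("doublet") population with
#' aspect ratio below 0.4 are added so the gating rules have something to
#' reject.
#'
#' @param labeled_per_ml true labeled-cell concentration, events/ml.
#' @param volume_ul analyzed volume in microlitres.
#' @param dim_fraction contaminant events as a fraction of labeled events.
#' @param doublet_fraction aggregate events as a fraction of labeled events.
#' @param seed integer seed.
#' @return list with `events` (data.frame) and `volume_ul`.
#' @export
generate_flow_events <- function(labeled_per_ml = 1e6, volume_ul = 20,
                                 dim_fraction = 0.2, doublet_fraction = 0.05,
                                 seed = 1) {
  set.seed(seed)
  n_lab <- round(labeled_per_ml * volume_ul / 1000)
  n_dim <- round(n_lab * dim_fraction)
  n_dbl <- round(n_lab * doublet_fraction)
  ev <- function(n, fsc_mu, fi_mu, fi_sd, asp_lo, asp_hi, class) {
    data.frame(
      FSC = stats::rlnorm(n, log(fsc_mu), 0.4),
      SSC = stats::rlnorm(n, log(fsc_mu / 2), 0.4),
      SSC_aspect_ratio = stats::runif(n, asp_lo, asp_hi),
      FI_yellow = stats::rlnorm(n, log(fi_mu), fi_sd),
      class = class, stringsAsFactors = FALSE
    )
  }
  events <- rbind(
    ev(n_lab, 5e4, 3e4, 0.3, 0.62, 1.0, "labeled"),
    ev(n_dim, 2e4, 3e2, 0.5, 0.62, 1.0, "dim"),
    ev(n_dbl, 1e5, 3e4, 0.3, 0.05, 0.39, "doublet")
  )
  events <- events[sample.int(nrow(events)), , drop = FALSE]
  rownames(events) <- NULL
  list(events = events, volume_ul = volume_ul,
       truth_labeled_per_ml = labeled_per_ml)
}

#' Generate a MaxQuant-dialect peptide table with known true copy numbers
#'
#' Builds a merged modification-specific peptide table for both hosts. Each
#' panel protein contributes `n_peptides` unique tryptic-like sequences;
#' peptide intensity is proportional to the host's true fmol abundance
#' (copies per bacteroid times bacteroids loaded over copies-per-fmol) times
#' a per-peptide response factor and multiplicative lognormal noise. The
#' spiked Hi3 standard (`P00489`) is present at its known amount in every
#' sample. The first peptide of each protein is emitted as an
#' unmodified/Met-oxidized pair whose intensities sum to the full peptide
#' signal, exercising the top3 summing rule; decoy rows with a missed
#' cleavage and with a disallowed modification are added with large
#' intensities so any filter failure is loud.
#'
#' @param gt output of [default_ground_truth()] (needs both hosts and the
#'   panel), or a list with `bean`, `pea`, `protein_panel`.
#' @param n_reps replicates per host.
#' @param seed integer seed.
#' @param noise_cv multiplicative intensity CV (default 0.10).
#' @param response_cv CV of per-peptide response factors (0 = equal
#'   response, exact noiseless recovery).
#' @param constants see [quant_constants()].
#' @param include_decoys add filter-violating rows (default `TRUE`).
#' @return list with `peptides` (canonical columns: `sequence`,
#'   `modifications`, `missed_cleavages`, `proteins`, `unique`, and
#'   `intensity_<host>_rep<i>` columns) and `truth` (the panel).
#' @export
generate_peptide_table <- function(gt, n_reps = 3, seed = 1,
                                   noise_cv = 0.10, response_cv = 0.25,
                                   constants = quant_constants(),
                                   include_decoys = TRUE) {
  panel <- gt$protein_panel
  if (any(panel$n_peptides < 3)) {
    stop("every panel protein needs >= 3 peptides", call. = FALSE)
  }
  set.seed(seed)
  samples <- c(outer(c("bean", "pea"), seq_len(n_reps),
                     function(h, i) paste0("intensity_", h, "_rep", i)))
  scale_per_fmol <- 1e5   # arbitrary instrument response, cancels in Hi3 ratio
  rows <- list()
  add_protein <- function(protein, n_pep, fmol_by_host) {
    rf <- if (response_cv > 0) .rlnorm_mean(n_pep, 1, response_cv) else rep(1, n_pep)
    base <- matrix(0, n_pep, length(samples), dimnames = list(NULL, samples))
    for (s in samples) {
      host <- if (grepl("_bean_", s)) "bean" else "pea"
      mu <- fmol_by_host[[host]] * rf * scale_per_fmol
      noise <- if (noise_cv > 0) .rlnorm_mean(n_pep, 1, noise_cv) else rep(1, n_pep)
      base[, s] <- mu * noise
    }
    seqs <- paste0(protein, "_PEP", seq_len(n_pep), "K")
    # peptide 1: split into unmodified + Met-oxidized rows summing to full
    out <- data.frame(sequence = c(seqs[1], seqs[1], seqs[-1]),
                      modifications = c("Unmodified", "Oxidation (M)",
                                        rep("Unmodified", n_pep - 1)),
                      missed_cleavages = 0L, proteins = protein,
                      unique = TRUE, stringsAsFactors = FALSE)
    inten <- rbind(base[1, , drop = FALSE] * 0.6,
                   base[1, , drop = FALSE] * 0.4,
                   base[-1, , drop = FALSE])
    cbind(out, as.data.frame(inten))
  }
  for (i in seq_len(nrow(panel))) {
    p <- panel[i, ]
    fmol <- list(
      bean = p$copies_bean * constants$B_D[["bean"]] / constants$copies_per_fmol,
      pea  = p$copies_pea * constants$B_D[["pea"]] / constants$copies_per_fmol
    )
    rows[[p$protein]] <- add_protein(p$protein, p$n_peptides, fmol)
  }
  rows[["P00489"]] <- add_protein("P00489", 4L,
                                  list(bean = constants$hi3_spike_fmol,
                                       pea = constants$hi3_spike_fmol))
  peptides <- do.call(rbind, rows)
  if (include_decoys) {
    decoy <- function(protein, mods, mc) {
      d <- data.frame(sequence = paste0(protein, "_DECOY", mc, "K"),
                      modifications = mods, missed_cleavages = mc,
                      proteins = protein, unique = TRUE,
                      stringsAsFactors = FALSE)
      inten <- matrix(1e12, 1, length(samples), dimnames = list(NULL, samples))
      cbind(d, as.data.frame(inten))
    }
    peptides <- rbind(peptides,
                      decoy(panel$protein[1], "Unmodified", 1L),
                      decoy(panel$protein[2], "Phospho (STY)", 0L))
  }
  rownames(peptides) <- NULL
  list(peptides = peptides, truth = panel)
}

#' Generate a skewed proteome mass profile
#'
#' Power-law mass shares `p_i` proportional to `i^(-alpha)`, with `alpha`
#' solved so that the top `n_top` proteins carry exactly `target_pct` of the
#' total mass — a deterministic stand-in for the heavy-tailed abundance
#' distribution of a bacteroid proteome.
#'
#' @param n_proteins number of proteins.
#' @param n_top rank at which the cumulative share hits `target_pct`.
#' @param target_pct cumulative percentage (default 50).
#' @return Numeric vector of mass percentages summing to 100, decreasing.
#' @export
generate_mass_profile <- function(n_proteins = 197, n_top = 18,
                                  target_pct = 50) {
  if (n_top >= n_proteins) stop("n_top must be < n_proteins", call. = FALSE)
  share <- function(alpha) {
    w <- seq_len(n_proteins)^(-alpha)
    sum(w[seq_len(n_top)]) / sum(w)
  }
  alpha <- stats::uniroot(function(a) share(a) - target_pct / 100,
                          lower = 1e-6, upper = 10, tol = 1e-12)$root
  w <- seq_len(n_proteins)^(-alpha)
  100 * w / sum(w)
}

#' Generate normalized RNA counts correlated with protein mass
#'
#' Plants a target Pearson correlation on the log10 scale between per-gene
#' protein mass and normalized RNA counts, using the standard construction
#' `log-count = r * z(log-mass) + sqrt(1 - r^2) * noise` (rescaled to a
#' realistic count magnitude).
#'
#' @param protein_mass per-gene protein masses (positive).
#' @param r target Pearson correlation on the log scale.
#' @param seed integer seed.
#' @param count_mean,count_sdlog location/scale of the log10 counts.
#' @return data.frame with `gene`, `protein_mass`, `rna_norm_counts`.
#' @export
generate_rna_counts <- function(protein_mass, r, seed = 1,
                                count_mean = 3, count_sdlog = 0.8) {
  stopifnot(abs(r) <= 1)
  .check_positive(protein_mass, "protein_mass")
  set.seed(seed)
  z <- scale(log10(protein_mass))[, 1]
  eps <- stats::rnorm(length(z))
  logc <- count_mean + count_sdlog * (r * z + sqrt(1 - r^2) * eps)
  data.frame(gene = paste0("g", seq_along(protein_mass)),
             protein_mass = protein_mass,
             rna_norm_counts = 10^logc,
             stringsAsFactors = FALSE)
}

#' Simulate the full measurement bundle
#'
#' Generates every raw table the pipeline consumes from one ground truth and
#' one seed. The seed fans out to per-table child seeds by fixed offsets, so
#' adding a table to the bundle never perturbs the draws of existing ones,
#' and identical `(gt, seed)` yield byte-identical bundles.
#'
#' @param gt output of [default_ground_truth()].
#' @param seed integer master seed.
#' @param n_plants,n_nodules,n_packing,n_reps cohort sizes.
#' @param n_bacteroids named vector `c(bean = , pea = )`.
#' @param rna_r named vector of planted log-scale RNA-protein correlations.
#' @param rna_n named vector of proteome sizes for the RNA/mass tables.
#' @param ... passed to [generate_peptide_table()].
#' @return list of tables (see spec fields) plus `provenance`.
#' @export
simulate_bundle <- function(gt = default_ground_truth(), seed = 1,
                            n_plants = 11, n_nodules = 8,
                            n_bacteroids = c(bean = 240, pea = 246),
                            n_packing = 6, n_reps = 3,
                            rna_r = c(bean = 0.66, pea = 0.84),
                            rna_n = c(bean = 184, pea = 197), ...) {
  s <- function(k) as.integer(seed + k)
  plant_table <- rbind(generate_plants(gt$bean, n_plants, s(1)),
                       generate_plants(gt$pea, n_plants, s(2)))
  segmentation_table <- rbind(
    generate_segmentation(gt$bean, n_bacteroids[["bean"]], s(5)),
    generate_segmentation(gt$pea, n_bacteroids[["pea"]], s(6)))
  packing_table <- rbind(generate_packing(gt$bean, n_packing, s(7)),
                         generate_packing(gt$pea, n_packing, s(8)))
  flow <- generate_flow_events(seed = s(9))
  pep <- generate_peptide_table(gt, n_reps = n_reps, seed = s(10), ...)
  rna <- do.call(rbind, lapply(c("bean", "pea"), function(h) {
    mass_pct <- generate_mass_profile(rna_n[[h]])
    counts <- generate_rna_counts(mass_pct, rna_r[[h]],
                                  seed = s(if (h == "bean") 11 else 12))
    counts$host <- h
    counts
  }))
  list(
    plant_table = plant_table,
    bean_section_table = generate_sections(gt$bean, n_nodules, s(3)),
    pea_section_table = generate_sections(gt$pea, n_nodules, s(4)),
    segmentation_table = segmentation_table,
    packing_table = packing_table,
    flow_event_table = flow$events,
    flow_volume_ul = flow$volume_ul,
    flow_truth_per_ml = flow$truth_labeled_per_ml,
    peptide_table = pep$peptides,
    peptide_truth = pep$truth,
    rna_count_table = rna,
    provenance = list(seed = seed)
  )
}
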