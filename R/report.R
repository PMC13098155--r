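#' Compare one parameter between the two hosts
#'
#' Group means with standard errors, a Student's unpaired t-test, and the
#' bean/pea fold change. `mode = "ratio_of_means"` (default, the table
#' convention) divides the group means; `mode = "mean_of_ratios"` averages
#' the element-wise ratios of paired values.
#'
#' @param bean,pea numeric vectors of per-replicate values.
#' @param mode fold-change convention.
#' @param parameter optional row label.
#' @return One-row data.frame: `parameter`, `bean_mean`, `bean_se`,
#'   `pea_mean`, `pea_se`, `fold_change`, `p_value`, `n_bean`, `n_pea`.
#' @export
compare_groups <- function(bean, pea,
                           mode = c("ratio_of_means", "mean_of_ratios"),
                           parameter = NA_character_) {
  mode <- match.arg(mode)
  se <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
  if (mode == "ratio_of_means") {
    if (mean(pea) == 0) stop("pea mean is zero in ratio mode", call. = FALSE)
    fc <- mean(bean) / mean(pea)
  } else {
    if (length(bean) != length(pea)) {
      stop("mean_of_ratios needs paired vectors", call. = FALSE)
    }
    fc <- mean(bean / pea)
  }
  p <- if (length(bean) >= 2 && length(pea) >= 2 &&
           (stats::sd(bean) > 0 || stats::sd(pea) > 0)) {
    stats::t.test(bean, pea, var.equal = TRUE)$p.value
  } else NA_real_
  data.frame(parameter = parameter,
             bean_mean = mean(bean), bean_se = se(bean),
             pea_mean = mean(pea), pea_se = se(pea),
             fold_change = fc, p_value = p,
             n_bean = length(bean), n_pea = length(pea),
             stringsAsFactors = FALSE)
}

#' Assemble the full comparison table with derived rows
#'
#' Takes a table of raw cohort means per host (reference-style columns
#' `parameter`, `bean_mean`, `pea_mean`; SEs optional) and appends every
#' derivable row with provenance:
#'
#' * `nodule_density` (mg/cm^3) = plant nodule dry mass / plant nodule volume
#' * `total_bacteroid_volume` (mm^3) = infected nodule volume x packing
#' * `bacteroids_per_nodule` (1e8) = total bacteroid volume / bacteroid volume
#' * `protein_density_bacteroid` (pg/um^3) = protein per bacteroid / volume
#' * `protein_density_nodule` (ug/mm^3) = the same density in nodule-scale units
#' * `pct_nodule_volume_bacteroid` (%) = total bacteroid volume /
#'   calculated nodule volume
#'
#' A derived row is only emitted when all its parent rows are present, so a
#' geometry-only input still yields the geometry rows. The fold-change
#' column is bean/pea (ratio of means) throughout.
#'
#' @param raw data.frame of raw rows.
#' @return data.frame with `parameter`, `bean`, `pea`, `fold_change`,
#'   `provenance`.
#' @export
build_table1 <- function(raw) {
  need <- c("parameter", "bean_mean", "pea_mean")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  val <- function(p, col) {
    i <- match(p, raw$parameter)
    if (is.na(i)) NA_real_ else raw[[col]][i]
  }
  rows <- data.frame(parameter = raw$parameter, bean = raw$bean_mean,
                     pea = raw$pea_mean, provenance = "raw",
                     stringsAsFactors = FALSE)
  derived <- list(
    list("nodule_density",
         parents = c("plant_nodule_dry_mass", "plant_nodule_volume"),
         f = function(m) m[1] / (m[2] * unit_registry$mm3_to_cm3)),
    list("total_bacteroid_volume",
         parents = c("infected_nodule_volume", "packing_fraction"),
         f = function(m) total_bacteroid_volume(m[1], m[2] / 100)),
    list("protein_density_bacteroid",
         parents = c("protein_per_bacteroid", "bacteroid_volume"),
         f = function(m) protein_density(m[1], m[2])),
    list("protein_density_nodule",
         parents = c("protein_per_bacteroid", "bacteroid_volume"),
         f = function(m) protein_density(m[1], m[2]) * 1000)
  )
  for (d in derived) {
    for (host in c("bean", "pea")) {
      col <- paste0(host, "_mean")
      m <- vapply(d$parents, val, numeric(1), col = col)
      if (any(is.na(m))) next
      i <- match(d[[1]], rows$parameter)
      if (is.na(i)) {
        rows <- rbind(rows, data.frame(
          parameter = d[[1]], bean = NA_real_, pea = NA_real_,
          provenance = paste0("derived-from:", paste(d$parents, collapse = "+")),
          stringsAsFactors = FALSE))
        i <- nrow(rows)
      }
      rows[[host]][i] <- d$f(m)
    }
  }
  # second-order rows, fed by the derived total bacteroid volume
  tv <- match("total_bacteroid_volume", rows$parameter)
  if (!is.na(tv)) {
    bv_b <- val("bacteroid_volume", "bean_mean")
    bv_p <- val("bacteroid_volume", "pea_mean")
    if (!is.na(bv_b) && !is.na(bv_p)) {
      rows <- rbind(rows, data.frame(
        parameter = "bacteroids_per_nodule",
        bean = bacteroids_per_nodule(rows$bean[tv], bv_b) / 1e8,
        pea = bacteroids_per_nodule(rows$pea[tv], bv_p) / 1e8,
        provenance = "derived-from:total_bacteroid_volume+bacteroid_volume",
        stringsAsFactors = FALSE))
    }
    cn_b <- val("calculated_nodule_volume", "bean_mean")
    cn_p <- val("calculated_nodule_volume", "pea_mean")
    if (!is.na(cn_b) && !is.na(cn_p)) {
      rows <- rbind(rows, data.frame(
        parameter = "pct_nodule_volume_bacteroid",
        bean = 100 * rows$bean[tv] / cn_b,
        pea = 100 * rows$pea[tv] / cn_p,
        provenance = "derived-from:total_bacteroid_volume+calculated_nodule_volume",
        stringsAsFactors = FALSE))
    }
  }
  rows$fold_change <- rows$bean / rows$pea
  rownames(rows) <- NULL
  rows[, c("parameter", "bean", "pea", "fold_change", "provenance")]
}

#' The published raw rows used as inputs to the derived-row closure
#'
#' Subset of [reference_means()] that the pipeline treats as measured
#' inputs (everything except the rows [build_table1()] derives).
#'
#' @return data.frame in the [reference_means()] layout.
#' @export
reference_raw_means <- function() {
  ref <- reference_means()
  derived <- c("nodule_density", "total_bacteroid_volume",
               "bacteroids_per_nodule", "protein_density_bacteroid",
               "protein_density_nodule")
  ref[!ref$parameter %in% derived, , drop = FALSE]
}

#' Run the full pipeline on a synthetic bundle
#'
#' Simulates (or accepts) a measurement bundle, then runs every stage:
#' nodule geometry on the section tables, the bacteroid census on the
#' segmentation/packing/flow tables, rate normalization on the plant table,
#' proteome quantification on the peptide table, and the assembled
#' comparison table. Identical `(gt, seed)` give identical results; if
#' `out_dir` is given, per-stage TSVs and a JSON summary are written there.
#'
#' @param seed integer seed for the simulation.
#' @param gt ground truth, see [default_ground_truth()].
#' @param bundle optionally a pre-built bundle (then `seed`/`gt` are only
#'   used for provenance).
#' @param out_dir optional output directory.
#' @param ... passed to [simulate_bundle()].
#' @return list with `geometry`, `census`, `rates`, `quant`, `table1`,
#'   `rna`, `summary`.
#' @export
run_pipeline <- function(seed = 1, gt = default_ground_truth(),
                         bundle = NULL, out_dir = NULL, ...) {
  if (is.null(bundle)) bundle <- simulate_bundle(gt, seed = seed, ...)

  geometry <- list(bean = bean_nodule_volumes(bundle$bean_section_table),
                   pea = pea_nodule_volumes(bundle$pea_section_table))

  census <- lapply(c(bean = "bean", pea = "pea"), function(h) {
    segs <- bundle$segmentation_table[bundle$segmentation_table$host == h, ]
    pk <- bundle$packing_table[bundle$packing_table$host == h, ]
    bacteroid_census(segs, pk, V_i = mean(geometry[[h]]$V_i),
                     protein_per_bacteroid_pg =
                       gt[[h]]$means$protein_per_bacteroid_pg)
  })

  rates <- lapply(c(bean = "bean", pea = "pea"), function(h) {
    pl <- bundle$plant_table[bundle$plant_table$host == h, ]
    fix <- vapply(seq_len(nrow(pl)), function(i) {
      plant_fixation_rate(data.frame(
        fraction = c("shoot", "root", "nodule"),
        atom_percent = c(pl$shoot_atom_pct[i], pl$root_atom_pct[i],
                         pl$nodule_atom_pct[i]),
        total_N_ug = c(pl$shoot_total_N_ug[i], pl$root_total_N_ug[i],
                       pl$nodule_total_N_ug[i])))
    }, numeric(1))
    ara <- ara_rate(pl$ethylene_nmol, pl$ara_incubation_h)
    cs <- census[[h]]
    scales <- function(r) normalize_rate(
      r,
      sdw_g = mean(pl$shoot_dry_mass_mg) / 1000,
      nodule_volume_cm3 = mean(pl$plant_nodule_volume_mm3) *
        unit_registry$mm3_to_cm3,
      nodule_dry_mass_ug = mean(pl$nodule_dry_mass_mg) * 1000,
      infected_volume_mm3 = mean(geometry[[h]]$V_i) * mean(pl$nodule_count),
      bacteroid_count = cs$bacteroids_per_nodule * mean(pl$nodule_count),
      protein_per_bacteroid_pg = cs$protein_per_bacteroid,
      bacteroid_volume_um3 = cs$mean_volume)
    list(fix_per_plant = fix, ara_per_plant = ara,
         fix_scales = scales(mean(fix)), ara_scales = scales(mean(ara)))
  })

  quant <- NULL
  if (!is.null(bundle$peptide_table)) {
    bq <- quantify_proteome(bundle$peptide_table, "bean",
                            samples = grep("^intensity_bean",
                                           names(bundle$peptide_table),
                                           value = TRUE))
    pq <- quantify_proteome(bundle$peptide_table, "pea",
                            samples = grep("^intensity_pea",
                                           names(bundle$peptide_table),
                                           value = TRUE))
    quant <- list(bean = bq, pea = pq,
                  fold_changes = fold_change_table(bq, pq))
  } else {
    warning("no peptide table in bundle; quantification stage skipped")
  }

  rna <- lapply(c(bean = "bean", pea = "pea"), function(h) {
    x <- bundle$rna_count_table[bundle$rna_count_table$host == h, ]
    c(rna_protein_correlation(x$protein_mass, x$rna_norm_counts, log = TRUE),
      proteome_mass_rank(x$protein_mass)["n_to_target"])
  })

  raw <- do.call(rbind, lapply(list(
    c("shoot_dry_mass", "shoot_dry_mass_mg"),
    c("plant_nodule_dry_mass", "nodule_dry_mass_mg"),
    c("plant_nodule_volume", "plant_nodule_volume_mm3")
  ), function(spec) {
    bt <- bundle$plant_table
    data.frame(parameter = spec[1],
               bean_mean = mean(bt[[spec[2]]][bt$host == "bean"]),
               pea_mean = mean(bt[[spec[2]]][bt$host == "pea"]),
               stringsAsFactors = FALSE)
  }))
  raw <- rbind(raw, data.frame(
    parameter = c("calculated_nodule_volume", "infected_nodule_volume",
                  "packing_fraction", "bacteroid_volume",
                  "protein_per_bacteroid"),
    bean_mean = c(mean(geometry$bean$V_n), mean(geometry$bean$V_i),
                  100 * census$bean$packing_fraction,
                  census$bean$mean_volume, census$bean$protein_per_bacteroid),
    pea_mean = c(mean(geometry$pea$V_n), mean(geometry$pea$V_i),
                 100 * census$pea$packing_fraction,
                 census$pea$mean_volume, census$pea$protein_per_bacteroid),
    stringsAsFactors = FALSE))
  table1 <- build_table1(raw)

  summary <- list(
    seed = bundle$provenance$seed,
    mean_Vn = list(bean = mean(geometry$bean$V_n),
                   pea = mean(geometry$pea$V_n)),
    packing = list(bean = census$bean$packing_fraction,
                   pea = census$pea$packing_fraction),
    bacteroids_per_nodule = list(bean = census$bean$bacteroids_per_nodule,
                                 pea = census$pea$bacteroids_per_nodule),
    fix_per_plant = list(bean = mean(rates$bean$fix_per_plant),
                         pea = mean(rates$pea$fix_per_plant)),
    rna_r = list(bean = rna$bean$r, pea = rna$pea$r)
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(rbind(geometry$bean, geometry$pea),
              file.path(out_dir, "geometry.tsv"))
    write_tsv(table1, file.path(out_dir, "table1.tsv"))
    if (!is.null(quant)) {
      write_tsv(quant$fold_changes, file.path(out_dir, "fold_changes.tsv"))
    }
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  list(geometry = geometry, census = census, rates = rates, quant = quant,
       table1 = table1, rna = rna, summary = summary)
}
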