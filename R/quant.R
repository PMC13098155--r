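#' Constants for absolute copy-number quantification
#'
#' The Hi3 spike amount, the copies-per-fmol conversion (Avogadro's number
#' scaled to fmol), the protein load per injection, and the per-host
#' denominators used for the five copy-number scales: bacteroids per loaded
#' sample (`B_D`), bacteroid volume (`B_vol`, um^3), bacteroids per nodule
#' (`B_nod`), mean nodule volume (`Nod_vol`, mm^3), and protein content per
#' bacteroid (`B_P`, pg). `B_D` is taken as an explicit constant rather than
#' re-derived from the load and protein content, because the published value
#' reflects an unrounded protein content.
#'
#' @param ... named overrides for any constant.
#' @return Named list of constants.
#' @export
quant_constants <- function(...) {
  k <- list(
    hi3_spike_fmol = 12.5,
    copies_per_fmol = 6.0221413e8,
    loaded_protein_ng = 380,
    B_D = c(bean = 1202531, pea = 608974),
    B_vol = c(bean = 0.93, pea = 4.50),
    B_nod = c(bean = 5.28e8, pea = 1.63e8),
    Nod_vol = c(bean = 6.07, pea = 4.61),
    B_P = c(bean = 0.32, pea = 0.62)
  )
  utils::modifyList(k, list(...))
}

# internal: classify a MaxQuant-style modification string
.mod_class <- function(modifications) {
  m <- trimws(as.character(modifications))
  out <- rep("other", length(m))
  out[m %in% c("", "Unmodified", "none", NA)] <- "none"
  out[grepl("^[0-9]* ?Oxidation \\(M\\)$", m) | m %in% c("Met-ox", "Oxidation (M)")] <- "met_ox"
  out[is.na(m)] <- "none"
  out
}

#' Top-three peptide intensity for one protein
#'
#' Implements the top3 rule: keep only unique peptides with zero missed
#' cleavages that are unmodified or carry methionine oxidation; when the same
#' sequence occurs both unmodified and oxidized, sum the two intensities;
#' then average the three highest resulting peptide intensities. Rows with
#' missed cleavages or disallowed modifications never contribute.
#'
#' @param peptides data.frame with columns `sequence`, `modifications`,
#'   `missed_cleavages`, `proteins`, `unique`, and one intensity column per
#'   sample (see [read_peptide_table()] for the MaxQuant-dialect mapping).
#' @param protein protein identifier to quantify.
#' @param sample name of the intensity column to use.
#' @param strict if `TRUE` (default) a protein with fewer than three
#'   qualifying peptides is an error; if `FALSE` the mean of the available
#'   peptides is returned with attribute `n_peptides`.
#' @return Mean intensity of the top three peptides (numeric scalar).
#' @export
top3 <- function(peptides, protein, sample, strict = TRUE) {
  if (!sample %in% names(peptides)) {
    stop("no intensity column '", sample, "'", call. = FALSE)
  }
  keep <- peptides$proteins == protein &
    as.logical(peptides$unique) &
    peptides$missed_cleavages == 0 &
    .mod_class(peptides$modifications) %in% c("none", "met_ox")
  rows <- peptides[keep, , drop = FALSE]
  if (nrow(rows) == 0) {
    if (strict) stop("no qualifying peptides for ", protein, call. = FALSE)
    return(structure(NA_real_, n_peptides = 0L))
  }
  # sum unmodified + Met-oxidized intensities of the same sequence
  per_seq <- tapply(rows[[sample]], rows$sequence, sum)
  per_seq <- sort(as.numeric(per_seq), decreasing = TRUE)
  if (length(per_seq) < 3) {
    if (strict) {
      stop(sprintf("protein %s has %d qualifying peptides (need 3)",
                   protein, length(per_seq)), call. = FALSE)
    }
    return(structure(mean(per_seq), n_peptides = length(per_seq)))
  }
  mean(per_seq[1:3])
}

#' Absolute protein abundance from the Hi3 spike
#'
#' Scales a protein's top3 intensity by the spiked Hi3 standard of known
#' amount: `A_b = (top3_protein / top3_hi3) * spike`.
#'
#' @param top3_protein top3 intensity of the protein.
#' @param top3_hi3 top3 intensity of the Hi3 standard in the same run.
#' @param spike_fmol spiked standard amount (default 12.5 fmol).
#' @return Abundance in fmol in the loaded sample.
#' @export
absolute_abundance <- function(top3_protein, top3_hi3, spike_fmol = 12.5) {
  .check_positive(top3_hi3, "top3_hi3")
  .check_positive(top3_protein, "top3_protein", strict = FALSE)
  (top3_protein / top3_hi3) * spike_fmol
}

#' Copy numbers at the five physiological scales
#'
#' Converts a fmol abundance to absolute copies (`C_p = A_b * copies_per_fmol`)
#' and expresses it per bacteroid (`C_p / B_D`), per bacteroid volume
#' (per-bacteroid / `B_vol`), per nodule (per-bacteroid * `B_nod`), per
#' nodule volume (per-nodule / `Nod_vol`) and per pg bacteroid protein
#' (per-bacteroid / `B_P`).
#'
#' @param A_b abundance in fmol (vectorized).
#' @param host `"bean"` or `"pea"`.
#' @param constants see [quant_constants()].
#' @return data.frame with `A_b`, `C_p`, `copies_per_bacteroid`,
#'   `copies_per_bacteroid_volume`, `copies_per_nodule`,
#'   `copies_per_nodule_volume`, `copies_per_unit_protein`, `host`.
#' @export
copy_numbers <- function(A_b, host = c("bean", "pea"),
                         constants = quant_constants()) {
  host <- match.arg(host)
  .check_positive(A_b, "A_b", strict = FALSE)
  C_p <- A_b * constants$copies_per_fmol
  per_bact <- C_p / constants$B_D[[host]]
  per_nod <- per_bact * constants$B_nod[[host]]
  data.frame(
    A_b = A_b, C_p = C_p,
    copies_per_bacteroid = per_bact,
    copies_per_bacteroid_volume = per_bact / constants$B_vol[[host]],
    copies_per_nodule = per_nod,
    copies_per_nodule_volume = per_nod / constants$Nod_vol[[host]],
    copies_per_unit_protein = per_bact / constants$B_P[[host]],
    host = host, stringsAsFactors = FALSE
  )
}

#' Quantify a whole proteome from a peptide table
#'
#' Runs top3 + Hi3 scaling + copy-number conversion for every protein in a
#' peptide table, per replicate intensity column.
#'
#' @param peptides peptide data.frame (canonical columns, see [top3()]).
#' @param host `"bean"` or `"pea"`.
#' @param samples character vector of intensity column names; default all
#'   columns starting with `"intensity"`.
#' @param hi3_protein accession of the spiked Hi3 standard (default
#'   `"P00489"`).
#' @param constants see [quant_constants()].
#' @param strict passed to [top3()].
#' @param normalize if `TRUE`, apply median-ratio normalization of replicate
#'   intensity columns before quantification (default `FALSE`).
#' @return data.frame, one row per protein x replicate, with top3 intensity
#'   and all copy-number scales.
#' @export
quantify_proteome <- function(peptides, host = c("bean", "pea"),
                              samples = NULL, hi3_protein = "P00489",
                              constants = quant_constants(),
                              strict = TRUE, normalize = FALSE) {
  host <- match.arg(host)
  if (is.null(samples)) {
    samples <- grep("^intensity", names(peptides), value = TRUE)
  }
  if (length(samples) == 0) stop("no intensity columns found", call. = FALSE)
  if (normalize) peptides <- median_ratio_normalize(peptides, samples)
  prots <- setdiff(unique(peptides$proteins), hi3_protein)
  out <- lapply(samples, function(s) {
    t3_hi3 <- top3(peptides, hi3_protein, s, strict = strict)
    t3 <- vapply(prots, function(p) as.numeric(top3(peptides, p, s, strict = strict)),
                 numeric(1))
    A_b <- absolute_abundance(t3, t3_hi3, constants$hi3_spike_fmol)
    cbind(data.frame(protein = prots, sample = s, top3_intensity = t3,
                     stringsAsFactors = FALSE),
          copy_numbers(A_b, host, constants))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Median-ratio normalization of replicate intensity columns
#'
#' Optional replicate normalization: each intensity column is divided by the
#' median of its peptide-wise ratios to the row-geometric-mean reference
#' (the DESeq-style size factor), equalizing systematic load differences
#' between runs.
#'
#' @param peptides peptide data.frame.
#' @param samples intensity column names.
#' @return The peptide table with normalized intensity columns.
#' @export
median_ratio_normalize <- function(peptides, samples) {
  m <- as.matrix(peptides[, samples, drop = FALSE])
  pos <- rowSums(m > 0) == ncol(m)
  ref <- exp(rowMeans(log(m[pos, , drop = FALSE])))
  sf <- apply(m[pos, , drop = FALSE], 2, function(col) stats::median(col / ref))
  for (i in seq_along(samples)) m[, i] <- m[, i] / sf[i]
  peptides[, samples] <- m
  peptides
}

#' Per-protein fold changes between hosts at all five scales
#'
#' For every protein quantified in both hosts, the fold change (pea/bean by
#' default) of the group means at each copy-number scale, with a Welch
#' two-sample t-test on the per-replicate values at each scale and a
#' significance flag at p < 0.05.
#'
#' @param bean_quant,pea_quant outputs of [quantify_proteome()] for the two
#'   hosts.
#' @return data.frame, one row per protein, with `fc_<scale>` and
#'   `p_<scale>` columns plus `significant_bacteroid`.
#' @export
fold_change_table <- function(bean_quant, pea_quant) {
  scales <- c("copies_per_bacteroid", "copies_per_bacteroid_volume",
              "copies_per_nodule", "copies_per_nodule_volume",
              "copies_per_unit_protein")
  shared <- intersect(unique(bean_quant$protein), unique(pea_quant$protein))
  if (length(shared) == 0) stop("no shared proteins", call. = FALSE)
  rows <- lapply(shared, function(p) {
    b <- bean_quant[bean_quant$protein == p, , drop = FALSE]
    q <- pea_quant[pea_quant$protein == p, , drop = FALSE]
    out <- list(protein = p)
    for (sc in scales) {
      bv <- b[[sc]]; pv <- q[[sc]]
      if (mean(bv) == 0) stop("zero bean mean for ", p, call. = FALSE)
      nm <- sub("^copies_", "", sc)
      out[[paste0("fc_", nm)]] <- mean(pv) / mean(bv)
      out[[paste0("p_", nm)]] <-
        if (length(bv) >= 2 && length(pv) >= 2 &&
            (stats::sd(bv) > 0 || stats::sd(pv) > 0)) {
          stats::t.test(pv, bv, var.equal = FALSE)$p.value
        } else NA_real_
    }
    as.data.frame(out, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$significant_bacteroid <- !is.na(res$p_per_bacteroid) &
    res$p_per_bacteroid < 0.05
  res
}

#' Cumulative proteome-mass ranking
#'
#' Sorts proteins by their share of total proteome mass and reports the
#' smallest number of proteins whose cumulative share reaches a target
#' percentage (default 50%).
#'
#' @param mass numeric vector of per-protein masses (any proportional unit)
#'   or mass percentages; optionally named.
#' @param target_pct cumulative percentage to reach (default 50).
#' @return list with `ranked` (data.frame of protein, mass_pct,
#'   cumulative_pct) and `n_to_target`.
#' @export
proteome_mass_rank <- function(mass, target_pct = 50) {
  if (length(mass) == 0) stop("empty input", call. = FALSE)
  .check_positive(mass, "mass", strict = FALSE)
  pct <- 100 * mass / sum(mass)
  ord <- order(pct, decreasing = TRUE)
  ranked <- data.frame(
    protein = if (is.null(names(mass))) as.character(seq_along(mass)[ord]) else names(mass)[ord],
    mass_pct = pct[ord],
    cumulative_pct = cumsum(pct[ord]),
    stringsAsFactors = FALSE
  )
  # tolerance so that an exact tie at the target is counted as reached
  list(ranked = ranked,
       n_to_target = which(ranked$cumulative_pct >= target_pct * (1 - 1e-12))[1])
}

#' Compare two proteome mass-fraction distributions
#'
#' Two-sample, two-sided Kolmogorov-Smirnov test on the per-protein mass
#' fractions of the two hosts.
#'
#' @param bean_fractions,pea_fractions numeric vectors of mass fractions.
#' @return list with `D` and `p_value`.
#' @export
distribution_compare <- function(bean_fractions, pea_fractions) {
  if (length(bean_fractions) < 2 || length(pea_fractions) < 2) {
    stop("need at least two values per group", call. = FALSE)
  }
  kt <- suppressWarnings(stats::ks.test(bean_fractions, pea_fractions,
                                        alternative = "two.sided"))
  list(D = unname(kt$statistic), p_value = kt$p.value)
}

#' RNA-protein correlation
#'
#' Pearson correlation between per-gene protein mass and normalized RNA
#' counts, optionally on the log scale (default, matching the usual display
#' of abundance-vs-expression scatter).
#'
#' @param protein_mass per-gene protein mass (e.g. fg/bacteroid).
#' @param rna_counts normalized RNA counts for the same genes.
#' @param log if `TRUE` (default) correlate `log10` of both vectors
#'   (zeroes dropped pairwise).
#' @return list with `r`, `r_squared`, `p_value`, `n`.
#' @export
rna_protein_correlation <- function(protein_mass, rna_counts, log = TRUE) {
  if (length(protein_mass) != length(rna_counts)) {
    stop("vectors must be paired", call. = FALSE)
  }
  x <- protein_mass; y <- rna_counts
  if (log) {
    keep <- x > 0 & y > 0
    x <- log10(x[keep]); y <- log10(y[keep])
  }
  if (length(x) < 3) stop("need at least 3 paired genes", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant vector", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  r <- unname(ct$estimate)
  list(r = r, r_squared = r^2, p_value = ct$p.value, n = length(x))
}
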