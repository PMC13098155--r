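make_peptides <- function(rows) {
  base <- data.frame(sequence = character(), modifications = character(),
                     missed_cleavages = integer(), proteins = character(),
                     unique = logical(), intensity_s1 = numeric(),
                     stringsAsFactors = FALSE)
  rbind(base, rows)
}

test_that("top3 averages the three most intense qualifying peptides", {
  pep <- make_peptides(data.frame(
    sequence = paste0("P", 1:4, "K"), modifications = "Unmodified",
    missed_cleavages = 0L, proteins = "A", unique = TRUE,
    intensity_s1 = c(10, 8, 6, 4)))
  expect_equal(top3(pep, "A", "intensity_s1"), 8)
})

test_that("top3 sums unmodified and Met-oxidized forms of the same sequence", {
  pep <- make_peptides(data.frame(
    sequence = c("XK", "XK", "YK", "ZK"),
    modifications = c("Unmodified", "Oxidation (M)", "Unmodified", "Unmodified"),
    missed_cleavages = 0L, proteins = "A", unique = TRUE,
    intensity_s1 = c(5, 3, 7, 6)))
  # XK contributes 5 + 3 = 8; top three are {8, 7, 6}
  expect_equal(top3(pep, "A", "intensity_s1"), 7)
})

test_that("top3 drops missed cleavages, non-unique rows and other modifications", {
  pep <- make_peptides(data.frame(
    sequence = c("AK", "BK", "CK", "MCK", "PHK", "NUK"),
    modifications = c(rep("Unmodified", 4), "Phospho (STY)", "Unmodified"),
    missed_cleavages = c(0L, 0L, 0L, 1L, 0L, 0L),
    proteins = "A", unique = c(rep(TRUE, 5), FALSE),
    intensity_s1 = c(3, 2, 1, 100, 100, 100)))
  expect_equal(top3(pep, "A", "intensity_s1"), 2)
  # invariant to adding any row with missed cleavages
  extra <- pep[4, ]; extra$intensity_s1 <- 1e9
  expect_equal(top3(rbind(pep, extra), "A", "intensity_s1"), 2)
  # permutation invariance in row order
  set.seed(2)
  for (i in 1:5) {
    expect_equal(top3(pep[sample.int(nrow(pep)), ], "A", "intensity_s1"), 2)
  }
})

test_that("strict top3 errors below three peptides; fallback averages", {
  pep <- make_peptides(data.frame(
    sequence = c("AK", "BK"), modifications = "Unmodified",
    missed_cleavages = 0L, proteins = "A", unique = TRUE,
    intensity_s1 = c(4, 2)))
  expect_error(top3(pep, "A", "intensity_s1"), "qualifying peptides")
  out <- top3(pep, "A", "intensity_s1", strict = FALSE)
  expect_equal(as.numeric(out), 3)
  expect_equal(attr(out, "n_peptides"), 2L)
})

test_that("Hi3 scaling converts intensity ratios to fmol", {
  expect_equal(absolute_abundance(100, 100), 12.5)     # unity ratio
  expect_equal(absolute_abundance(200, 100), 25)
  expect_error(absolute_abundance(1, 0), "must be > 0")
})

test_that("copy numbers follow the five-scale constants", {
  k <- quant_constants()
  row <- copy_numbers(1, "bean", k)
  expect_equal(row$C_p, 6.0221413e8)
  expect_equal(row$copies_per_bacteroid, 6.0221413e8 / 1202531,
               tolerance = 1e-10)
  expect_equal(row$copies_per_bacteroid, 500.8, tolerance = 1e-3)
  zero <- copy_numbers(0, "pea", k)
  expect_true(all(unlist(zero[sapply(zero, is.numeric)]) == 0))
  # scale identities for arbitrary abundances
  rows <- copy_numbers(c(0.2, 1, 7), "pea", k)
  expect_equal(rows$copies_per_bacteroid_volume * k$B_vol[["pea"]],
               rows$copies_per_bacteroid)
  expect_equal(rows$copies_per_nodule / k$B_nod[["pea"]],
               rows$copies_per_bacteroid)
  expect_equal(rows$copies_per_nodule_volume * k$Nod_vol[["pea"]],
               rows$copies_per_nodule)
  expect_equal(rows$copies_per_unit_protein * k$B_P[["pea"]],
               rows$copies_per_bacteroid)
})

test_that("zero-noise peptide tables round-trip planted copy numbers", {
  gt <- default_ground_truth()
  pep <- generate_peptide_table(gt, n_reps = 2, seed = 1,
                                noise_cv = 0, response_cv = 0)
  q <- quantify_proteome(pep$peptides, "bean",
                         samples = c("intensity_bean_rep1"))
  got <- q$copies_per_bacteroid[match(pep$truth$protein, q$protein)]
  expect_equal(got, pep$truth$copies_bean, tolerance = 1e-3 / 100)
  qp <- quantify_proteome(pep$peptides, "pea",
                          samples = c("intensity_pea_rep1"))
  gotp <- qp$copies_per_bacteroid[match(pep$truth$protein, qp$protein)]
  expect_equal(gotp, pep$truth$copies_pea, tolerance = 1e-3 / 100)
})

test_that("fold-change table recovers planted ratios and the scale identities", {
  gt <- default_ground_truth()
  pep <- generate_peptide_table(gt, n_reps = 3, seed = 8,
                                noise_cv = 0.10, response_cv = 0.25)
  bq <- quantify_proteome(pep$peptides, "bean",
                          samples = grep("bean", names(pep$peptides), value = TRUE))
  pq <- quantify_proteome(pep$peptides, "pea",
                          samples = grep("pea", names(pep$peptides), value = TRUE))
  fc <- fold_change_table(bq, pq)
  k <- quant_constants()
  # exact cascade identities per protein
  expect_equal(fc$fc_per_bacteroid_volume,
               fc$fc_per_bacteroid * k$B_vol[["bean"]] / k$B_vol[["pea"]])
  expect_equal(fc$fc_per_unit_protein,
               fc$fc_per_bacteroid * k$B_P[["bean"]] / k$B_P[["pea"]])
  # planted NifH ratio 5.49 recovered within sampling error
  # (3 replicates at 10% CV: ~3 relative standard errors = 25%)
  nifh <- fc$fc_per_bacteroid[fc$protein == "NifH"]
  expect_lt(abs(nifh - 5.49) / 5.49, 0.25)
  # identical groups: unit fold change, p near 1
  same <- fold_change_table(bq, transform(bq, host = "pea"))
  expect_equal(same$fc_per_bacteroid, rep(1, nrow(same)))
  expect_true(all(same$p_per_bacteroid > 0.9))
})

test_that("proteome mass ranking finds the 50% rank", {
  expect_equal(proteome_mass_rank(c(30, 25, 10, 9, 8, 8, 5, 5))$n_to_target, 2)
  expect_equal(proteome_mass_rank(rep(1, 100))$n_to_target, 50)
  # planted pea-like skew: top 18 of 197 proteins carry 50% of the mass
  prof <- generate_mass_profile(197, 18, 50)
  expect_equal(proteome_mass_rank(prof)$n_to_target, 18)
  expect_equal(sum(prof), 100)
  expect_error(proteome_mass_rank(numeric(0)), "empty")
})

test_that("distribution comparison behaves at the extremes and detects skew", {
  ident <- distribution_compare(1:20, 1:20)
  expect_equal(ident$D, 0)
  expect_equal(ident$p_value, 1)
  disj <- distribution_compare(1:20, 21:40)
  expect_equal(disj$D, 1)
  # two lognormals with different sigma separate at n ~ 190 per group
  set.seed(14)
  a <- rlnorm(190, 0, 0.5); b <- rlnorm(190, 0, 1.5)
  expect_lt(distribution_compare(a, b)$p_value, 0.05)
})

test_that("RNA-protein correlation recovers planted log-scale r", {
  x <- c(1, 2, 4, 8)
  expect_equal(rna_protein_correlation(x, 3 * x)$r, 1)
  expect_equal(rna_protein_correlation(x, 3 * x)$r_squared, 1)
  expect_equal(rna_protein_correlation(x, rev(x))$r, -1)
  expect_error(rna_protein_correlation(x, rep(2, 4)), "constant")
  mass <- generate_mass_profile(197)
  rna <- generate_rna_counts(mass, r = 0.84, seed = 4)
  got <- rna_protein_correlation(rna$protein_mass, rna$rna_norm_counts)
  # 95% CI half-width of r = 0.84 at n = 197 is about 0.05
  expect_lt(abs(got$r - 0.84), 0.1)
})

test_that("median-ratio normalization equalizes a scaled replicate", {
  pep <- make_peptides(data.frame(
    sequence = paste0("P", 1:6, "K"), modifications = "Unmodified",
    missed_cleavages = 0L, proteins = "A", unique = TRUE,
    intensity_s1 = c(10, 8, 6, 4, 2, 1)))
  pep$intensity_s2 <- pep$intensity_s1 * 2   # doubled load
  out <- median_ratio_normalize(pep, c("intensity_s1", "intensity_s2"))
  expect_equal(out$intensity_s2 / out$intensity_s1, rep(1, 6))
})
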