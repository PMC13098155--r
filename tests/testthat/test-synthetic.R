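test_that("generators are deterministic under a fixed seed", {
  gt <- default_ground_truth()
  b1 <- simulate_bundle(gt, seed = 99, n_plants = 4, n_nodules = 3,
                        n_bacteroids = c(bean = 20, pea = 20), n_packing = 3)
  b2 <- simulate_bundle(gt, seed = 99, n_plants = 4, n_nodules = 3,
                        n_bacteroids = c(bean = 20, pea = 20), n_packing = 3)
  expect_identical(b1, b2)
  b3 <- simulate_bundle(gt, seed = 100, n_plants = 4, n_nodules = 3,
                        n_bacteroids = c(bean = 20, pea = 20), n_packing = 3)
  expect_false(identical(b1$plant_table, b3$plant_table))
})

test_that("zero-CV ground truth gives degenerate plant rows at the means", {
  gt <- zero_noise_gt()
  pl <- generate_plants(gt$bean, n_plants = 3, seed = 1)
  m <- gt$bean$means
  expect_equal(pl$shoot_dry_mass_mg, rep(m$shoot_dry_mass_mg, 3))
  expect_equal(pl$nodule_dry_mass_mg, rep(m$nodule_dry_mass_mg, 3))
  expect_equal(pl$nodule_count, rep(round(m$nodule_count), 3))
  # all three rows identical in every measured column
  expect_equal(pl[1, -1], pl[2, -1], ignore_attr = TRUE)
  expect_error(generate_plants(gt$bean, n_plants = 1), ">= 2")
})

test_that("large cohorts recover the generator's own means (law of large numbers)", {
  gt <- default_ground_truth()
  pl <- generate_plants(gt$bean, n_plants = 1000, seed = 7)
  expect_lt(abs(mean(pl$shoot_dry_mass_mg) - 610) / 610, 0.02)
})

test_that("pipeline estimates lie within 3 standard errors of ground truth", {
  gt <- default_ground_truth()
  # cap the CVs at 20% for the recovery bound
  for (h in c("bean", "pea")) gt[[h]]$cv <- lapply(gt[[h]]$cv, min, 0.20)
  n <- 500
  pl <- generate_plants(gt$bean, n_plants = n, seed = 17)
  segs <- generate_segmentation(gt$bean, n_bacteroids = n, seed = 18)
  pk <- generate_packing(gt$bean, n_samples = n, seed = 19)
  m <- gt$bean$means
  checks <- list(
    list(pl$shoot_dry_mass_mg, m$shoot_dry_mass_mg),
    list(pl$nodule_dry_mass_mg, m$nodule_dry_mass_mg),
    list(pl$plant_nodule_volume_mm3, m$plant_nodule_volume_mm3),
    list(segs$volume_um3, m$bacteroid_volume_um3),
    list(pk$occupied_um3 / (pk$X_um * pk$Y_um * pk$Z_um), m$packing_fraction)
  )
  for (ch in checks) {
    x <- ch[[1]]; truth <- ch[[2]]
    expect_lt(abs(mean(x) - truth), 3 * sd(x) / sqrt(length(x)))
  }
})

test_that("section tables encode the planted colonization density", {
  gt <- default_ground_truth()
  bean <- generate_sections(gt$bean, 5, seed = 2)
  expect_equal(bean$A_i / bean$A_iz,
               rep(gt$bean$means$colonization_density, 5))
  pea <- generate_sections(gt$pea, 5, seed = 2)
  expect_equal(pea$A_i / pea$A_iz,
               rep(gt$pea$means$colonization_density, 5))
  # measurement invariants hold
  expect_true(all(bean$A_i <= bean$A_iz & bean$A_iz <= bean$A_nod))
  expect_true(all(pea$A_i <= pea$A_iz & pea$A_iz <= pea$A_body))
  expect_true(all(pea$h <= pea$c))
})

test_that("downstream census matches the count implied by ground truth at zero noise", {
  gt <- zero_noise_gt()
  for (h in c("bean", "pea")) {
    sec <- generate_sections(gt[[h]], 3, seed = 1)
    geo <- if (h == "bean") bean_nodule_volumes(sec) else pea_nodule_volumes(sec)
    segs <- generate_segmentation(gt[[h]], 30, seed = 1)
    pk <- generate_packing(gt[[h]], 3, seed = 1)
    cs <- bacteroid_census(segs, pk, V_i = mean(geo$V_i))
    m <- gt[[h]]$means
    implied <- m$infected_fraction * m$packing_fraction *
      m$section_nodule_volume_mm3 * unit_registry$mm3_to_um3 /
      m$bacteroid_volume_um3
    expect_equal(cs$bacteroids_per_nodule, implied, tolerance = 0.01)
  }
})

test_that("peptide tables satisfy the generator contracts", {
  gt <- default_ground_truth()
  pep <- generate_peptide_table(gt, n_reps = 2, seed = 5)
  p <- pep$peptides
  # Hi3 standard present with qualifying peptides in every sample
  expect_true("P00489" %in% p$proteins)
  # decoy rows exist and are the only filter-violating rows
  expect_true(any(p$missed_cleavages > 0))
  expect_true(any(.mod <- !(p$modifications %in% c("Unmodified", "Oxidation (M)"))))
  # some sequences occur both unmodified and oxidized
  both <- tapply(p$modifications, p$sequence, function(x) {
    all(c("Unmodified", "Oxidation (M)") %in% x)
  })
  expect_true(any(both))
  # strict-mode generation refuses panels with < 3 peptides
  gt_bad <- gt
  gt_bad$protein_panel$n_peptides[1] <- 2L
  expect_error(generate_peptide_table(gt_bad), ">= 3")
})

test_that("peptide TSV round-trips through the MaxQuant dialect", {
  gt <- default_ground_truth()
  pep <- generate_peptide_table(gt, n_reps = 2, seed = 5)
  path <- tempfile(fileext = ".tsv")
  write_peptide_table(pep$peptides, path)
  header <- readLines(path, n = 1)
  expect_match(header, "Sequence\tModifications\tMissed cleavages\tProteins\tUnique")
  expect_match(header, "Intensity bean_rep1")
  back <- read_peptide_table(path)
  expect_equal(back$sequence, pep$peptides$sequence)
  expect_equal(back$intensity_pea_rep2, pep$peptides$intensity_pea_rep2)
  expect_true(is.logical(back$unique))
  unlink(path)
})
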