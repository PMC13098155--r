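test_that("sphere volume from section matches closed forms and conventions", {
  # unit sphere: A = pi r^2 with r = 1, Feret diameter 2
  expect_equal(sphere_volume_from_section(pi, 2), 4 * pi / 3)
  # section that inverts to a typical bean nodule volume
  expect_equal(sphere_volume_from_section(4.0239, 2.2634), 6.07,
               tolerance = 1e-3)
  # the literal (radius) convention is exactly twice the diameter convention
  for (i in 1:10) {
    A <- runif(1, 0.5, 10); Fd <- runif(1, 0.5, 5)
    expect_equal(sphere_volume_from_section(A, Fd, "radius"),
                 2 * sphere_volume_from_section(A, Fd, "diameter"))
  }
  # max/min Feret pair: mean of the two volumes
  expect_equal(sphere_volume_from_section(3, cbind(2, 1)),
               mean(c(sphere_volume_from_section(3, 2),
                      sphere_volume_from_section(3, 1))))
  expect_error(sphere_volume_from_section(-1, 2), "must be > 0")
})

test_that("cap volume: hemisphere closed form, literal mode, quadrature oracle", {
  # c = 2, h = 1 with half-chord base radius 1 is a hemisphere of r = 1
  expect_equal(cap_volume(2, 1), 2 * pi / 3)
  # literal full-chord evaluation
  expect_equal(cap_volume(2, 1, "full_chord"), 13 * pi / 6)
  # half-chord formula agrees with numerical integration of the cap
  expect_equal(cap_volume(1.5, 0.4), cap_volume_quadrature(0.75, 0.4),
               tolerance = 0.005)
  set.seed(11)
  for (i in 1:50) {
    cc <- runif(1, 0.5, 3); hh <- runif(1, 0.1, cc)
    expect_equal(cap_volume(cc, hh), cap_volume_quadrature(cc / 2, hh),
                 tolerance = 0.005)
  }
  expect_error(cap_volume(0, 1), "must be > 0")
})

test_that("cylinder volume from section area and midline length", {
  # l = 2, d = 1 rectangle: pi (d/2)^2 l = pi/2
  expect_equal(cylinder_volume(2, 2), pi / 2)
  # direct evaluation cross-checked against pi (d/2)^2 l with d = A / l
  d <- 4.2 / 3.0
  expect_equal(cylinder_volume(4.2, 3.0), pi * (d / 2)^2 * 3.0)
  expect_equal(cylinder_volume(4.2, 3.0), 4.618, tolerance = 1e-3)
  # homogeneity: volume is degree 2 in area
  expect_equal(cylinder_volume(2 * 4.2, 3.0), 4 * cylinder_volume(4.2, 3.0))
})

test_that("colonization fraction is the bounded area ratio", {
  expect_equal(colonization_fraction(2.1, 2.1), 1)
  expect_equal(colonization_fraction(0, 2.1), 0)
  expect_equal(colonization_fraction(0.53, 2.1), 0.2523810, tolerance = 1e-6)
  expect_error(colonization_fraction(3, 2.1), "exceed")
})

test_that("whole-nodule volume is monotone in each positive measurement", {
  base_b <- data.frame(A_nod = 3, F_dmax = 2.2, F_dmin = 1.8, A_iz = 1.5,
                       F_dmax_iz = 1.4, F_dmin_iz = 1.2, A_i = 0.9)
  v0 <- bean_nodule_volumes(base_b)$V_n
  for (col in c("A_nod", "F_dmax", "F_dmin")) {
    m <- base_b; m[[col]] <- m[[col]] * 1.3
    expect_gt(bean_nodule_volumes(m)$V_n, v0)
  }
  base_p <- data.frame(c = 1.4, h = 0.5, A_body = 4, l_c = 3, A_iz = 2,
                       l_iz = 2.7, A_i = 1.4)
  v0 <- pea_nodule_volumes(base_p)$V_n
  for (col in c("c", "h", "A_body")) {
    m <- base_p; m[[col]] <- m[[col]] * 1.3
    expect_gt(pea_nodule_volumes(m)$V_n, v0)
  }
})

test_that("bean volumes: zero infected area zeroes V_i and leaves V_n intact", {
  m <- data.frame(A_nod = 3, F_dmax = 2.2, F_dmin = 1.8, A_iz = 1.5,
                  F_dmax_iz = 1.4, F_dmin_iz = 1.2, A_i = 0)
  out <- bean_nodule_volumes(m)
  expect_equal(out$V_i, 0)
  expect_equal(out$V_n, bean_nodule_volumes(transform(m, A_i = 0.5))$V_n)
})

test_that("pea volumes: vanishing cap leaves only the cylindrical body", {
  body <- data.frame(c = 1.4, h = 1e-9, A_body = 4, l_c = 3, A_iz = 2,
                     l_iz = 2.7, A_i = 1.4)
  expect_equal(pea_nodule_volumes(body)$V_n, cylinder_volume(4, 3),
               tolerance = 1e-6)
})

test_that("zero-noise synthetic sections round-trip through the geometry module", {
  gt <- zero_noise_gt()
  # bean: a nodule drawn by displacement volume inverts to the same volume
  gt$bean$means$section_nodule_volume_mm3 <- 6.07
  sec <- generate_sections(gt$bean, n_nodules = 3, seed = 1)
  out <- bean_nodule_volumes(sec)
  expect_equal(out$V_n, rep(6.07, 3), tolerance = 1e-8)
  expect_equal(out$f_c, rep(gt$bean$means$colonization_density, 3))
  expect_equal(out$V_i / out$V_n, rep(gt$bean$means$infected_fraction, 3),
               tolerance = 1e-8)
  # pea: cap + cylinder reconstruction
  psec <- generate_sections(gt$pea, n_nodules = 3, seed = 1)
  pout <- pea_nodule_volumes(psec)
  expect_equal(pout$V_n, rep(gt$pea$means$section_nodule_volume_mm3, 3),
               tolerance = 1e-6)
  expect_equal(pout$V_i / pout$V_n, rep(gt$pea$means$infected_fraction, 3),
               tolerance = 1e-6)
})

test_that("synthetic cohorts of 8 nodules recover the cohort-mean volumes", {
  gt <- default_ground_truth()
  bean <- bean_nodule_volumes(generate_sections(gt$bean, 8, seed = 101))
  pea <- pea_nodule_volumes(generate_sections(gt$pea, 8, seed = 102))
  # stochastic: sample mean within 2 sample standard errors of the target
  expect_lt(abs(mean(bean$V_n) - 5.40), 2 * sd(bean$V_n) / sqrt(8))
  expect_lt(abs(mean(pea$V_n) - 5.16), 2 * sd(pea$V_n) / sqrt(8))
})
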