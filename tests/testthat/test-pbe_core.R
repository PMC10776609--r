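test_that("uniform grids have the expected class widths", {
  expect_equal(size_grid(0, 60e-6, 30)$dr, 2e-6)
  expect_equal(size_grid(0, 60e-6, 60)$dr, 1e-6)
  expect_equal(size_grid(0, 60e-6, 15)$dr, 4e-6)
  g <- size_grid(0, 60e-6, 30)
  expect_length(g$r_faces, 31)
  expect_true(all(abs(diff(g$r_faces) - g$dr) < 1e-12 * g$dr))
  expect_error(size_grid(10e-6, 10e-6, 30), "r_max")
  expect_error(size_grid(0, 60e-6, 2), "3 size classes")
})

test_that("minmod selects the smallest-magnitude agreeing slope", {
  expect_equal(minmod(2, 3, 1), 1)
  expect_equal(minmod(-2, 1, 3), 0)
  expect_equal(minmod(-2, -1, -3), -1)
  expect_equal(minmod(0, 1, 2), 0)
  expect_error(minmod(), "at least one")
})

test_that("limited slopes are exact on linear data and vanish at extrema", {
  g <- size_grid(0, 60e-6, 30)
  a <- 2e19
  f <- a * g$r_centers + 1e14
  s <- limited_slopes(f, g)
  expect_equal(s[2:29], rep(a, 28), tolerance = 1e-12)

  # local maximum gives mixed-sign candidates
  f2 <- rep(1, 30); f2[10] <- 3; f2[11] <- 2
  expect_equal(limited_slopes(f2, g)[10], 0)

  expect_equal(limited_slopes(rep(5e14, 30), g), rep(0, 30))
  expect_error(limited_slopes(f, g, theta = 2.5), "theta")
})

test_that("growth flux divergence is conservative with closed boundaries", {
  g <- size_grid(0, 60e-6, 30)
  f <- numeric(30); f[10] <- 1e15
  d <- growth_flux_divergence(f, 1e-6, g, "growth")
  expect_equal(sum(d) * g$dr, 0, tolerance = 1e-10 * 1e15 * 1e-6)

  # uniform field, constant G: interior classes are unchanged
  fu <- rep(1e15, 30)
  du <- growth_flux_divergence(fu, 1e-6, g, "growth")
  expect_equal(du[2:29], rep(0, 28))

  expect_error(growth_flux_divergence(f, -1e-6, g), ">= 0")
  expect_error(growth_flux_divergence(f, rep(1e-6, 7), g), "per face")
})

test_that("number is conserved during growth advection away from boundaries", {
  g <- size_grid(0, 60e-6, 30)
  f0 <- jetcryst:::class_average(profile_function("gaussian"), g)
  out <- advect_profile(f0, 1e-6, 10, g, "growth")
  expect_equal(sum(out$f) * g$dr, sum(f0) * g$dr, tolerance = 1e-10)
})

test_that("nucleation source deposits into the first class only", {
  g <- size_grid(0, 60e-6, 30)
  expect_equal(nucleation_source(0, g), numeric(30))
  s <- nucleation_source(1e12, g)
  expect_equal(s[1], 1e12 / 2e-6)
  expect_equal(sum(s) * g$dr, 1e12)   # delta-source integral conserved
  expect_equal(nucleation_source(3e11, g) + nucleation_source(7e11, g),
               nucleation_source(1e12, g))
  expect_error(nucleation_source(-1, g), ">= 0")
})

test_that("number-to-mass conversion integrates the third moment", {
  g1 <- size_grid(2e-6, 4e-6, 4)   # probe a single known face pair
  # independent arithmetic: rho_c k_v f (r_hi^4 - r_lo^4) / 4 on class 1
  f <- c(1e12, 0, 0, 0)
  fw <- number_to_mass(f, g1, rho_c = 1273, k_v = pi / 6)
  r_lo <- 2e-6; r_hi <- 2e-6 + g1$dr
  expect_equal(fw[1], 1273 * (pi / 6) * 1e12 * (r_hi^4 - r_lo^4) / 4,
               tolerance = 1e-12)
  expect_equal(fw[2:4], rep(0, 3))
  expect_equal(number_to_mass(2 * f, g1, 1273, pi / 6), 2 * fw)

  # mass of a full class span equals the analytic integral of r^3
  g <- size_grid(0, 60e-6, 30)
  fu <- rep(1e15, 30)
  expect_equal(sum(number_to_mass(fu, g, 1273, pi / 6)),
               1273 * (pi / 6) * 1e15 * (60e-6)^4 / 4, tolerance = 1e-12)
  expect_error(number_to_mass(fu, g, rho_c = 0), "positive")
})

test_that("CSD summaries reproduce known moments", {
  g <- size_grid(0, 60e-6, 30)
  # all mass in one class
  f <- numeric(30); f[6] <- 1e15   # centered at 11 um
  cs <- csd_summary(f, g)
  expect_equal(cs$mean_num, g$r_centers[6])
  expect_equal(cs$mean_mass, g$r_centers[6])
  expect_equal(cs$sd_num, 0)
  expect_equal(cs$total_number, 1e15 * g$dr)

  # symmetric distribution: mean at the center of symmetry
  fs <- numeric(30); fs[c(10, 20)] <- 1e15
  expect_equal(csd_summary(fs, g)$mean_num,
               mean(g$r_centers[c(10, 20)]))

  # exponential (MSMPR) distribution: number mean G*tau, mass mean 4 G*tau
  gf <- size_grid(0, 200e-6, 800)
  L <- 10e-6
  fe <- msmpr_analytic(1e12, 1e-6, 10, gf)
  cse <- csd_summary(fe, gf)
  expect_equal(cse$mean_num, L, tolerance = 0.02)
  expect_equal(cse$mean_mass, 4 * L, tolerance = 0.02)

  # empty field is flagged
  expect_true(csd_summary(numeric(30), g)$empty)
})

test_that("growth advection converges to the analytic oracle at second order", {
  drs <- c(4, 2, 1, 0.5) * 1e-6
  prof <- profile_function("gaussian", center = 40e-6, sigma = 10e-6)
  errs <- vapply(120e-6 / drs, advection_l1_error, numeric(1),
                 profile = prof, displacement = 20e-6, r_max = 120e-6)
  co <- convergence_order(drs, errs)
  expect_true(co$monotone)
  expect_gte(co$order, 1.8)
})

test_that("advection errors match the independently computed reference", {
  # frozen from an independent implementation of the same semi-discrete
  # scheme (numpy/scipy, RK45 at rtol 1e-10): 0.0967 at dr = 2 um and
  # 0.0309 at dr = 1 um for the sigma = 4 um Gaussian advected 10 um;
  # a small CFL isolates the spatial error the reference measures
  e2 <- advection_l1_error(30, cfl = 0.05)
  e1 <- advection_l1_error(60, cfl = 0.05)
  expect_equal(e2, 0.0967, tolerance = 0.01)
  expect_equal(e1, 0.0309, tolerance = 0.01)
  expect_gt(e2 / e1, 3)
})

test_that("the scheme is TVD and positivity-preserving on random profiles", {
  set.seed(101)
  g <- size_grid(0, 60e-6, 30)
  for (k in 1:20) {
    f0 <- runif(30)^2 * 1e15
    f0[26:30] <- 0                     # support away from the outer face
    out <- advect_profile(f0, 1e-6, 8, g, "growth")
    expect_lte(max(out$f), max(f0) * (1 + 1e-12))
    expect_gte(out$min_before_clip, -1e-12 * max(f0))
  }
})

test_that("dissolution reverses growth within twice the one-way error", {
  g <- size_grid(0, 60e-6, 30)
  prof <- profile_function("gaussian")
  f0 <- jetcryst:::class_average(prof, g)
  fwd <- advect_profile(f0, 1e-6, 10, g, "growth")$f
  back <- advect_profile(fwd, 1e-6, 10, g, "dissolution")$f
  e_one <- sum(abs(fwd - analytic_advection(prof, g, 1e-6, 10)))
  e_round <- sum(abs(back - f0))
  expect_lte(e_round, 2 * e_one)
})

test_that("growth respects the outer zero-flux boundary with an overflow audit", {
  g <- size_grid(0, 60e-6, 30)
  f <- numeric(30); f[30] <- 1e15
  d <- growth_flux_divergence(f, 1e-6, g, "growth")
  expect_gt(attr(d, "outer_overflow"), 0)
  expect_equal(sum(d) * g$dr, 0, tolerance = 1)   # retained, not lost
})
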