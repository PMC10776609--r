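test_that("solubility matches direct evaluation of the correlation", {
  # pure methanol at the reference temperature: exponential factor is 1
  expect_equal(solubility(0, 296), 0.001 * 33.089, tolerance = 1e-12)

  # hand-evaluated cubic branch at the boundary composition
  w <- 45.67
  cubic <- 0.001 * (-2.7455e-4 * w^3 + 3.3716e-2 * w^2 - 1.6704 * w + 33.089)
  expect_equal(solubility(w, 296), cubic, tolerance = 1e-12)
  expect_equal(cubic, 9.7236530859e-4, tolerance = 1e-9)

  # temperature factor applied independently
  for (T_K in c(280, 296, 298.15, 310)) {
    expect_equal(solubility(10, T_K),
                 0.001 * exp(15.45763 * (1 - 296 / T_K)) *
                   (-2.7455e-4 * 1e3 + 3.3716e-2 * 1e2 - 16.704 + 33.089),
                 tolerance = 1e-12)
  }
})

test_that("upper solubility branch is continuous by default, discontinuous as printed", {
  lo <- solubility(45.67, 296)
  hi <- solubility(45.67 + 1e-9, 296)
  expect_lt(abs(hi / lo - 1), 0.005)

  hi_printed <- solubility(45.67 + 1e-9, 296, branch_mode = "as_printed")
  expect_gt(hi_printed / lo, 80)   # ~85x jump is reported, not hidden
  expect_lt(hi_printed / lo, 90)
})

test_that("solubility is monotone: decreasing in w_as, increasing in T", {
  w <- seq(0, 100, by = 0.5)
  expect_true(all(diff(solubility(w, 298.15)) < 0))
  T_K <- seq(278, 320, by = 1)
  expect_true(all(diff(solubility(30, T_K)) > 0))
})

test_that("solubility rejects out-of-domain inputs", {
  expect_error(solubility(-1, 296), "w_as")
  expect_error(solubility(101, 296), "w_as")
  expect_error(solubility(50, 0), "T_K")
})

test_that("supersaturation ratio follows its definition", {
  st <- supersaturation(solubility(20, 300), 20, 300)
  expect_equal(st$S, 1, tolerance = 1e-12)
  expect_equal(supersaturation(0, 20, 300)$S, 0)
  # concentration chosen as 8.8x the solubility of the pure-methanol feed
  expect_equal(supersaturation(0.3255, 0, 298.15)$S, 8.8, tolerance = 1e-3)
  expect_error(supersaturation(-0.1, 0, 298.15), "non-negative")
})

test_that("nucleation and growth closed forms match independent arithmetic", {
  # ln S = 1 exactly
  r <- kinetic_rates(exp(1))
  expect_equal(r$B_hom, 6.97e14 * exp(-15.8), tolerance = 1e-12)
  expect_equal(r$B_het, 2.18e8 * exp(-0.994), tolerance = 1e-12)
  expect_equal(r$B, r$B_hom + r$B_het, tolerance = 1e-15)
  expect_equal(r$G, 8.33e-30 * 2460^6.7, tolerance = 1e-12)

  # 20 sampled states against plainly-written formulas
  S <- seq(1.2, 20, length.out = 20)
  expect_equal(nucleation_rate(S)$B,
               6.97e14 * exp(-15.8 / log(S)^2) +
                 2.18e8 * exp(-0.994 / log(S)^2),
               tolerance = 1e-12)
  expect_equal(growth_rate(S), 8.33e-30 * (2.46e3 * log(S))^6.7,
               tolerance = 1e-12)
})

test_that("rates vanish at and below saturation", {
  for (S in c(0, 0.3, 1)) {
    r <- kinetic_rates(S)
    expect_identical(r$B, 0)
    expect_identical(r$G, 0)
  }
  expect_error(growth_rate(-1), "non-negative")
  expect_error(nucleation_rate(-0.5), "non-negative")
})

test_that("rates are strictly increasing in S above saturation", {
  S <- seq(1.01, 20, length.out = 100)
  expect_true(all(diff(nucleation_rate(S)$B) > 0))
  expect_true(all(diff(growth_rate(S)) > 0))
})

test_that("pointwise rates at the reported average supersaturation are plausible", {
  # printed volume-averaged rates differ by nonlinear averaging only
  S_bar <- 6.8388
  expect_equal(nucleation_rate(S_bar)$B, 9.9818e12, tolerance = 0.05)
  expect_equal(growth_rate(S_bar), 3.5706e-5, tolerance = 0.05)
})

test_that("mix_streams blends compositions with exact mass conservation", {
  # symmetric blend of methanol solution and water
  a <- list(mdot = 1e-3, C = 0, w_as = 0, T_K = 298.15)
  b <- list(mdot = 1e-3, C = 0, w_as = 100, T_K = 298.15)
  expect_equal(mix_streams(a, b)$w_as, 50)

  # zero-flow stream is an identity
  sol <- list(mdot = 2e-3, C = 0.3255, w_as = 0, T_K = 300)
  none <- list(mdot = 0, C = 0, w_as = 100, T_K = 298.15)
  m <- mix_streams(sol, none)
  expect_equal(m$C, sol$C)
  expect_equal(m$w_as, sol$w_as)
  expect_equal(m$T_K, sol$T_K)

  # 1:1 by solvent mass with pure water halves C and sets w_as = 50
  msolv <- 1e-3
  a <- list(mdot = msolv * (1 + 0.3255), C = 0.3255, w_as = 0, T_K = 298.15)
  b <- list(mdot = msolv, C = 0, w_as = 100, T_K = 298.15)
  m <- mix_streams(a, b)
  expect_equal(m$C, 0.16275, tolerance = 1e-12)
  expect_equal(m$w_as, 50, tolerance = 1e-12)

  expect_error(mix_streams(none, none), "positive mass flow")
})

test_that("mix_streams conserves each component for random stream pairs", {
  set.seed(7)
  for (k in 1:20) {
    a <- list(mdot = runif(1, 0, 2e-3), C = runif(1, 0, 0.4),
              w_as = runif(1, 0, 100), T_K = runif(1, 280, 320))
    b <- list(mdot = runif(1, 0, 2e-3), C = runif(1, 0, 0.4),
              w_as = runif(1, 0, 100), T_K = runif(1, 280, 320))
    m <- mix_streams(a, b)
    comp <- function(s) {
      ms <- s$mdot / (1 + s$C)
      c(ms * s$C, ms * (1 - s$w_as / 100), ms * s$w_as / 100)
    }
    tot_in <- comp(a) + comp(b)
    solv_out <- m$mdot_solvents
    tot_out <- c(solv_out * m$C, solv_out * (1 - m$w_as / 100),
                 solv_out * m$w_as / 100)
    expect_equal(tot_out, tot_in, tolerance = 1e-12)
  }
})

test_that("feed concentration inverts the supersaturation definition", {
  C <- feed_concentration(8.8, 0, 298.15)
  expect_equal(supersaturation(C, 0, 298.15)$S, 8.8, tolerance = 1e-12)
})

test_that("physical constants carry the fixed property values", {
  const <- physical_constants()
  expect_equal(const$rho_water, 997.1)
  expect_equal(const$rho_methanol, 782)
  expect_equal(const$rho_crystal, 1273)
  expect_equal(physical_constants(k_v = 1)$k_v, 1)
  expect_error(physical_constants(bogus = 1), "unknown physical constant")
})
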