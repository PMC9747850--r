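test_that("line-source geometry factor matches the integral oracle", {
  for (case in list(c(1, 90), c(2, 90), c(0.5, 30), c(3, 120), c(1, 5))) {
    expect_equal(geometry_factor_line(case[1], case[2], 0.35),
                 oracle_gl(case[1], case[2], 0.35), tolerance = 1e-9)
  }
  # point-source limit
  expect_equal(geometry_factor_line(2, 90, 1e-9), 0.25, tolerance = 1e-6)
  # on-axis closed form, cross-checked against the same integral
  expect_equal(geometry_factor_line(1, 0, 0.35), 1 / (1 - 0.35^2 / 4),
               tolerance = 1e-12)
  expect_equal(geometry_factor_line(1, 0, 0.35), oracle_gl(1, 0, 0.35),
               tolerance = 1e-9)
  # continuity across theta -> 0
  expect_equal(geometry_factor_line(1, 1e-5, 0.35),
               geometry_factor_line(1, 0, 0.35), tolerance = 1e-8)
  # far field: G r^2 -> 1, monotone approach
  r <- c(5, 10, 50, 100)
  gr2 <- geometry_factor_line(r, 90, 0.35) * r^2
  expect_true(all(diff(gr2) > 0))
  expect_equal(gr2[4], 1, tolerance = 1e-5)
  # a point on the active line is rejected
  expect_error(geometry_factor_line(0.1, 0, 0.35), "active line")
})

test_that("dose-rate constant is the unit-consistent ratio", {
  # numerically equal inputs give Lambda = 1
  expect_equal(dose_rate_constant(2.5e-13, 2.5e-13)$lambda, 1)
  d <- dose_rate_constant(1.3e-13, 1.2e-13, u_d = 0.003, u_s = 0.004)
  expect_equal(d$lambda, 1.3 / 1.2)
  expect_equal(d$rel_unc_k1, sqrt(0.003^2 + 0.004^2))
  expect_equal(d$u_k2, 2 * d$u_k1)
  expect_error(dose_rate_constant(1, 1, normalization_d = "per_history",
                                  normalization_s = "per_decay"),
               "normalisation")
})

test_that("consensus construction averages and rounds half-up", {
  expect_identical(consensus_dose_rate_constant(c(1.118, 1.115)), 1.117)
  expect_identical(consensus_dose_rate_constant(), 1.117)
  expect_identical(round_half_up(0.125, 2), 0.13)
  expect_identical(round_half_up(51.715, 2), 51.72)
  ref <- lambda_reference()
  expect_equal(ref$consensus, consensus_dose_rate_constant(ref$sources))
})

test_that("radial dose function normalises and inverts the geometry factor", {
  r <- c(0.5, 1, 2, 3, 5)
  gl <- geometry_factor_line(r, 90, 0.35)
  # doses proportional to G alone: g_L identically 1
  g <- radial_dose_function(r, 7 * gl)
  expect_equal(g$g_L, rep(1, 5))
  # doses G * exp(-0.03 r): g_L(r) = exp(-0.03 (r - 1))
  g2 <- radial_dose_function(r, gl * exp(-0.03 * r))
  expect_equal(g2$g_L, exp(-0.03 * (r - 1)), tolerance = 1e-12)
  expect_identical(g2$g_L[r == 1], 1)
  # reference radius must be present
  expect_error(radial_dose_function(c(0.5, 2), c(1, 1)), "r0")
})

test_that("anisotropy function normalises at theta0 for every radius", {
  grid <- expand.grid(r = c(1, 3), theta = c(10, 30, 90, 150))
  gl <- geometry_factor_line(grid$r, grid$theta, 0.35)
  f <- anisotropy_function(grid$r, grid$theta, 3 * gl)
  expect_equal(f$F, rep(1, nrow(grid)))
  # halved dose at theta = 10 only -> F = 0.5 there (direct substitution)
  dose <- 3 * gl
  dose[grid$theta == 10] <- dose[grid$theta == 10] / 2
  f2 <- anisotropy_function(grid$r, grid$theta, dose)
  expect_equal(f2$F[f2$theta == 10], c(0.5, 0.5))
  expect_equal(f2$F[f2$theta == 90], c(1, 1))
  expect_error(anisotropy_function(c(1, 1), c(10, 30), c(1, 1)), "reference")
})

test_that("forward TG-43 dose reproduces its factor decomposition", {
  g_tab <- data.frame(r = c(0.5, 1, 2, 5), g_L = c(1.02, 1, 0.97, 0.90))
  f_tab <- expand.grid(theta = c(0, 30, 90, 150, 180), r = c(0.5, 1, 2, 5))
  f_tab$F <- ifelse(f_tab$theta == 90, 1,
                    0.7 + 0.3 * sin(f_tab$theta * pi / 180))
  params <- tg43_parameters(1.117, 0.35, g_tab,
                            f_tab[, c("r", "theta", "F")])
  # reference point with S_K = 1 U: dose rate equals Lambda
  expect_equal(tg43_dose(params, 1, 1, 90), 1.117)
  # hand substitution of the five factors at a tabulated node
  g0 <- geometry_factor_line(1, 90, 0.35)
  hand <- 10 * 1.117 * geometry_factor_line(2, 30, 0.35) / g0 * 0.97 *
    (0.7 + 0.3 * sin(30 * pi / 180))
  expect_equal(tg43_dose(params, 10, 2, 30), hand, tolerance = 1e-12)
  # inverse square when g = F = 1 and L -> 0
  p0 <- tg43_parameters(1, 1e-9,
                        data.frame(r = c(0.5, 1, 10), g_L = c(1, 1, 1)))
  expect_equal(tg43_dose(p0, 1, 2, 90), 1 / 4, tolerance = 1e-6)
  # extrapolation guard and nearest-edge override
  expect_error(tg43_dose(params, 1, 9, 90), "allow_nearest")
  expect_equal(tg43_dose(params, 1, 9, 90, allow_nearest = TRUE),
               1.117 * geometry_factor_line(9, 90, 0.35) / g0 * 0.90)
})

test_that("round trip: parameters extracted from a dose map reproduce it", {
  # build a synthetic dose map with a known angular/radial structure
  r <- c(0.5, 1, 2, 3, 5)
  theta <- c(10, 30, 60, 90, 120, 170)
  grid <- expand.grid(r = r, theta = theta)
  true_g <- function(r) exp(-0.02 * (r - 1))
  true_f <- function(r, th) 1 - 0.2 * cos(th * pi / 180)^2
  dose <- 5 * geometry_factor_line(grid$r, grid$theta, 0.35) *
    true_g(grid$r) * true_f(grid$r, grid$theta)
  gt <- radial_dose_function(r, dose[grid$theta == 90][order(r)], 0.35)
  ft <- anisotropy_function(grid$r, grid$theta, dose)
  # with S_K = 1, Lambda absorbs the overall scale: the reference dose
  lam <- dose[grid$r == 1 & grid$theta == 90]
  params <- tg43_parameters(lam, 0.35, gt, ft)
  rebuilt <- tg43_dose(params, 1, grid$r, grid$theta)
  expect_equal(rebuilt, dose, tolerance = 1e-10)
})

test_that("geometry-factor extraction flattens a pure line-source profile", {
  pos <- seq(-5, 5, 0.5)
  pos <- pos[abs(pos) > 0.2]
  # profile along z through the source centre, source axis along x
  r <- abs(pos)
  gl <- geometry_factor_line(r, 90, 0.35)
  out <- extract_geometry_factor(pos, 4 * gl)
  expect_equal(out$adjusted_dose,
               rep(4 * geometry_factor_line(1, 90, 0.35), length(pos)),
               tolerance = 1e-12)
  # multiplier is 1 at the reference point
  out2 <- extract_geometry_factor(1, 1)
  expect_equal(out2$multiplier, 1)
  # multiplier at r = 2 equals G(1,90)/G(2,90) from the integral oracle
  out3 <- extract_geometry_factor(2, 1)
  expect_equal(out3$multiplier, oracle_gl(1, 90, 0.35) /
                 oracle_gl(2, 90, 0.35), tolerance = 1e-9)
  # a point on the active segment is excluded and flagged
  expect_warning(
    out4 <- extract_geometry_factor(c(0.1, 1), c(1, 1),
                                    line = list(point = c(0, 0, 0),
                                                direction = c(1, 0, 0))),
    "excluded")
  expect_true(out4$excluded[1])
  expect_true(is.na(out4$adjusted_dose[1]))
})

test_that("tg43 parameter container validates its normalisation", {
  expect_error(tg43_parameters(1.1, 0.35,
                               data.frame(r = c(1, 2), g_L = c(1.01, 0.9))),
               "g_L")
  expect_error(tg43_parameters(1.1, 0.35,
                               data.frame(r = c(2, 3), g_L = c(1, 0.9))),
               "r0")
})
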