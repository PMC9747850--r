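water_cube <- function(n = 41, half = 2.05) {
  voxel_phantom(array(1L, c(n, n, n)), "water",
                origin_cm = rep(-half, 3))
}
point_source <- function(E = 0.3) {
  list(spectrum = E, geometry = NULL, center_cm = c(0, 0, 0), axis = "x")
}

test_that("voxel traversal partitions the in-grid segment exactly", {
  ph <- water_cube(10, 0.5)  # 10 x 10 x 10 mm box at origin corner -0.5
  # axis-aligned ray through a full row: 10 chords of 0.1 cm
  tv <- trace_voxels(c(-1, -0.45, -0.45), c(1, 0, 0), ph)
  expect_equal(nrow(tv), 10L)
  expect_equal(tv$chord_cm, rep(0.1, 10), tolerance = 1e-12)
  # in-plane 45 degree diagonal across one voxel
  tv2 <- trace_voxels(c(-0.5, -0.5, -0.45) + 1e-9, c(1, 1, 0), ph)
  expect_equal(tv2$chord_cm[1], sqrt(2) * 0.1, tolerance = 1e-6)
  # random rays: total chord equals the analytic box intersection
  set.seed(1)
  for (k in 1:1000) {
    p <- runif(3, -2, 2)
    d <- rnorm(3)
    tv3 <- trace_voxels(p, d, ph)
    expect_lt(abs(sum(tv3$chord_cm) -
                    oracle_box_intersection(p, d, rep(-0.5, 3),
                                            rep(0.5, 3))), 1e-9)
  }
  # a ray that misses the grid returns no chords
  expect_equal(nrow(trace_voxels(c(5, 5, 5), c(1, 0, 0), ph)), 0L)
})

test_that("TLE reproduces the closed-form primary kerma in uniform water", {
  lib <- material_library()
  E <- 0.3
  mu <- mixture_coefficient(lib$water, E) * lib$water$density
  muen <- mixture_coefficient(lib$water, E, "energy_absorption")
  edges <- c(0.95, 1.05, 1.95, 2.05, 4.95, 5.05)
  sk <- sphere_kerma(E, geometry = NULL, r_edges_cm = edges,
                     n_histories = 4e5, seed = 11, primaries_only = TRUE)
  for (i in c(1, 3, 5)) {
    expected <- oracle_primary_shell_kerma(E, mu, muen, edges[i],
                                           edges[i + 1])
    got <- sk$dose_per_history[sk$r_lo == edges[i]]
    expect_lt(abs(got / expected - 1), 0.01)
  }
})

test_that("in-vacuo kerma follows the inverse-square law", {
  shells <- lapply(c(10, 50, 100), function(d)
    sphere_kerma(0.3, geometry = NULL,
                 r_edges_cm = c(d - 0.25, d + 0.25),
                 medium = "vacuum", scoring_material = "air",
                 n_histories = 2e5, seed = 21, sphere_radius_cm = 101))
  d_eff2 <- vapply(shells, function(s)
    (s$r_lo^2 + s$r_lo * s$r_hi + s$r_hi^2) / 3, numeric(1))
  k2 <- vapply(shells, function(s) s$dose_per_history, numeric(1)) * d_eff2
  relunc <- vapply(shells, function(s) s$rel_unc, numeric(1))
  # for a point source in vacuo every history crosses every shell with a
  # purely radial chord, so the product is constant to machine precision
  for (i in 2:3)
    expect_lt(abs(k2[i] / k2[1] - 1),
              2 * sqrt(relunc[i]^2 + relunc[1]^2) + 1e-12)
  # and matches the analytic point-source air kerma E muen_air / 4 pi
  lib <- material_library()
  muen_air <- mixture_coefficient(lib$air, 0.3, "energy_absorption")
  analytic <- 0.3 * muen_air / (4 * pi) * 1.602176634e-10
  expect_lt(abs(k2[3] / analytic - 1), 3 * relunc[3] + 0.005)
})

test_that("air-kerma strength scoring is distance independent in vacuo", {
  sp <- load_spectrum()
  g <- gmp_source()
  a <- score_air_kerma_strength(sp, g, n_histories = 2e5, seed = 31,
                                distance_cm = 50)
  b <- score_air_kerma_strength(sp, g, n_histories = 2e5, seed = 32,
                                distance_cm = 100)
  expect_gt(a$s_k_per_history, 0)
  expect_lt(abs(a$s_k_per_history / b$s_k_per_history - 1),
            2 * sqrt(a$rel_unc^2 + b$rel_unc^2))
})

test_that("analog transport conserves energy to 1e-9 relative", {
  ph <- water_cube()
  res <- run_simulation(ph, point_source(),
                        run_config(5e4, seed = 41, scoring = "analog"))
  e <- res$energy_mev
  expect_lt(abs(e$emitted - e$deposited - e$escaped - e$void_banked) /
              e$emitted, 1e-9)
  # with the full spectrum and the encapsulated source as well
  src <- list(spectrum = load_spectrum(), geometry = gmp_source(),
              center_cm = c(0, 0, 0), axis = "x")
  res2 <- run_simulation(ph, src,
                         run_config(5e4, seed = 42, scoring = "analog"))
  e2 <- res2$energy_mev
  expect_lt(abs(e2$emitted - e2$deposited - e2$escaped - e2$void_banked) /
              e2$emitted, 1e-9)
})

test_that("simulation runs replay bit-identically under a fixed seed", {
  ph <- water_cube(21, 1.05)
  cfg <- run_config(2e4, seed = 5, scoring = "analog")
  a <- run_simulation(ph, point_source(), cfg)
  b <- run_simulation(ph, point_source(), cfg)
  expect_identical(a$dose, b$dose)
  expect_identical(a$rel_unc, b$rel_unc)
  s1 <- sphere_kerma(0.3, NULL, c(0.95, 1.05), n_histories = 2e4, seed = 8)
  s2 <- sphere_kerma(0.3, NULL, c(0.95, 1.05), n_histories = 2e4, seed = 8)
  expect_identical(s1$dose_per_history, s2$dose_per_history)
})

test_that("TLE and analog dose agree in uniform water beyond 1 cm", {
  ph <- water_cube()
  an <- run_simulation(ph, point_source(),
                       run_config(4e5, seed = 51, scoring = "analog"))
  tl <- run_simulation(ph, point_source(),
                       run_config(4e5, seed = 52, scoring = "tle"))
  ctr <- (1:41 - 0.5) * 0.1 - 2.05
  rr <- sqrt(outer(ctr^2, outer(ctr^2, ctr^2, "+"), "+"))
  m <- rr >= 1 & rr <= 1.4
  # aggregate over the shell: combined uncertainty of the two shell means
  ua <- sqrt(sum((an$dose[m] * an$rel_unc[m])^2, na.rm = TRUE)) /
    sum(an$dose[m])
  ut <- sqrt(sum((tl$dose[m] * tl$rel_unc[m])^2, na.rm = TRUE)) /
    sum(tl$dose[m])
  expect_lt(abs(mean(tl$dose[m]) / mean(an$dose[m]) - 1),
            3 * sqrt(ua^2 + ut^2))
})

test_that("Woodcock tracking matches grid tracking in expectation", {
  ph <- build_slab_phantom(6, carve_source = FALSE)
  src <- list(spectrum = load_spectrum(), geometry = gmp_source(),
              center_cm = attr(ph, "source_center_cm"), axis = "x")
  gr <- run_simulation(ph, src, run_config(2e5, seed = 61,
                                           scoring = "analog"))
  wc <- run_simulation(ph, src, run_config(2e5, seed = 62,
                                           scoring = "analog",
                                           tracking = "woodcock"))
  fg <- gr$energy_mev$deposited / gr$energy_mev$emitted
  fw <- wc$energy_mev$deposited / wc$energy_mev$emitted
  expect_lt(abs(fg - fw) / fg, 0.01)
})

test_that("uncertainty estimator follows the expected statistics", {
  # constant per-history scores: zero variance
  expect_equal(estimate_uncertainty(100, 100^2 / 1e4, 1e4), 0)
  # Bernoulli(1/2) score: relative SE ~ 1/sqrt(n) at n = 1e4
  set.seed(2)
  x <- rbinom(1e4, 1, 0.5)
  u <- estimate_uncertainty(sum(x), sum(x^2), 1e4)
  expect_lt(abs(u / 0.01 - 1), 0.2)
  # zero-score bins flagged undefined, n < 2 undefined
  expect_true(is.na(estimate_uncertainty(0, 0, 100)))
  expect_true(is.na(estimate_uncertainty(10, 4, 1)))
})

test_that("uncertainty halves when histories quadruple", {
  run_u <- function(n, seed) {
    s <- sphere_kerma(0.3, NULL, c(0.95, 1.05), n_histories = n,
                      seed = seed)
    s$rel_unc
  }
  u1 <- run_u(5e4, 71)
  u4 <- run_u(2e5, 72)
  expect_lt(abs(u1 / u4 - 2), 0.3)
})

test_that("run configuration guards its contract", {
  expect_error(run_config(1e4, primaries_only = TRUE, scoring = "analog"),
               "tle")
  expect_error(run_config(1e4, scoring = "tle", tracking = "woodcock"),
               "analog")
  expect_warning(run_config(3e9), "ceiling")
  ph <- water_cube(11, 0.55)
  expect_error(
    run_simulation(ph, list(spectrum = 0.3, geometry = NULL,
                            center_cm = c(9, 9, 9), axis = "x"),
                   run_config(10)),
    "outside")
})
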