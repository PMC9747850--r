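test_that("material library holds exactly the fifteen expected entries", {
  lib <- material_library()
  expect_setequal(names(lib),
                  c("titanium", "lung", "muscle", "bone", "adipose",
                    "cartilage", "stainless_steel", "peek", "pmma", "water",
                    "air", "vacuum", "iridium_seed", "steel_304",
                    "steel_316l"))
  expect_equal(lib$water$fractions[["H"]], 0.111894, tolerance = 1e-6)
  expect_equal(lib$water$fractions[["O"]], 0.888106, tolerance = 1e-6)
  expect_equal(lib$water$density, 1.0)
  expect_equal(lib$lung$density, 0.26)
  expect_equal(lib$steel_316l$density, 8.03)
  expect_equal(lib$steel_304$density, 5.6)
  expect_equal(lib$iridium_seed$fractions[["Ir"]], 1.0)
  for (m in lib)
    expect_lt(abs(sum(m$fractions) - 1), 1e-3)
})

test_that("titanium correction and strict mode behave as documented", {
  lib <- material_library()
  expect_equal(lib$titanium$fractions[["Ti"]], 0.90)
  expect_equal(lib$titanium$fractions[["Al"]], 0.06)
  strict <- material_library(strict = TRUE)
  # printed row Al 6 / Ti 9 / V 4 renormalised to its 19 percent sum
  expect_equal(strict$titanium$fractions[["Ti"]], 9 / 19, tolerance = 1e-12)
  expect_lt(abs(sum(strict$titanium$fractions) - 1), 1e-12)
})

test_that("coefficient tables satisfy their physical invariants", {
  ct <- load_coefficients()
  expect_true(all(c("H", "O", "Fe", "Ir", "Mo") %in% names(ct)))
  for (el in names(ct)) {
    tab <- ct[[el]]
    expect_lte(tab$energy_mev[1], 0.010)
    expect_gte(tab$energy_mev[nrow(tab)], 1.40)
    expect_true(all(tab$mu_rho > 0))
    expect_true(all(tab$mu_en_rho > 0))
    expect_true(all(tab$mu_en_rho <= tab$mu_rho * (1 + 1e-12)))
  }
})

test_that("mixture rule degenerates for a single element and interpolates log-log", {
  ct <- load_coefficients()
  lib <- material_library()
  # single-element material at a grid energy: exactly the tabulated value
  e_grid <- ct$Ir$energy_mev[30]
  expect_equal(mixture_coefficient(lib$iridium_seed, e_grid, "attenuation"),
               ct$Ir$mu_rho[30], tolerance = 1e-12)
  # hand log-log interpolation between the two bracketing rows for water
  e <- 0.3
  w <- lib$water$fractions
  hand <- 0
  for (el in names(w)) {
    tab <- ct[[el]]
    i <- max(which(tab$energy_mev <= e))
    f <- (log(e) - log(tab$energy_mev[i])) /
      (log(tab$energy_mev[i + 1]) - log(tab$energy_mev[i]))
    hand <- hand + w[[el]] * exp((1 - f) * log(tab$mu_rho[i]) +
                                   f * log(tab$mu_rho[i + 1]))
  }
  expect_equal(mixture_coefficient(lib$water, e, "attenuation"), hand,
               tolerance = 1e-12)
  # no extrapolation outside the table
  expect_error(mixture_coefficient(lib$water, 0.001), "range")
  expect_error(mixture_coefficient(lib$water, 2.0), "range")
  # vacuum is a void, not a material with coefficients
  expect_error(mixture_coefficient(lib$vacuum, 0.3), "void")
})

test_that("interaction probabilities partition the total coefficient", {
  lib <- material_library()
  p <- interaction_probabilities(lib$water, 1.0)
  expect_gt(p$p_compton, 0.99)
  p2 <- interaction_probabilities(lib$stainless_steel, 0.02)
  expect_gt(p2$p_photoelectric, p2$p_compton)
  for (m in c("water", "bone", "steel_316l", "iridium_seed", "lung")) {
    pr <- interaction_probabilities(lib[[m]], c(0.05, 0.3, 1.0))
    expect_true(all(pr$p_compton >= 0 & pr$p_compton <= 1))
    expect_equal(pr$p_compton + pr$p_photoelectric, rep(1, 3))
  }
})

test_that("material constructor validates fraction sums", {
  expect_error(material("x", c(H = 0.5, O = 0.4), 1), "sum")
  expect_error(material("x", c(Xx = 1), 1), "coefficient data")
  m <- material("w", c(H = 0.111894, O = 0.888106), 1)
  expect_s3_class(m, "material")
})
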