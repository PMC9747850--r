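#' Construct a material
#'
#' A material is a named set of elemental mass fractions plus a bulk density.
#' Fractions must sum to 1 within 1e-3 (they are not silently renormalised
#' here; the library loader renormalises published rows once, on load).
#'
#' @param name label.
#' @param fractions named numeric vector, element symbol -> mass fraction.
#' @param density g/cm3, must be positive.
#' @return A `material` object.
#' @export
material <- function(name, fractions, density) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(fractions), !is.null(names(fractions)),
            all(fractions >= 0), density > 0)
  unknown <- setdiff(names(fractions), .element_data$symbol)
  if (length(unknown))
    stop("no coefficient data for element(s): ", paste(unknown, collapse = ", "))
  s <- sum(fractions)
  if (abs(s - 1) > 1e-3)
    stop(sprintf("mass fractions of '%s' sum to %.6f, not 1", name, s))
  structure(list(name = name, fractions = fractions, density = density),
            class = "material")
}

#' @export
print.material <- function(x, ...) {
  cat(sprintf("material '%s' (%.4g g/cm3): %s\n", x$name, x$density,
              paste(sprintf("%s %.4f", names(x$fractions), x$fractions),
                    collapse = ", ")))
  invisible(x)
}

#' Bundled material library
#'
#' Loads the fifteen-material library used by the source model and the slab
#' phantoms: the tissue and implant set (titanium, lung, muscle, bone,
#' adipose, cartilage, stainless steel, PEEK, PMMA, water, air, vacuum) plus
#' the source hardware alloys (iridium core, AISI 304 wire, AISI 316L
#' capsule). Published compositions are renormalised to unit fraction sum on
#' load. The published titanium row (Al 6, Ti 9, V 4 percent -- an evident
#' Ti-6Al-4V misprint summing to 19 percent) is corrected to Ti 90 percent
#' unless `strict = TRUE`, which keeps the printed row renormalised for
#' sensitivity checks. The bone entry lists potassium at 20.99 percent with
#' no comparable calcium share; it is kept as published.
#'
#' @param file optional path to a material CSV
#'   (columns `material`, `density`, `element`, `percent`).
#' @param strict keep the printed titanium composition (renormalised) instead
#'   of the Ti-6Al-4V correction.
#' @return Named list of [material()] objects.
#' @examples
#' lib <- material_library()
#' lib$water$fractions
#' lib$lung$density
#' @export
material_library <- function(file = NULL, strict = FALSE) {
  if (is.null(file)) {
    key <- paste0("matlib_", strict)
    if (!is.null(.cache[[key]])) return(.cache[[key]])
    file <- system.file("extdata", "materials.csv", package = "brachymc",
                        mustWork = TRUE)
    cache_key <- key
  } else cache_key <- NULL
  tab <- read.csv(file, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("material", "density", "element", "percent") %in% names(tab)))
  lib <- lapply(split(tab, factor(tab$material, unique(tab$material))),
                function(d) {
    fr <- d$percent
    names(fr) <- d$element
    if (d$material[1L] == "titanium" && !strict)
      fr[["Ti"]] <- 90
    material(d$material[1L], fr / sum(fr), d$density[1L])
  })
  if (!is.null(cache_key)) .cache[[cache_key]] <- lib
  lib
}

#' Element photon interaction coefficient tables
#'
#' Loads the bundled per-element mass attenuation and mass energy-absorption
#' coefficients covering 10 keV to 1.4 MeV. The tables are generated from
#' free-electron Klein-Nishina closed forms (incoherent channel) plus
#' Cromer-Liberman photoabsorption cross-sections, with coherent scattering
#' excluded and photoabsorption treated as full local absorption -- exactly
#' the interaction model the transport engine samples, so track-length kerma
#' and analog energy deposition agree in expectation.
#'
#' @param dir optional directory of per-element CSVs
#'   (columns `energy_mev`, `mu_rho`, `mu_en_rho`).
#' @return A `coefficient_table`: named list of per-element data frames.
#' @examples
#' ct <- load_coefficients()
#' names(ct)[1:5]
#' @export
load_coefficients <- function(dir = NULL) {
  if (is.null(dir)) {
    if (!is.null(.cache$coeff)) return(.cache$coeff)
    dir <- system.file("extdata", "coefficients", package = "brachymc",
                       mustWork = TRUE)
    cache <- TRUE
  } else cache <- FALSE
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  if (!length(files)) stop("no coefficient CSVs in ", dir)
  tabs <- lapply(files, function(f) {
    d <- read.csv(f, comment.char = "#")
    stopifnot(all(c("energy_mev", "mu_rho", "mu_en_rho") %in% names(d)),
              !is.unsorted(d$energy_mev),
              all(d$mu_rho > 0), all(d$mu_en_rho > 0),
              all(d$mu_en_rho <= d$mu_rho * (1 + 1e-12)),
              d$energy_mev[1L] <= 0.010,
              d$energy_mev[nrow(d)] >= 1.40)
    d
  })
  names(tabs) <- sub("\\.csv$", "", basename(files))
  out <- structure(tabs, class = "coefficient_table")
  if (cache) .cache$coeff <- out
  out
}

# log-log interpolation on an ascending table; hard range error
.interp_loglog <- function(e, tab_e, tab_v) {
  if (any(e < tab_e[1L] * (1 - 1e-9)) || any(e > tab_e[length(tab_e)] * (1 + 1e-9)))
    stop(sprintf("energy outside coefficient table range [%.4g, %.4g] MeV",
                 tab_e[1L], tab_e[length(tab_e)]))
  e <- pmin(pmax(e, tab_e[1L]), tab_e[length(tab_e)])
  exp(approx(log(tab_e), log(tab_v), xout = log(e), ties = "ordered")$y)
}

#' Mixture interaction coefficient
#'
#' Mass-weighted mixture rule: the material coefficient is the sum of the
#' elemental coefficients weighted by mass fraction, each element
#' interpolated log-log in energy. No extrapolation outside the table range.
#' Vacuum carries no coefficient: the transport engine treats it as a true
#' void, and requesting a coefficient for it is an error.
#'
#' @param mat a [material()].
#' @param energy photon energy (MeV), vectorised.
#' @param kind `"attenuation"` (mu/rho) or `"energy_absorption"` (mu_en/rho).
#' @param table a [load_coefficients()] table.
#' @return Coefficient(s) in cm2/g.
#' @examples
#' lib <- material_library()
#' mixture_coefficient(lib$water, 0.3, "attenuation")
#' @export
mixture_coefficient <- function(mat, energy,
                                kind = c("attenuation", "energy_absorption"),
                                table = load_coefficients()) {
  kind <- match.arg(kind)
  stopifnot(inherits(mat, "material"))
  if (mat$name == "vacuum")
    stop("vacuum has no interaction coefficient; the transport engine treats it as a void")
  col <- if (kind == "attenuation") "mu_rho" else "mu_en_rho"
  out <- 0
  for (el in names(mat$fractions)) {
    w <- mat$fractions[[el]]
    if (w == 0) next
    tab <- table[[el]]
    if (is.null(tab)) stop("no coefficient table for element ", el)
    out <- out + w * .interp_loglog(energy, tab$energy_mev, tab[[col]])
  }
  out
}

#' Klein-Nishina cross sections
#'
#' Closed-form free-electron Klein-Nishina cross sections per electron:
#' `"total"` (collision), `"scatter"` (energy-scattering, i.e. weighted by
#' the fraction of energy kept by the photon) and `"transfer"`
#' (energy-transfer, total minus scatter).
#'
#' @param energy photon energy (MeV), vectorised.
#' @param kind which cross section.
#' @return Cross section(s) in cm2 per electron.
#' @export
klein_nishina_cross_section <- function(energy,
                                        kind = c("total", "scatter",
                                                 "transfer")) {
  kind <- match.arg(kind)
  a <- energy / .const$mec2_mev
  re2 <- .const$re_cm^2
  t <- 1 + 2 * a
  tot <- 2 * pi * re2 * ((1 + a) / a^2 * (2 * (1 + a) / t - log(t) / a) +
                           log(t) / (2 * a) - (1 + 3 * a) / t^2)
  if (kind == "total") return(tot)
  sc <- pi * re2 * (log(t) / a^3 +
                      2 * (1 + a) * (2 * a^2 - 2 * a - 1) / (a^2 * t^2) +
                      8 * a^2 / (3 * t^3))
  if (kind == "scatter") sc else tot - sc
}

# incoherent (Klein-Nishina) mass attenuation coefficient of a material
.mu_incoherent <- function(mat, energy) {
  za <- 0
  for (el in names(mat$fractions)) {
    i <- match(el, .element_data$symbol)
    za <- za + mat$fractions[[el]] * .element_data$Z[i] / .element_data$A[i]
  }
  za * .const$avogadro * klein_nishina_cross_section(energy, "total")
}

#' Interaction channel probabilities
#'
#' Partition of the total interaction coefficient into the incoherent
#' (Compton) and photoabsorption channels: the Compton share is the
#' analytic Klein-Nishina incoherent coefficient over the tabulated total,
#' and photoabsorption takes the remainder, so the two always sum to 1.
#'
#' @inheritParams mixture_coefficient
#' @return List with vectors `p_compton` and `p_photoelectric`.
#' @examples
#' lib <- material_library()
#' interaction_probabilities(lib$water, 1.0)$p_compton  # > 0.99
#' @export
interaction_probabilities <- function(mat, energy,
                                      table = load_coefficients()) {
  mu <- mixture_coefficient(mat, energy, "attenuation", table)
  pc <- pmin(1, pmax(0, .mu_incoherent(mat, energy) / mu))
  list(p_compton = pc, p_photoelectric = 1 - pc)
}

#' Sample Compton scattering
#'
#' Samples scattered photon energies and polar scattering angles from the
#' free-electron Klein-Nishina differential cross section (composition and
#' rejection sampling), consistent with the Compton relation
#' E' = E / (1 + (E/mec2)(1 - cos theta)).
#'
#' @param n number of samples.
#' @param energy incident photon energy (MeV), scalar.
#' @param seed integer seed (bit-exact replay for equal seeds).
#' @return Data frame with `energy_out` (MeV) and `cos_theta`.
#' @examples
#' s <- sample_compton(1e4, 0.511, seed = 1)
#' min(s$energy_out) >= 0.511 / 3
#' @export
sample_compton <- function(n, energy, seed = 1L) {
  stopifnot(energy > 0, n >= 1)
  m <- cpp_sample_compton(as.integer(n), energy, as.integer(seed))
  data.frame(energy_out = m[, 1L], cos_theta = m[, 2L])
}

#' Klein-Nishina differential cross section
#'
#' d sigma / d cos(theta) per electron for incident energy `energy`.
#'
#' @param energy incident photon energy (MeV), scalar.
#' @param cos_theta polar scattering angle cosine(s).
#' @return Differential cross section in cm2 per electron per unit
#'   cos(theta).
#' @export
klein_nishina_dcs <- function(energy, cos_theta) {
  a <- energy / .const$mec2_mev
  eps <- 1 / (1 + a * (1 - cos_theta))
  pi * .const$re_cm^2 * eps^2 * (eps + 1 / eps - 1 + cos_theta^2)
}
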