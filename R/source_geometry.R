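#' GammaMed Plus source geometry
#'
#' Fixed geometry of the modelled HDR source: a 3.5 mm long, 0.6 mm diameter
#' pure-iridium active core inside a 316L stainless-steel capsule (outer
#' diameter 0.9 mm, inner diameter 0.7 mm) whose distal end is a truncated
#' cone, attached to a 2 mm long, 0.9 mm diameter 304 stainless-steel drive
#' wire stub. The local frame has z along the source long axis with the
#' origin at the active-core centre (TG-43 convention); the wire sits at
#' negative z, the conical tip at positive z. All lengths in cm.
#'
#' @param tip_height height of the truncated-cone capsule tip in cm
#'   (default 0.05); dose points of interest lie off the tip axis at 2 mm or
#'   more, where this detail is second order.
#' @return A `source_geometry` list with the dimension, material and density
#'   fields.
#' @examples
#' g <- gmp_source()
#' g$core_length                       # 0.35 cm
#' (g$capsule_outer_diameter - g$capsule_inner_diameter) / 2  # wall, cm
#' @export
gmp_source <- function(tip_height = 0.05) {
  stopifnot(tip_height > 0, tip_height < 0.2)
  structure(list(
    core_length = 0.35,
    core_diameter = 0.06,
    capsule_outer_diameter = 0.09,
    capsule_inner_diameter = 0.07,
    wire_length = 0.2,
    wire_diameter = 0.09,
    tip_height = tip_height,
    tip_end_diameter = 0.04,
    core_material = "iridium_seed",
    capsule_material = "steel_316l",
    wire_material = "steel_304",
    cavity_material = "air",
    core_density = 22.42,
    capsule_density = 8.03,
    wire_density = 5.6
  ), class = "source_geometry")
}

#' @export
print.source_geometry <- function(x, ...) {
  cat("GammaMed Plus style HDR source geometry (cm):\n")
  cat(sprintf("  core    L = %.3f, d = %.3f  (%s, %.2f g/cm3)\n",
              x$core_length, x$core_diameter, x$core_material,
              x$core_density))
  cat(sprintf("  capsule d_out = %.3f, d_in = %.3f, tip height %.3f (%s)\n",
              x$capsule_outer_diameter, x$capsule_inner_diameter,
              x$tip_height, x$capsule_material))
  cat(sprintf("  wire    L = %.3f, d = %.3f (%s)\n",
              x$wire_length, x$wire_diameter, x$wire_material))
  invisible(x)
}

# Numeric parameter vector consumed by the C++ tracker.
# Axial layout (cm): core |z| <= z_core; inner cavity |z| <= z_cav;
# capsule outer shell from z_cap_bot to z_cav, frustum tip from z_cav to
# z_cav + tip_h tapering r_out -> r_tip; wire from z_wire_bot to z_cap_bot.
.source_geom_params <- function(geom) {
  stopifnot(inherits(geom, "source_geometry"))
  r_core <- geom$core_diameter / 2
  r_cav <- geom$capsule_inner_diameter / 2
  r_out <- geom$capsule_outer_diameter / 2
  z_core <- geom$core_length / 2
  z_cav <- z_core + 0.01            # 0.1 mm axial clearance inside capsule
  cap_bottom <- 0.04                # solid base cap thickness
  z_cap_bot <- -(z_cav + cap_bottom)
  c(r_core = r_core, z_core = z_core,
    r_cav = r_cav, z_cav = z_cav,
    r_out = r_out, z_cap_bot = z_cap_bot,
    tip_h = geom$tip_height, r_tip = geom$tip_end_diameter / 2,
    z_wire_bot = z_cap_bot - geom$wire_length)
}

#' Sample decay photons from the source
#'
#' Draws emission positions uniformly inside the active iridium core,
#' isotropic directions, and line energies with probability proportional to
#' line intensity. All weights are 1. Lines below the transport cut are
#' returned flagged (`below_cut`); the transport engine drops them while
#' still counting the histories.
#'
#' @param n number of photons to sample.
#' @param spectrum a [load_spectrum()] object.
#' @param geometry a [gmp_source()] geometry, or `NULL` for a point source at
#'   the origin.
#' @param seed integer seed; the same seed replays the identical sample
#'   sequence bit for bit.
#' @return Data frame with columns `x`, `y`, `z` (cm, source frame),
#'   `ux`, `uy`, `uz` (unit direction), `energy` (MeV), `weight`,
#'   `below_cut`.
#' @examples
#' s <- sample_decay(1000, load_spectrum(), gmp_source(), seed = 1)
#' max(abs(s$z)) <= 0.175
#' @export
sample_decay <- function(n, spectrum, geometry = gmp_source(), seed = 1L) {
  spectrum <- .as_spectrum(spectrum)
  stopifnot(n >= 1, nrow(spectrum) >= 1)
  cdf <- cumsum(spectrum$intensity) / sum(spectrum$intensity)
  gp <- if (is.null(geometry)) numeric(0) else .source_geom_params(geometry)
  m <- cpp_sample_decay(as.integer(n), as.integer(seed),
                        spectrum$energy, cdf, gp)
  out <- as.data.frame(m)
  names(out) <- c("x", "y", "z", "ux", "uy", "uz", "energy", "weight")
  out$below_cut <- out$energy < attr(spectrum, "energy_cut")
  out
}
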