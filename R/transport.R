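#' Transport run configuration
#'
#' @param n_histories number of primary photons. A history is one emitted
#'   photon sampled from the intensity-normalised line spectrum; spectrum
#'   lines below the energy cut are dropped at sampling time but still count
#'   toward the history total. A soft warning is issued above 2.1e9, the
#'   single-run ceiling the workflow assumes.
#' @param seed integer RNG seed (MT19937); equal seeds give bit-identical
#'   runs.
#' @param energy_cut photon energy cut in MeV (default 0.010); photons that
#'   fall below it are terminated with local energy deposition.
#' @param scoring `"analog"` (local deposition of transferred energy at
#'   interaction sites, the phantom-comparison default) or `"tle"`
#'   (track-length kerma estimator).
#' @param primaries_only terminate each photon at its first interaction
#'   (uncollided-fluence diagnostics; TLE scoring only).
#' @param tracking `"grid"` (chord-wise optical depth through the voxel
#'   grid) or `"woodcock"` (delta tracking with a majorant cross-section;
#'   identical expectation, analog scoring only).
#' @return A `run_config` object.
#' @export
run_config <- function(n_histories, seed = 1L, energy_cut = 0.010,
                       scoring = c("analog", "tle"), primaries_only = FALSE,
                       tracking = c("grid", "woodcock")) {
  scoring <- match.arg(scoring)
  tracking <- match.arg(tracking)
  stopifnot(n_histories >= 1, energy_cut > 0)
  if (n_histories > 2.1e9)
    warning("n_histories exceeds the assumed 2.1e9 single-run ceiling")
  if (primaries_only && scoring != "tle")
    stop("primaries_only requires scoring = 'tle'")
  if (tracking == "woodcock" && scoring != "analog")
    stop("woodcock tracking supports analog scoring only")
  structure(list(n_histories = n_histories, seed = as.integer(seed),
                 energy_cut = energy_cut, scoring = scoring,
                 primaries_only = primaries_only, tracking = tracking),
            class = "run_config")
}

#' Voxel phantom container
#'
#' @param material_index 3-D integer array of 1-based indices into
#'   `materials`.
#' @param materials character vector of material names resolvable in the
#'   [material_library()].
#' @param spacing_mm voxel edge lengths in mm (default 1 mm cubes).
#' @param origin_cm position of the corner of voxel (1,1,1) in cm.
#' @return A `voxel_phantom` object.
#' @export
voxel_phantom <- function(material_index, materials,
                          spacing_mm = c(1, 1, 1),
                          origin_cm = c(0, 0, 0)) {
  stopifnot(is.array(material_index), length(dim(material_index)) == 3L,
            length(spacing_mm) == 3L, all(spacing_mm > 0),
            length(origin_cm) == 3L)
  idx <- as.integer(material_index)
  if (any(idx < 1L) || any(idx > length(materials)))
    stop("material_index entries must map into 'materials'")
  lib <- material_library()
  missing <- setdiff(materials, names(lib))
  if (length(missing))
    stop("unknown material(s): ", paste(missing, collapse = ", "))
  structure(list(material_index = material_index, materials = materials,
                 spacing_mm = spacing_mm, origin_cm = origin_cm),
            class = "voxel_phantom")
}

#' @export
print.voxel_phantom <- function(x, ...) {
  dm <- dim(x$material_index)
  cat(sprintf("voxel phantom %d x %d x %d, spacing %s mm\n", dm[1], dm[2],
              dm[3], paste(x$spacing_mm, collapse = "x")))
  tabs <- table(factor(x$material_index, seq_along(x$materials),
                       x$materials))
  for (nm in names(tabs))
    if (tabs[[nm]] > 0) cat(sprintf("  %-16s %d voxels\n", nm, tabs[[nm]]))
  invisible(x)
}

#' Exact voxel-grid ray traversal
#'
#' Chords of a ray through the voxel grid; the chords partition the in-grid
#' segment exactly (their sum equals the geometric path length inside the
#' grid to better than 1e-9 cm). A ray that misses the grid returns zero
#' rows.
#'
#' @param start ray origin in cm (length-3).
#' @param direction ray direction (normalised internally).
#' @param phantom a [voxel_phantom()].
#' @return Data frame with 1-based voxel indices `ix`, `iy`, `iz` and
#'   `chord_cm`.
#' @export
trace_voxels <- function(start, direction, phantom) {
  stopifnot(inherits(phantom, "voxel_phantom"))
  res <- cpp_trace_voxels(as.numeric(start), as.numeric(direction),
                          dim(phantom$material_index),
                          phantom$spacing_mm / 10, phantom$origin_cm)
  data.frame(ix = res$ijk[, 1], iy = res$ijk[, 2], iz = res$ijk[, 3],
             chord_cm = res$chord)
}

# Per-material physics tables on a shared log-energy grid for the C++ core.
# Returns log linear attenuation (1/cm), log mu_en/rho, Compton probability,
# void flags and densities for the named materials.
.material_physics <- function(mat_names, library = material_library(),
                              table = load_coefficients()) {
  eg <- sort(unique(c(table$Ir$energy_mev, table$Mo$energy_mev)))
  nE <- length(eg)
  nm <- length(mat_names)
  logMu <- matrix(0, nE, nm)
  logMuen <- matrix(0, nE, nm)
  pcomp <- matrix(0, nE, nm)
  isVoid <- integer(nm)
  dens <- numeric(nm)
  for (j in seq_len(nm)) {
    mat <- library[[mat_names[j]]]
    if (is.null(mat)) stop("unknown material: ", mat_names[j])
    dens[j] <- mat$density
    if (mat$name == "vacuum") {
      isVoid[j] <- 1L
      logMu[, j] <- -690
      logMuen[, j] <- -690
      next
    }
    mu <- mixture_coefficient(mat, eg, "attenuation", table)
    muen <- mixture_coefficient(mat, eg, "energy_absorption", table)
    logMu[, j] <- log(mu * mat$density)
    logMuen[, j] <- log(muen)
    pcomp[, j] <- pmin(1, pmax(0, .mu_incoherent(mat, eg) / mu))
  }
  list(logE = log(eg), logMu = logMu, logMuen = logMuen, pcomp = pcomp,
       isVoid = isVoid, density = dens)
}

# normalised cumulative intensity over all lines (below-cut lines included:
# they count as histories and are dropped by the engine at sampling time)
.spec_cdf <- function(spectrum) {
  cumsum(spectrum$intensity) / sum(spectrum$intensity)
}

# orthonormal frame whose third column is the source long axis
.source_frame <- function(axis) {
  if (is.character(axis))
    axis <- switch(axis, x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1),
                   stop("axis must be 'x', 'y', 'z' or a unit 3-vector"))
  u3 <- axis / sqrt(sum(axis^2))
  helper <- if (abs(u3[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u1 <- helper - sum(helper * u3) * u3
  u1 <- u1 / sqrt(sum(u1^2))
  u2 <- c(u3[2] * u1[3] - u3[3] * u1[2],
          u3[3] * u1[1] - u3[1] * u1[3],
          u3[1] * u1[2] - u3[2] * u1[1])
  cbind(u1, u2, u3)
}

#' Run a Monte Carlo simulation in a voxel phantom
#'
#' Transports photons from the source through the phantom grid and scores
#' dose to medium per history, either by analog local deposition of the
#' energy transferred at interaction sites (Compton electron energy and
#' photoabsorbed energy; the kerma approximation with no electron transport)
#' or by the track-length kerma estimator. Statistical uncertainty is
#' estimated history by history.
#'
#' @param phantom a [voxel_phantom()]; the source position must lie inside.
#' @param source list with `spectrum` (a [load_spectrum()] object or single
#'   energy in MeV), `geometry` (a [gmp_source()] or `NULL` for an isotropic
#'   point source), `center_cm` (length-3) and `axis` (`"x"`, `"y"`, `"z"`
#'   or unit 3-vector; source long axis).
#' @param config a [run_config()].
#' @return A `dose_grid`: list with 3-D arrays `dose` (Gy per history) and
#'   `rel_unc` (k=1 relative statistical uncertainty, `NA` where no dose was
#'   scored), the phantom metadata, and the analog energy accounting
#'   (`emitted`, `deposited`, `escaped`, `void_banked`, MeV).
#' @export
run_simulation <- function(phantom, source, config) {
  stopifnot(inherits(phantom, "voxel_phantom"), inherits(config, "run_config"))
  spectrum <- .as_spectrum(source$spectrum)
  geom <- source$geometry
  if (!is.null(geom)) stopifnot(inherits(geom, "source_geometry"))
  center <- as.numeric(source$center_cm)
  dm <- dim(phantom$material_index)
  sp_cm <- phantom$spacing_mm / 10
  lo <- phantom$origin_cm
  hi <- lo + dm * sp_cm
  if (any(center <= lo) || any(center >= hi))
    stop("source center lies outside the phantom grid")
  frame <- .source_frame(if (is.null(source$axis)) "x" else source$axis)
  phys <- .material_physics(phantom$materials)
  gp <- if (is.null(geom)) numeric(0) else .source_geom_params(geom)
  res <- cpp_voxel_run(config$n_histories, config$seed,
                       as.integer(phantom$material_index), dm, sp_cm, lo,
                       phys$logE, phys$logMu, phys$logMuen, phys$pcomp,
                       phys$isVoid, phys$density,
                       spectrum$energy, .spec_cdf(spectrum),
                       center, as.numeric(frame), gp,
                       config$energy_cut,
                       if (config$scoring == "tle") 1L else 0L,
                       config$primaries_only,
                       config$tracking == "woodcock")
  n <- res$n
  unc <- estimate_uncertainty(res$sum, res$sumsq, n)
  mean_score <- res$sum / n
  vvox <- prod(sp_cm)  # cm3
  # analog scores are MeV per voxel; TLE scores are MeV cm3/g per voxel
  dose <- if (config$scoring == "tle") {
    mean_score / vvox * .const$mev_per_g_to_gy
  } else {
    dens <- phys$density[as.integer(phantom$material_index)]
    mean_score / (dens * vvox) * .const$mev_per_g_to_gy
  }
  structure(list(
    dose = array(dose, dm),
    rel_unc = array(unc, dm),
    n_histories = n,
    scoring = config$scoring,
    seed = config$seed,
    spacing_mm = phantom$spacing_mm,
    origin_cm = phantom$origin_cm,
    source_center_cm = center,
    source_axis = if (is.null(source$axis)) "x" else source$axis,
    energy_mev = list(emitted = res$emitted, deposited = res$deposited,
                      escaped = res$escaped, void_banked = res$void_banked)
  ), class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  dm <- dim(x$dose)
  cat(sprintf("dose grid %d x %d x %d (%s scoring, %g histories)\n",
              dm[1], dm[2], dm[3], x$scoring, x$n_histories))
  cat(sprintf("  max dose %.4g Gy/history\n", max(x$dose)))
  invisible(x)
}

#' Kerma scoring on spherical shells around the source
#'
#' Transports photons from the encapsulated source (tracked on its analytic
#' surfaces) through a surrounding sphere of medium, scoring collisional
#' kerma with the track-length estimator onto (r, theta) shell sectors
#' centred on the source: each photon flight segment credits
#' E (mu_en/rho) chord / V to every sector it crosses. Shell scoring avoids
#' the dose-gradient-over-voxel bias of cartesian grids for TG-43 work.
#'
#' @param spectrum a [load_spectrum()] object or a single energy (MeV).
#' @param geometry a [gmp_source()], or `NULL` for a bare isotropic point
#'   source at the origin.
#' @param r_edges_cm ascending shell radii (cm).
#' @param theta_edges_deg ascending polar-angle sector edges (degrees from
#'   the source long axis; default one sector spanning 0-180).
#' @param medium `"water"` or `"vacuum"` filling the sphere outside the
#'   source capsule.
#' @param scoring_material material whose mass energy-absorption coefficient
#'   converts photon fluence to kerma (water for dose-to-water, air for
#'   air-kerma scoring).
#' @param n_histories,seed,energy_cut,primaries_only see [run_config()].
#' @param sphere_radius_cm phantom sphere radius (default 40 cm).
#' @return Data frame with one row per (r, theta) sector: `r_lo`, `r_hi`,
#'   `r_mid`, `theta_lo`, `theta_hi`, `theta_mid`, `volume_cm3`,
#'   `dose_per_history` (Gy/history) and `rel_unc` (k=1).
#' @export
sphere_kerma <- function(spectrum, geometry = gmp_source(), r_edges_cm,
                         theta_edges_deg = c(0, 180),
                         medium = c("water", "vacuum"),
                         scoring_material = "water",
                         n_histories = 1e5, seed = 1L, energy_cut = 0.010,
                         primaries_only = FALSE, sphere_radius_cm = 40) {
  medium <- match.arg(medium)
  spectrum <- .as_spectrum(spectrum)
  stopifnot(!is.unsorted(r_edges_cm), length(r_edges_cm) >= 2,
            !is.unsorted(theta_edges_deg), length(theta_edges_deg) >= 2,
            max(r_edges_cm) <= sphere_radius_cm)
  if (!is.null(geometry)) stopifnot(inherits(geometry, "source_geometry"))
  gp <- if (is.null(geometry)) numeric(0) else .source_geom_params(geometry)
  mats <- c("iridium_seed", "air", "steel_316l", "steel_304",
            if (medium == "water") "water" else "vacuum")
  if (!scoring_material %in% mats) mats <- c(mats, scoring_material)
  phys <- .material_physics(mats)
  res <- cpp_sphere_run(n_histories, as.integer(seed), spectrum$energy,
                        .spec_cdf(spectrum), gp, sphere_radius_cm,
                        r_edges_cm, theta_edges_deg,
                        c(0L, 1L, 2L, 3L, 4L),  # region -> material column
                        phys$logE, phys$logMu, phys$logMuen, phys$pcomp,
                        phys$isVoid, phys$density,
                        match(scoring_material, mats) - 1L, 4L,
                        energy_cut, primaries_only)
  nr <- length(r_edges_cm) - 1L
  nth <- length(theta_edges_deg) - 1L
  grid <- expand.grid(it = seq_len(nth), ir = seq_len(nr))
  r_lo <- r_edges_cm[grid$ir]
  r_hi <- r_edges_cm[grid$ir + 1L]
  th_lo <- theta_edges_deg[grid$it]
  th_hi <- theta_edges_deg[grid$it + 1L]
  vol <- 2 * pi / 3 * (r_hi^3 - r_lo^3) *
    (cos(th_lo * pi / 180) - cos(th_hi * pi / 180))
  dose <- res$sum / res$n / vol * .const$mev_per_g_to_gy
  out <- data.frame(r_lo = r_lo, r_hi = r_hi, r_mid = (r_lo + r_hi) / 2,
                    theta_lo = th_lo, theta_hi = th_hi,
                    theta_mid = (th_lo + th_hi) / 2,
                    volume_cm3 = vol, dose_per_history = dose,
                    rel_unc = estimate_uncertainty(res$sum, res$sumsq,
                                                   res$n))
  attr(out, "n_histories") <- res$n
  attr(out, "n_below_cut") <- res$n_below_cut
  attr(out, "normalization") <- "per_history"
  out
}

#' Score air-kerma strength in vacuo
#'
#' Simulates the encapsulated source in a void (the capsule and wire remain
#' attenuating), scores air kerma on a thin transverse-axis shell at the
#' reference distance, and multiplies by the squared effective distance.
#' In vacuo the product is independent of the distance.
#'
#' @inheritParams sphere_kerma
#' @param distance_cm scoring distance (default 100 cm).
#' @param shell_thickness_cm radial thickness of the scoring shell.
#' @param theta_band_deg half-width of the transverse sector around 90
#'   degrees.
#' @return List with `s_k_per_history` (Gy cm2 per history), `rel_unc`
#'   (k=1) and the scoring geometry.
#' @examples
#' \donttest{
#' sk <- score_air_kerma_strength(load_spectrum(), gmp_source(),
#'                                n_histories = 2e5, seed = 7)
#' sk$s_k_per_history
#' }
#' @export
score_air_kerma_strength <- function(spectrum, geometry = gmp_source(),
                                     n_histories = 1e6, seed = 1L,
                                     distance_cm = 100,
                                     shell_thickness_cm = 0.5,
                                     theta_band_deg = 3,
                                     energy_cut = 0.010) {
  r1 <- distance_cm - shell_thickness_cm / 2
  r2 <- distance_cm + shell_thickness_cm / 2
  shell <- sphere_kerma(spectrum, geometry, r_edges_cm = c(r1, r2),
                        theta_edges_deg = c(90 - theta_band_deg,
                                            90 + theta_band_deg),
                        medium = "vacuum", scoring_material = "air",
                        n_histories = n_histories, seed = seed,
                        energy_cut = energy_cut,
                        sphere_radius_cm = r2 + 1)
  d_eff2 <- (r1^2 + r1 * r2 + r2^2) / 3  # volume-average of 1/r^2 inverted
  out <- list(s_k_per_history = shell$dose_per_history[1L] * d_eff2,
              rel_unc = shell$rel_unc[1L], distance_cm = distance_cm,
              n_histories = n_histories)
  attr(out, "normalization") <- "per_history"
  out
}

#' History-by-history statistical uncertainty
#'
#' Relative k=1 standard error of the per-history mean from accumulated
#' first and second moments of per-history scores. Voxels or bins with zero
#' score are flagged `NA`.
#'
#' @param score_sum sum of per-history scores.
#' @param score_sum_sq sum of squared per-history scores.
#' @param n_histories number of histories (must be at least 2).
#' @return Relative standard error(s) of the mean (dimensionless, k=1).
#' @examples
#' estimate_uncertainty(100, 1, 1e4)   # constant scores -> 0
#' @export
estimate_uncertainty <- function(score_sum, score_sum_sq, n_histories) {
  if (n_histories < 2) return(rep(NA_real_, length(score_sum)))
  m <- score_sum / n_histories
  v <- (score_sum_sq / n_histories - m^2) / (n_histories - 1)
  v <- pmax(v, 0)
  out <- ifelse(m > 0, sqrt(v) / m, NA_real_)
  out
}
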