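#' TG-43 line-source geometry factor
#'
#' G_L(r, theta) = beta / (L r sin(theta)), with beta the angle the active
#' line of length L subtends at the point (r, theta); on the long axis the
#' limit 1 / (r^2 - L^2/4) applies. beta is computed as a difference of two
#' `atan2` angles for stability near the axis. Units cm^-2.
#'
#' @param r radial distance from the source centre (cm), vectorised.
#' @param theta polar angle from the source long axis (degrees), vectorised.
#' @param L active length (cm), default 0.35.
#' @return Geometry factor(s) in cm^-2.
#' @examples
#' geometry_factor_line(1, 90)             # ~0.99013 for L = 0.35
#' geometry_factor_line(2, 90, L = 1e-9)   # ~1/4 (point-source limit)
#' @export
geometry_factor_line <- function(r, theta, L = 0.35) {
  stopifnot(all(r > 0), all(theta >= 0), all(theta <= 180), L > 0)
  n <- max(length(r), length(theta))
  r <- rep_len(r, n)
  theta <- rep_len(theta, n)
  th <- theta * pi / 180
  y <- r * sin(th)   # distance from the long axis
  z <- r * cos(th)   # along the axis
  on_axis <- y < 1e-9 * pmax(r, 1)
  if (any(on_axis & r <= L / 2))
    stop("point lies on the active line segment; geometry factor undefined")
  beta <- atan2(z + L / 2, y) - atan2(z - L / 2, y)
  g <- ifelse(on_axis, 1 / (r^2 - L^2 / 4), beta / (L * y))
  g
}

#' Dose-rate constant from reference dose and air-kerma strength
#'
#' Lambda = D(r0, theta0) / S_K with both per history. With the dose in
#' Gy/history and S_K in Gy cm2/history the ratio is in cm^-2, numerically
#' equal to cGy h^-1 U^-1 (1 U = 1 uGy m2 h^-1 = 1 cGy cm2 h^-1).
#' Uncertainties combine in quadrature.
#'
#' @param d_ref dose to water at the reference point (1 cm, 90 deg) per
#'   history (Gy/history).
#' @param s_k air-kerma strength per history (Gy cm2/history).
#' @param u_d,u_s relative k=1 uncertainties of the two inputs.
#' @param normalization_d,normalization_s normalisation labels; when both
#'   are given they must match.
#' @return List with `lambda` (cGy h^-1 U^-1), `rel_unc_k1` and absolute
#'   `u_k1`, `u_k2`.
#' @export
dose_rate_constant <- function(d_ref, s_k, u_d = 0, u_s = 0,
                               normalization_d = NULL,
                               normalization_s = NULL) {
  stopifnot(d_ref > 0, s_k > 0)
  if (!is.null(normalization_d) && !is.null(normalization_s) &&
      !identical(normalization_d, normalization_s))
    stop("dose and air-kerma strength use different history normalisations")
  lambda <- d_ref / s_k
  rel <- sqrt(u_d^2 + u_s^2)
  list(lambda = lambda, rel_unc_k1 = rel, u_k1 = lambda * rel,
       u_k2 = 2 * lambda * rel)
}

#' Consensus dose-rate constant construction
#'
#' Averages independently published dose-rate constants and rounds half-up
#' to three decimals, the construction used for the consensus value of the
#' GammaMed Plus source: (1.118 + 1.115) / 2 -> 1.117 cGy h^-1 U^-1.
#'
#' @param values published estimates (cGy h^-1 U^-1).
#' @return The consensus value rounded half-up to 3 decimals.
#' @examples
#' consensus_dose_rate_constant()  # 1.117
#' @export
consensus_dose_rate_constant <- function(values = c(1.118, 1.115)) {
  round_half_up(mean(values), 3)
}

#' Reference dose-rate constant values
#'
#' Published comparison values for the GammaMed Plus source: the consensus
#' dose-rate constant 1.117 +/- 0.004 cGy h^-1 U^-1 built from the two
#' source estimates 1.118 +/- 0.003 and 1.115 +/- 0.003.
#'
#' @return List with `consensus`, `consensus_unc`, `sources`, `source_unc`.
#' @export
lambda_reference <- function() {
  list(consensus = 1.117, consensus_unc = 0.004,
       sources = c(1.118, 1.115), source_unc = c(0.003, 0.003))
}

#' Radial dose function from transverse-axis doses
#'
#' g_L(r) = D(r, theta0) G_L(r0, theta0) / (D(r0, theta0) G_L(r, theta0)),
#' normalised exactly to 1 at r0 = 1 cm. The r grid must contain r0; no
#' silent interpolation at the reference point.
#'
#' @param r radii (cm) of the transverse-axis doses.
#' @param dose doses (any common normalisation) at `r`, theta = 90 deg.
#' @param L active length (cm).
#' @param r0 reference radius (cm), default 1.
#' @return Data frame with columns `r` and `g_L`.
#' @export
radial_dose_function <- function(r, dose, L = 0.35, r0 = 1) {
  stopifnot(length(r) == length(dose), all(dose > 0))
  i0 <- which(abs(r - r0) < 1e-9)
  if (length(i0) != 1L)
    stop("radius grid must contain the reference radius r0 = ", r0, " cm")
  gl <- geometry_factor_line(r, 90, L)
  g <- dose * gl[i0] / (dose[i0] * gl)
  g[i0] <- 1  # exact at the reference by construction
  data.frame(r = r, g_L = g)
}

#' Anisotropy function from (r, theta) shell doses
#'
#' F(r, theta) = D(r, theta) G_L(r, theta0) / (D(r, theta0) G_L(r, theta)),
#' normalised exactly to 1 at theta0 = 90 deg for every tabulated radius.
#' Every radius must include a theta0 entry.
#'
#' @param r,theta,dose vectors of equal length (long table of shell doses).
#' @param L active length (cm).
#' @param theta0 reference angle (degrees), default 90.
#' @return Data frame with columns `r`, `theta`, `F`.
#' @export
anisotropy_function <- function(r, theta, dose, L = 0.35, theta0 = 90) {
  stopifnot(length(r) == length(theta), length(r) == length(dose),
            all(dose > 0))
  out <- do.call(rbind, lapply(split(data.frame(r, theta, dose), r),
                               function(d) {
    i0 <- which(abs(d$theta - theta0) < 1e-9)
    if (length(i0) != 1L)
      stop("theta grid at r = ", d$r[1L], " cm lacks the reference angle ",
           theta0, " deg")
    gl <- geometry_factor_line(d$r, d$theta, L)
    f <- d$dose * gl[i0] / (d$dose[i0] * gl)
    f[i0] <- 1
    data.frame(r = d$r, theta = d$theta, F = f)
  }))
  rownames(out) <- NULL
  out
}

#' Assemble a TG-43 parameter set
#'
#' @param lambda dose-rate constant (cGy h^-1 U^-1).
#' @param L active length (cm).
#' @param g_table data frame `r`, `g_L` (from [radial_dose_function()]).
#' @param f_table data frame `r`, `theta`, `F` (from
#'   [anisotropy_function()]), or `NULL` for an isotropic F = 1.
#' @param r0,theta0 reference point (1 cm, 90 deg).
#' @return A `tg43_params` object.
#' @export
tg43_parameters <- function(lambda, L, g_table, f_table = NULL, r0 = 1,
                            theta0 = 90) {
  stopifnot(lambda > 0, L > 0, all(g_table$g_L > 0))
  i0 <- which(abs(g_table$r - r0) < 1e-9)
  if (length(i0) != 1L || abs(g_table$g_L[i0] - 1) > 1e-9)
    stop("g_L table must contain g_L(r0) = 1 at r0 = ", r0)
  if (!is.null(f_table)) {
    stopifnot(all(f_table$F > 0))
    for (rr in unique(f_table$r)) {
      d <- f_table[f_table$r == rr, ]
      j <- which(abs(d$theta - theta0) < 1e-9)
      if (length(j) != 1L || abs(d$F[j] - 1) > 1e-9)
        stop("F table must contain F(r, theta0) = 1 at every radius")
    }
  }
  structure(list(lambda = lambda, L = L, r0 = r0, theta0 = theta0,
                 g_table = g_table[order(g_table$r), ],
                 f_table = f_table),
            class = "tg43_params")
}

#' @export
print.tg43_params <- function(x, ...) {
  cat(sprintf("TG-43 parameters: Lambda = %.4f cGy/h/U, L = %.2f cm\n",
              x$lambda, x$L))
  cat(sprintf("  g_L over r in [%.2g, %.2g] cm (%d points)\n",
              min(x$g_table$r), max(x$g_table$r), nrow(x$g_table)))
  if (!is.null(x$f_table))
    cat(sprintf("  F over %d radii x %d angles\n",
                length(unique(x$f_table$r)),
                length(unique(x$f_table$theta))))
  invisible(x)
}

# linear interpolation of g_L in r; nearest-edge only when allowed
.interp_g <- function(params, r, allow_nearest) {
  tab <- params$g_table
  if (!allow_nearest && (any(r < min(tab$r) - 1e-12) ||
                         any(r > max(tab$r) + 1e-12)))
    stop("r outside the g_L table; pass allow_nearest = TRUE to clamp")
  approx(tab$r, tab$g_L, xout = pmin(pmax(r, min(tab$r)), max(tab$r)),
         ties = "ordered")$y
}

# bilinear interpolation of F in (r, theta)
.interp_f <- function(params, r, theta, allow_nearest) {
  if (is.null(params$f_table)) return(rep(1, max(length(r), length(theta))))
  tab <- params$f_table
  rs <- sort(unique(tab$r))
  if (!allow_nearest && (any(r < min(rs) - 1e-12) ||
                         any(r > max(rs) + 1e-12)))
    stop("r outside the F table; pass allow_nearest = TRUE to clamp")
  r <- pmin(pmax(r, min(rs)), max(rs))
  n <- max(length(r), length(theta))
  r <- rep_len(r, n)
  theta <- rep_len(theta, n)
  vapply(seq_len(n), function(i) {
    hi <- which(rs >= r[i] - 1e-12)[1L]
    lo <- if (rs[hi] <= r[i] + 1e-12) hi else hi - 1L
    f_at <- function(rr) {
      d <- tab[abs(tab$r - rr) < 1e-12, ]
      if (!allow_nearest && (theta[i] < min(d$theta) - 1e-9 ||
                             theta[i] > max(d$theta) + 1e-9))
        stop("theta outside the F table; pass allow_nearest = TRUE to clamp")
      approx(d$theta, d$F,
             xout = pmin(pmax(theta[i], min(d$theta)), max(d$theta)),
             ties = "ordered")$y
    }
    if (lo == hi) return(f_at(rs[lo]))
    w <- (r[i] - rs[lo]) / (rs[hi] - rs[lo])
    (1 - w) * f_at(rs[lo]) + w * f_at(rs[hi])
  }, numeric(1))
}

#' TG-43 U1 forward dose rate
#'
#' D(r, theta) = S_K Lambda [G_L(r, theta) / G_L(r0, theta0)] g_L(r)
#' F(r, theta), with linear interpolation of g_L in r and bilinear
#' interpolation of F in (r, theta). Points outside the tabulated range
#' raise an error unless `allow_nearest = TRUE` clamps to the table edge.
#'
#' @param params a [tg43_parameters()] object.
#' @param s_k air-kerma strength (U).
#' @param r radial distance (cm), vectorised.
#' @param theta polar angle (degrees), vectorised.
#' @param allow_nearest clamp out-of-table points to the nearest edge.
#' @return Dose rate(s) in cGy/h.
#' @export
tg43_dose <- function(params, s_k, r, theta, allow_nearest = FALSE) {
  stopifnot(inherits(params, "tg43_params"), s_k > 0)
  n <- max(length(r), length(theta))
  r <- rep_len(r, n)
  theta <- rep_len(theta, n)
  g0 <- geometry_factor_line(params$r0, params$theta0, params$L)
  s_k * params$lambda * geometry_factor_line(r, theta, params$L) / g0 *
    .interp_g(params, r, allow_nearest) *
    .interp_f(params, r, theta, allow_nearest)
}

#' Remove the line-source geometry factor from a profile
#'
#' Multiplies each profile dose by G_L(r0, theta0) / G_L(r, theta)
#' ("D x G0/G"), with (r, theta) computed from the source pose, so the
#' steep line-source falloff is divided out and profile comparisons are not
#' dominated by it. Points on the active segment are excluded and flagged.
#'
#' @param position position along the profile line (cm), relative to
#'   `line$point`.
#' @param dose dose at each position.
#' @param L active length (cm).
#' @param line list with `point` (cm, a point the line passes through) and
#'   `direction` (unit 3-vector).
#' @param source list with `center` (cm) and `axis` (unit 3-vector, source
#'   long axis).
#' @param r0,theta0 reference point.
#' @return Data frame with `position`, `dose`, `adjusted_dose`,
#'   `multiplier`, `r`, `theta`, `excluded`.
#' @export
extract_geometry_factor <- function(position, dose, L = 0.35,
                                    line = list(point = c(0, 0, 0),
                                                direction = c(0, 0, 1)),
                                    source = list(center = c(0, 0, 0),
                                                  axis = c(1, 0, 0)),
                                    r0 = 1, theta0 = 90) {
  stopifnot(length(position) == length(dose))
  dirn <- line$direction / sqrt(sum(line$direction^2))
  axis <- source$axis / sqrt(sum(source$axis^2))
  rel <- t(vapply(position, function(s) line$point + s * dirn - source$center,
                  numeric(3)))
  r <- sqrt(rowSums(rel^2))
  ct <- pmin(1, pmax(-1, as.numeric(rel %*% axis) / r))
  theta <- acos(ct) * 180 / pi
  y <- r * sin(theta * pi / 180)
  excluded <- y < 1e-9 & r <= L / 2
  mult <- rep(NA_real_, length(r))
  g0 <- geometry_factor_line(r0, theta0, L)
  ok <- !excluded & r > 0
  mult[ok] <- g0 / geometry_factor_line(r[ok], theta[ok], L)
  if (any(excluded))
    warning(sum(excluded), " point(s) on the active segment excluded")
  data.frame(position = position, dose = dose,
             adjusted_dose = dose * mult, multiplier = mult,
             r = r, theta = theta, excluded = excluded)
}
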