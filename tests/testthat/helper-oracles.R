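# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain quadrature, brute-force searches and
# closed forms recomputed from first principles.

# line-source geometry factor by direct numerical integration of
# (1/L) * integral dl / d(l)^2 over the active line
oracle_gl <- function(r, theta, L) {
  th <- theta * pi / 180
  y <- r * sin(th)
  z <- r * cos(th)
  f <- function(l) 1 / (y^2 + (z - l)^2)
  stats::integrate(f, -L / 2, L / 2, rel.tol = 1e-12)$value / L
}

# Klein-Nishina differential cross section per electron, d sigma / d cos,
# written out independently (units cancel in the ratios the tests use)
oracle_kn_dcs <- function(E, ct) {
  a <- E / 0.51099895
  eps <- 1 / (1 + a * (1 - ct))
  eps^2 * (eps + 1 / eps - 1 + ct^2)
}

# mean scattered-energy fraction by quadrature
oracle_kn_mean_eps <- function(E) {
  a <- E / 0.51099895
  num <- stats::integrate(function(ct) oracle_kn_dcs(E, ct) /
                            (1 + a * (1 - ct)),
                          -1, 1, rel.tol = 1e-10)$value
  den <- stats::integrate(function(ct) oracle_kn_dcs(E, ct),
                          -1, 1, rel.tol = 1e-10)$value
  num / den
}

# normalised CDF of cos(theta) by cumulative quadrature on a fine grid
oracle_kn_cos_cdf <- function(E, grid = seq(-1, 1, length.out = 4001)) {
  dens <- oracle_kn_dcs(E, grid)
  cdf <- cumsum(c(0, diff(grid) * (dens[-1] + dens[-length(dens)]) / 2))
  cdf / cdf[length(cdf)]
}

# brute-force 1-D gamma: exact minimum over each linear segment of the
# evaluated profile via stats::optimize, plus segment endpoints
oracle_gamma_1d <- function(ref, eval, dose_pct, dist_mm, cap = 2,
                            search_limit_mm = cap * dist_mm) {
  xr <- ref$position_cm * 10
  xe <- eval$position_cm * 10
  de <- eval$dose
  vapply(seq_along(xr), function(i) {
    dn <- ref$dose[i] * dose_pct / 100
    if (dn <= 0) return(NA_real_)
    lo <- xr[i] - search_limit_mm
    hi <- xr[i] + search_limit_mm
    best <- Inf
    for (s in seq_len(length(xe) - 1)) {
      a <- max(xe[s], lo)
      b <- min(xe[s + 1], hi)
      if (a > b) next
      f <- function(x) {
        dd <- de[s] + (de[s + 1] - de[s]) * (x - xe[s]) / (xe[s + 1] - xe[s])
        sqrt(((x - xr[i]) / dist_mm)^2 + ((dd - ref$dose[i]) / dn)^2)
      }
      best <- min(best, f(a), f(b))
      if (b - a > 1e-9)
        best <- min(best, stats::optimize(f, c(a, b), tol = 1e-10)$objective)
    }
    min(best, cap)
  }, numeric(1))
}

# analytic ray/axis-aligned-box intersection length (slab method)
oracle_box_intersection <- function(p, d, lo, hi) {
  d <- d / sqrt(sum(d^2))
  t0 <- -Inf
  t1 <- Inf
  for (k in 1:3) {
    if (abs(d[k]) < 1e-15) {
      if (p[k] < lo[k] || p[k] > hi[k]) return(0)
    } else {
      ta <- (lo[k] - p[k]) / d[k]
      tb <- (hi[k] - p[k]) / d[k]
      t0 <- max(t0, min(ta, tb))
      t1 <- min(t1, max(ta, tb))
    }
  }
  max(0, t1 - max(t0, 0))
}

# shell-averaged uncollided kerma for a monoenergetic point source in a
# uniform medium: E muen (exp(-mu r1) - exp(-mu r2)) / mu / V_shell
oracle_primary_shell_kerma <- function(E, mu, muen_rho, r1, r2) {
  v <- 4 * pi / 3 * (r2^3 - r1^3)
  E * muen_rho * (exp(-mu * r1) - exp(-mu * r2)) / mu / v * 1.602176634e-10
}
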