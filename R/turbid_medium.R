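#' Turbid slab optical properties
#'
#' Bundle of the optical properties of a homogeneous scattering slab:
#' scattering coefficient `mus` (1/mm), absorption coefficient `mua` (1/mm),
#' scattering anisotropy `g` (mean cosine of the single-scattering polar
#' angle), refractive index `n`, thickness `d` (mm), ambient index outside
#' the slab, and a per-event Rayleigh weight factor `gamma_r`.
#'
#' The free-path sampler assumes absorption is weak relative to scattering
#' (path lengths are drawn from `mus` alone and absorption is applied as a
#' Beer-Lambert weight); a warning is issued when `mua > 0.1 * mus`.
#'
#' @param mus scattering coefficient, 1/mm (> 0).
#' @param mua absorption coefficient, 1/mm (>= 0).
#' @param g anisotropy factor, -1 < g < 1.
#' @param n slab refractive index (>= 1).
#' @param d slab thickness, mm (> 0).
#' @param n_ambient refractive index outside the slab (>= 1).
#' @param gamma_r per-scattering-event weight factor (default 1).
#' @return object of class `medium_optics`.
#' @examples
#' medium_optics(mus = 6, mua = 0.01, g = 0.8, n = 1.4, d = 8)
#' @export
medium_optics <- function(mus, mua = 0, g, n = 1.4, d, n_ambient = 1,
                          gamma_r = 1) {
  stopifnot(length(mus) == 1, length(mua) == 1, length(g) == 1,
            length(n) == 1, length(d) == 1)
  if (!is.finite(mus) || mus < 0) stop("'mus' must be >= 0")
  if (!is.finite(mua) || mua < 0) stop("'mua' must be >= 0")
  if (!is.finite(g) || abs(g) >= 1) stop("'g' must satisfy -1 < g < 1")
  if (!is.finite(d) || d <= 0) stop("'d' must be positive")
  if (!is.finite(n) || n < 1) stop("'n' must be >= 1")
  if (!is.finite(n_ambient) || n_ambient < 1) stop("'n_ambient' must be >= 1")
  if (!is.finite(gamma_r) || gamma_r < 0) stop("'gamma_r' must be >= 0")
  if (mus > 0 && mua > 0.1 * mus) {
    warning("mua > 0.1 * mus: the free-path sampler assumes mua << mus")
  }
  structure(
    list(mus = mus, mua = mua, g = g, n = n, d = d, n_ambient = n_ambient,
         gamma_r = gamma_r),
    class = "medium_optics")
}

#' @export
print.medium_optics <- function(x, ...) {
  cat(sprintf(
    "turbid slab: mus = %g /mm, mua = %g /mm, g = %g, n = %g, d = %g mm (d/l* = %g)\n",
    x$mus, x$mua, x$g, x$n, x$d, optical_depth(x)))
  invisible(x)
}

#' Transport mean free path l* = 1 / (mus * (1 - g))
#'
#' @param medium a [medium_optics()].
#' @return transport (reduced) mean free path, mm.
#' @export
transport_mfp <- function(medium) {
  stopifnot(inherits(medium, "medium_optics"))
  if (medium$mus <= 0) return(Inf)
  1 / (medium$mus * (1 - medium$g))
}

#' Optical depth d / l*
#'
#' Slab thickness in units of the transport (reduced) mean free path,
#' `d * mus * (1 - g)`. The transport definition of l* reproduces the
#' conventional labelling of tissue phantoms (for example d = 8 mm,
#' mus = 6 /mm, g = 0.8 gives d/l* = 9.6; d = 1 mm, mus = 10 /mm, g = 0.8
#' gives 2.0), whereas the scattering mean free path 1/mus would not.
#'
#' @param medium a [medium_optics()].
#' @return dimensionless optical depth.
#' @export
optical_depth <- function(medium) {
  stopifnot(inherits(medium, "medium_optics"))
  medium$d * medium$mus * (1 - medium$g)
}

#' Henyey-Greenstein phase function
#'
#' Per-steradian single-scattering density
#' `p_HG(cos theta') = (1/4pi) (1 - g^2) / (1 + g^2 - 2 g cos theta')^(3/2)`.
#'
#' @param cos_theta cosine(s) of the polar scattering angle, in \[-1, 1\].
#' @param g anisotropy factor, |g| < 1.
#' @return density per steradian.
#' @export
hg_pdf <- function(cos_theta, g) {
  if (abs(g) >= 1) stop("'g' must satisfy |g| < 1")
  if (any(abs(cos_theta) > 1 + 1e-12)) stop("|cos_theta| must be <= 1")
  (1 - g^2) / (4 * pi * (1 + g^2 - 2 * g * cos_theta)^1.5)
}

#' Sample scattering angles by inversion of the HG phase function
#'
#' Closed-form inverse-CDF sampling of the polar angle,
#' `cos theta' = (1/2g) * (1 + g^2 - ((1 - g^2) / (1 - g + 2 g xi1))^2)`
#' for `g != 0` (isotropic `2 xi1 - 1` otherwise), with the azimuth uniform
#' on `[0, 2 pi)` (the HG kernel has no azimuthal dependence).
#'
#' @param g anisotropy factor, |g| < 1.
#' @param xi1,xi2 uniform random numbers in (0, 1].
#' @return list with `cos_theta` and `azimuth` vectors.
#' @export
sample_scatter_angles <- function(g, xi1, xi2) {
  if (abs(g) >= 1) stop("'g' must satisfy |g| < 1")
  if (any(xi1 <= 0 | xi1 > 1) || any(xi2 <= 0 | xi2 > 1)) {
    stop("'xi1' and 'xi2' must lie in (0, 1]")
  }
  ct <- if (g == 0) {
    2 * xi1 - 1
  } else {
    (1 + g^2 - ((1 - g^2) / (1 - g + 2 * g * xi1))^2) / (2 * g)
  }
  list(cos_theta = pmin(1, pmax(-1, ct)), azimuth = 2 * pi * xi2)
}

#' Inverse-CDF sampler for an arbitrary tabulated phase function
#'
#' Builds a table-lookup inverse CDF for any azimuthally symmetric phase
#' function given as a density in `cos theta'`. Used when no closed-form
#' inversion exists; the Henyey-Greenstein kernel has one and uses
#' [sample_scatter_angles()] instead.
#'
#' @param pdf function of `cos_theta` returning a per-steradian density
#'   (any positive scale; it is renormalized internally).
#' @param n_table number of table nodes (default 4096).
#' @return function of `(xi1)` returning sampled `cos_theta` values.
#' @export
tabulated_scatter_sampler <- function(pdf, n_table = 4096) {
  ct <- seq(-1, 1, length.out = n_table)
  dens <- pdf(ct)
  if (any(!is.finite(dens)) || any(dens < 0)) stop("invalid phase function")
  cdf <- cumsum((dens[-1] + dens[-n_table]) / 2 * diff(ct))
  cdf <- c(0, cdf) / cdf[n_table - 1]
  inv <- stats::approxfun(cdf, ct, ties = "ordered", yleft = -1, yright = 1)
  function(xi1) inv(xi1)
}

#' Sample exponential free path
#'
#' `l = -log(xi) / mus`, the path length between successive scattering
#' events in a medium of scattering coefficient `mus`.
#'
#' @param mus scattering coefficient, 1/mm (> 0).
#' @param xi uniform random number(s) in (0, 1].
#' @return path length(s), mm.
#' @export
sample_free_path <- function(mus, xi) {
  if (!is.finite(mus) || mus <= 0) stop("'mus' must be positive")
  if (any(xi <= 0 | xi > 1)) stop("'xi' must lie in (0, 1]")
  -log(xi) / mus
}

#' Snell/Fresnel interaction at a planar boundary
#'
#' Refracts and reflects a photon direction at an interface between indices
#' `n1` (incident side) and `n2`, applying the Fresnel amplitude
#' coefficients separately to the s- and p-components of each polarization
#' vector. Energy is bookkept through the power transmittance/reflectance
#' of the actual polarization content carried by the pair `(P_x, P_y)`;
#' the outgoing polarization pairs are rescaled to a common norm so that
#' statistical weight alone carries the energy split. Beyond the critical
#' angle the transmittance is exactly zero (total internal reflection).
#'
#' @param direction unit 3-vector of propagation.
#' @param px,py real polarization 3-vectors (the tracked pair).
#' @param n1,n2 refractive indices on the incident and far side.
#' @param normal unit surface normal; its orientation is internally aligned
#'   with the propagation direction.
#' @return list with `transmitted`, `reflected` (unit directions),
#'   `transmittance`, `reflectance` (powers, summing to one),
#'   `px_t`, `py_t`, `px_r`, `py_r` (outgoing polarization pairs), and
#'   `tir` (logical).
#' @export
boundary_interact <- function(direction, px, py, n1, n2,
                              normal = c(0, 0, 1)) {
  d <- as.numeric(direction)
  if (abs(sqrt(sum(d^2)) - 1) > 1e-9) stop("'direction' must be unit length")
  if (n1 < 1 || n2 < 1) stop("indices must be >= 1")
  nh <- as.numeric(normal) / sqrt(sum(normal^2))
  if (sum(d * nh) < 0) nh <- -nh
  c1 <- sum(d * nh)
  s1 <- sqrt(max(0, 1 - c1^2))
  eta <- n1 / n2
  s2 <- eta * s1
  refl_dir <- d - 2 * c1 * nh

  if (s2 >= 1) {           # total internal reflection
    return(list(transmitted = NULL, reflected = refl_dir,
                transmittance = 0, reflectance = 1,
                px_t = NULL, py_t = NULL, px_r = px, py_r = py, tir = TRUE))
  }
  c2 <- sqrt(1 - s2^2)
  trans_dir <- eta * d + (c2 - eta * c1) * nh
  trans_dir <- trans_dir / sqrt(sum(trans_dir^2))

  ts <- 2 * n1 * c1 / (n1 * c1 + n2 * c2)
  tp <- 2 * n1 * c1 / (n2 * c1 + n1 * c2)
  rs <- (n1 * c1 - n2 * c2) / (n1 * c1 + n2 * c2)
  rp <- (n2 * c1 - n1 * c2) / (n2 * c1 + n1 * c2)
  pow <- n2 * c2 / (n1 * c1)

  if (s1 < 1e-12) {
    # normal incidence: the s/p frame is degenerate and the coefficients
    # coincide; reuse the incoming polarization frame
    T <- pow * ts^2
    R <- rs^2
    return(list(transmitted = trans_dir, reflected = refl_dir,
                transmittance = T, reflectance = R,
                px_t = px, py_t = py, px_r = px, py_r = py, tir = FALSE))
  }

  sh <- c(d[2] * nh[3] - d[3] * nh[2],
          d[3] * nh[1] - d[1] * nh[3],
          d[1] * nh[2] - d[2] * nh[1])
  sh <- sh / sqrt(sum(sh^2))
  p1 <- c(sh[2] * d[3] - sh[3] * d[2],
          sh[3] * d[1] - sh[1] * d[3],
          sh[1] * d[2] - sh[2] * d[1])
  p2 <- c(sh[2] * trans_dir[3] - sh[3] * trans_dir[2],
          sh[3] * trans_dir[1] - sh[1] * trans_dir[3],
          sh[1] * trans_dir[2] - sh[2] * trans_dir[1])
  pr <- c(sh[2] * refl_dir[3] - sh[3] * refl_dir[2],
          sh[3] * refl_dir[1] - sh[1] * refl_dir[3],
          sh[1] * refl_dir[2] - sh[2] * refl_dir[1])

  split_one <- function(P, coef_s, coef_p, pout) {
    as_ <- sum(P * sh); ap <- sum(P * p1)
    list(v = coef_s * as_ * sh + coef_p * ap * pout,
         pow2 = c(s = as_^2, p = ap^2))
  }
  xt <- split_one(px, ts, tp, p2); yt <- split_one(py, ts, tp, p2)
  xr <- split_one(px, rs, rp, pr); yr <- split_one(py, rs, rp, pr)

  # energy splits over the transverse (s/p) content only, so that
  # reflectance + transmittance = 1 holds exactly
  norm0 <- sum(xt$pow2) + sum(yt$pow2)
  pow_t <- sum(xt$v^2) + sum(yt$v^2)
  pow_r <- sum(xr$v^2) + sum(yr$v^2)
  T <- pow * pow_t / norm0
  R <- pow_r / norm0
  scl_t <- if (pow_t > 0) sqrt(norm0 / pow_t) else 1
  scl_r <- if (pow_r > 0) sqrt(norm0 / pow_r) else 1

  list(transmitted = trans_dir, reflected = refl_dir,
       transmittance = T, reflectance = R,
       px_t = xt$v * scl_t, py_t = yt$v * scl_t,
       px_r = xr$v * scl_r, py_r = yr$v * scl_r, tir = FALSE)
}
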