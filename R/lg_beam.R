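#' Laguerre-Gaussian beam specification
#'
#' Defines an LG_p^l mode by its topological charge, radial index, waist and
#' wavelength. Derived quantities (wavenumber `k = 2*pi/lambda`, Rayleigh
#' range `z_R = pi*w0^2/lambda`) are computed once and stored. All lengths
#' are millimetres, so `k` and `z_R` come out in 1/mm and mm.
#'
#' @param l integer topological charge (sign sets the handedness of the
#'   helical phase `exp(-i*l*phi)`).
#' @param p non-negative integer radial index.
#' @param w0 beam waist of the embedded zero-order Gaussian, mm.
#' @param wavelength vacuum wavelength, mm (633 nm = 6.33e-4 mm).
#' @param omega angular frequency (s^-1). Only a common scale factor of the
#'   Poynting vector; it never affects normalized launch directions. Kept
#'   for completeness, default 1.
#' @return object of class `beam_spec`.
#' @examples
#' beam_spec(l = 3, p = 0, w0 = 0.8, wavelength = 633e-6)
#' @export
beam_spec <- function(l, p = 0L, w0, wavelength, omega = 1) {
  stopifnot(length(l) == 1, length(p) == 1, length(w0) == 1,
            length(wavelength) == 1)
  if (!is.finite(l) || l != round(l)) stop("'l' must be a (signed) integer")
  if (!is.finite(p) || p != round(p) || p < 0) {
    stop("'p' must be a non-negative integer")
  }
  if (!is.finite(w0) || w0 <= 0) stop("'w0' must be positive")
  if (!is.finite(wavelength) || wavelength <= 0) {
    stop("'wavelength' must be positive")
  }
  structure(
    list(l = as.integer(l), p = as.integer(p), w0 = w0,
         wavelength = wavelength, k = 2 * pi / wavelength,
         z_r = pi * w0^2 / wavelength, omega = omega),
    class = "beam_spec")
}

#' @export
print.beam_spec <- function(x, ...) {
  cat(sprintf("LG_%d^%+d beam: w0 = %g mm, lambda = %g nm, z_R = %g mm\n",
              x$p, x$l, x$w0, x$wavelength * 1e6, x$z_r))
  invisible(x)
}

#' Beam radius w(z)
#'
#' @param beam a [beam_spec()].
#' @param z axial distance from the waist, mm.
#' @return beam radius at `z`, mm.
#' @export
beam_radius <- function(beam, z) {
  beam$w0 * sqrt(1 + (z / beam$z_r)^2)
}

#' Gouy phase G(z) = (2p + |l| + 1) * arctan(z / z_R)
#'
#' @inheritParams beam_radius
#' @return Gouy phase in radians (unwrapped).
#' @export
gouy_phase <- function(beam, z) {
  (2 * beam$p + abs(beam$l) + 1) * atan(z / beam$z_r)
}

# Generalized Laguerre polynomial L_p^alpha(x) by the standard three-term
# recurrence; p is small (radial index), so this is exact and cheap.
glaguerre <- function(p, alpha, x) {
  if (p == 0L) return(rep(1, length(x)))
  lm1 <- rep(1, length(x))
  lc <- 1 + alpha - x
  if (p == 1L) return(lc)
  for (k in 1:(p - 1)) {
    lp1 <- ((2 * k + 1 + alpha - x) * lc - (k + alpha) * lm1) / (k + 1)
    lm1 <- lc
    lc <- lp1
  }
  lc
}

#' Complex Laguerre-Gaussian field (paraxial)
#'
#' Evaluates the normalized paraxial LG_p^l mode
#' \deqn{LG(\rho,\phi,z) = \sqrt{\frac{2 p!}{\pi(|l|+p)! w^2(z)}}
#'   \left[\frac{\sqrt2 \rho}{w(z)}\right]^{|l|}
#'   L_p^{|l|}\!\left(\frac{2\rho^2}{w^2(z)}\right)
#'   e^{-\rho^2/w^2(z)} e^{i(2p+|l|+1)\arctan(z/z_R)}
#'   e^{-ik\rho^2 z / 2(z^2+z_R^2)} e^{-il\phi} e^{-ikz},}
#' normalized so that the transverse intensity integrates to one at every z.
#'
#' @param beam a [beam_spec()].
#' @param rho radial coordinate(s), mm (>= 0).
#' @param phi azimuth(s), radians.
#' @param z axial distance(s) from the waist, mm.
#' @return complex field amplitude (units 1/mm so that
#'   `integral |LG|^2 rho drho dphi = 1`).
#' @export
lg_field <- function(beam, rho, phi, z) {
  stopifnot(inherits(beam, "beam_spec"))
  if (any(!is.finite(rho)) || any(!is.finite(phi)) || any(!is.finite(z))) {
    stop("non-finite coordinates")
  }
  if (any(rho < 0)) stop("'rho' must be >= 0")
  la <- abs(beam$l)
  w <- beam_radius(beam, z)
  u <- 2 * rho^2 / w^2
  amp <- sqrt(2 * factorial(beam$p) / (pi * factorial(la + beam$p))) / w *
    (sqrt(2) * rho / w)^la * glaguerre(beam$p, la, u) * exp(-rho^2 / w^2)
  ph <- lg_phase(beam, rho, phi, z, wrap = FALSE)
  amp * exp(1i * ph)
}

#' LG beam phase evolution
#'
#' The phase of the paraxial LG mode,
#' \deqn{\Psi(\rho,\phi,z) = \frac{-k\rho^2 z}{2(z^2+z_R^2)} - l\phi - kz
#'   + G(z),}
#' with the Gouy term `G(z) = (2p+|l|+1) arctan(z/z_R)`. This is the argument
#' of [lg_field()] wherever the real radial envelope is positive (for p > 0
#' the generalized Laguerre polynomial changes sign across its radial nodes,
#' which adds pi to the argument there).
#'
#' @inheritParams lg_field
#' @param wrap if `TRUE` (default) wrap the result to (-pi, pi]; otherwise
#'   return the unwrapped value.
#' @return phase in radians.
#' @export
lg_phase <- function(beam, rho, phi, z, wrap = TRUE) {
  stopifnot(inherits(beam, "beam_spec"))
  if (any(!is.finite(rho)) || any(!is.finite(phi)) || any(!is.finite(z))) {
    stop("non-finite coordinates")
  }
  ps <- -beam$k * rho^2 * z / (2 * (z^2 + beam$z_r^2)) - beam$l * phi -
    beam$k * z + gouy_phase(beam, z)
  if (wrap) wrap_phase(ps) else ps
}

#' Poynting-vector launch direction
#'
#' The local energy-flow direction of an LG mode in Cartesian components,
#' \deqn{s_x = \frac{kzx}{z^2+z_R^2} - \frac{l y}{x^2+y^2}, \quad
#'       s_y = \frac{kzy}{z^2+z_R^2} + \frac{l x}{x^2+y^2}, \quad
#'       s_z = k,}
#' normalized to unit length. The azimuthal term carries the OAM-induced
#' skew; it is singular on the axis, so on-axis requests with `l != 0` are
#' rejected.
#'
#' @param beam a [beam_spec()].
#' @param x,y transverse coordinates, mm.
#' @param z axial coordinate, mm.
#' @return n x 3 matrix of unit direction vectors.
#' @export
launch_direction <- function(beam, x, y, z) {
  stopifnot(inherits(beam, "beam_spec"))
  n <- max(length(x), length(y), length(z))
  x <- rep_len(x, n); y <- rep_len(y, n); z <- rep_len(z, n)
  r2 <- x^2 + y^2
  if (beam$l != 0 && any(r2 == 0)) {
    stop("on-axis launch direction is singular for l != 0")
  }
  curv <- beam$k * z / (z^2 + beam$z_r^2)
  azim <- if (beam$l == 0) 0 else beam$l / r2
  sx <- curv * x - azim * y
  sy <- curv * y + azim * x
  sz <- rep_len(beam$k, n)
  nrm <- sqrt(sx^2 + sy^2 + sz^2)
  cbind(sx = sx / nrm, sy = sy / nrm, sz = sz / nrm)
}

#' Sample source photons from an LG mode
#'
#' Draws transverse launch positions with probability density proportional
#' to the local mode intensity `|LG|^2` at the launch plane (rejection
#' sampling under a uniform disc envelope), assigns every photon the same
#' statistical weight, the analytic mode phase at its own position as
#' initial phase, the local Poynting direction as initial direction, and a
#' linear polarization pair (P_x along the configured axis orthogonalized
#' against the direction, P_y completing the right-handed triad).
#'
#' @param beam a [beam_spec()].
#' @param n number of photons (>= 1).
#' @param z_launch launch plane distance from the waist, mm (default 0: the
#'   waist coincides with the medium entry face).
#' @param weight common initial statistical weight (default 1).
#' @param polarization `"x"` (horizontal, default) or `"y"`.
#' @param seed optional integer seed; if `NULL` the current RNG stream is
#'   used (so callers can manage reproducibility globally).
#' @return data.frame with one row per photon: position `x, y, z`, unit
#'   direction `sx, sy, sz`, initial phase `psi0` (wrapped), weight `w`, and
#'   polarization vectors `pxx, pxy, pxz, pyx, pyy, pyz`.
#' @export
sample_source <- function(beam, n, z_launch = 0, weight = 1,
                          polarization = c("x", "y"), seed = NULL) {
  stopifnot(inherits(beam, "beam_spec"))
  if (!is.finite(n) || n < 1) stop("'n' must be >= 1")
  n <- as.integer(n)
  polarization <- match.arg(polarization)
  if (!is.null(seed)) set.seed(seed)

  w <- beam_radius(beam, z_launch)
  rmax <- w * (sqrt((abs(beam$l) + 2 * beam$p) / 2) + 4.5)
  guard <- 1e-12 * beam$w0
  # envelope: uniform over the disc; majorant from a dense radial scan
  rg <- seq(guard, rmax, length.out = 4096)
  dens_max <- max(Mod(lg_field(beam, rg, 0, z_launch))^2) * 1.05

  xs <- numeric(0); ys <- numeric(0)
  acc_est <- 0.15
  iter <- 0L
  while (length(xs) < n) {
    iter <- iter + 1L
    if (iter > 1000L) stop("rejection sampling failed to converge")
    m <- max(1000L, ceiling((n - length(xs)) / acc_est * 1.2))
    m <- min(m, 4e6)
    r <- rmax * sqrt(runif(m))
    ph <- runif(m, -pi, pi)
    dens <- Mod(lg_field(beam, r, ph, z_launch))^2
    if (any(dens > dens_max)) stop("rejection envelope violated")
    keep <- (runif(m) * dens_max < dens) & (r > guard)
    if (any(keep)) {
      xs <- c(xs, (r * cos(ph))[keep])
      ys <- c(ys, (r * sin(ph))[keep])
      acc_est <- max(mean(keep), 1e-3)
    }
  }
  xs <- xs[seq_len(n)]; ys <- ys[seq_len(n)]
  rho <- sqrt(xs^2 + ys^2)
  phi <- atan2(ys, xs)
  psi0 <- lg_phase(beam, rho, phi, z_launch)
  s <- launch_direction(beam, xs, ys, z_launch)

  # P_x: transverse part of the polarization axis; P_y = s x P_x
  ax <- if (polarization == "x") c(1, 0, 0) else c(0, 1, 0)
  dp <- s[, 1] * ax[1] + s[, 2] * ax[2] + s[, 3] * ax[3]
  px <- cbind(ax[1] - dp * s[, 1], ax[2] - dp * s[, 2], ax[3] - dp * s[, 3])
  px <- px / sqrt(rowSums(px^2))
  py <- cbind(s[, 2] * px[, 3] - s[, 3] * px[, 2],
              s[, 3] * px[, 1] - s[, 1] * px[, 3],
              s[, 1] * px[, 2] - s[, 2] * px[, 1])

  data.frame(x = xs, y = ys, z = z_launch, sx = s[, 1], sy = s[, 2],
             sz = s[, 3], psi0 = psi0, w = weight,
             pxx = px[, 1], pxy = px[, 2], pxz = px[, 3],
             pyx = py[, 1], pyy = py[, 2], pyz = py[, 3])
}

#' Forked hologram phase pattern
#'
#' Phase map of the SLM grating that converts a Gaussian beam into an LG
#' beam in the first diffraction order: a blazed linear grating with an
#' l-pronged edge dislocation at the origin,
#' `phase(x, y) = wrap(l * atan2(y, x) + 2*pi*x / period)`.
#'
#' @param l integer topological charge imprinted by the fork.
#' @param period grating period, mm (> 0).
#' @param grid a [pixel_grid()].
#' @return matrix (ny rows x nx columns, row = y index increasing upward) of
#'   wrapped phases in (-pi, pi].
#' @export
fork_hologram <- function(l, period, grid) {
  stopifnot(inherits(grid, "pixel_grid"))
  if (!is.finite(period) || period <= 0) stop("'period' must be positive")
  if (l != round(l)) stop("'l' must be an integer")
  ctr <- pixel_centers(grid)
  xm <- matrix(ctr$x, nrow = grid$ny, ncol = grid$nx, byrow = TRUE)
  ym <- matrix(ctr$y, nrow = grid$ny, ncol = grid$nx)
  wrap_phase(l * atan2(ym, xm) + 2 * pi * xm / period)
}
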