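# centered unitary 2D DFT helpers (DC at the grid center)
fftshift2 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  m[c((floor(nr / 2) + 1):nr, 1:floor(nr / 2)),
    c((floor(nc / 2) + 1):nc, 1:floor(nc / 2)), drop = FALSE]
}
ifftshift2 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  m[c((ceiling(nr / 2) + 1):nr, 1:ceiling(nr / 2)),
    c((ceiling(nc / 2) + 1):nc, 1:ceiling(nc / 2)), drop = FALSE]
}
lens_ft <- function(m) {
  fftshift2(stats::fft(ifftshift2(m))) / sqrt(length(m))
}

#' Log-polar OAM sorter geometry
#'
#' Geometry of the two-element log-polar mode sorter: the first phase
#' element performs the Cartesian to log-polar mapping that unwraps the
#' helical phase `exp(-i l phi)` into a linear transverse gradient, the
#' second corrects the residual phase so a lens focuses each charge to a
#' distinct lateral position spaced by `lambda f / (2 pi a)`.
#'
#' Defaults are chosen for numerical stability on the given grid: `a`
#' (azimuth-to-length scale, mapping 2*pi to 2*pi*a) is an eighth of the
#' grid width over pi/2 (`a = W/(4 pi)`), so the unwrapped strip fills half
#' of the transformed plane and adjacent charges land 4 pixels apart;
#' `b` is of order the beam size; `f` makes the transformed plane twice the
#' input width.
#'
#' @param grid a square [pixel_grid()].
#' @param wavelength vacuum wavelength, mm.
#' @param a azimuthal scale, mm; default `nx * pitch / (4 pi)`.
#' @param b radial reference, mm; default `0.75 * waist` (or a tenth of the
#'   grid width when no waist is given).
#' @param f focal length of the Fourier lenses, mm; default
#'   `2 * nx * pitch^2 / wavelength`.
#' @param waist beam scale used for the `b` default, mm.
#' @return object of class `sorter_geometry`.
#' @export
sorter_geometry <- function(grid, wavelength, a = NULL, b = NULL, f = NULL,
                            waist = NULL) {
  stopifnot(inherits(grid, "pixel_grid"))
  if (grid$nx != grid$ny) stop("the sorter requires a square grid")
  W <- grid$nx * grid$pitch
  if (is.null(a)) a <- W / (4 * pi)
  if (is.null(b)) b <- if (is.null(waist)) W / 10 else 0.75 * waist
  if (is.null(f)) f <- 2 * W * grid$pitch / wavelength
  if (a <= 0 || b <= 0 || f <= 0 || wavelength <= 0) {
    stop("sorter parameters must be positive")
  }
  structure(list(a = a, b = b, f = f, wavelength = wavelength, grid = grid,
                 spacing = wavelength * f / (2 * pi * a)),
            class = "sorter_geometry")
}

#' @export
print.sorter_geometry <- function(x, ...) {
  cat(sprintf(
    "log-polar OAM sorter: a = %.4g mm, b = %.4g mm, f = %.4g mm, charge spacing = %.4g mm\n",
    x$a, x$b, x$f, x$spacing))
  invisible(x)
}

#' Unwrapping phase element of the log-polar sorter
#'
#' First element: imposes
#' `phi1(x, y) = (2 pi a / lambda f) * (y atan2(y, x) - x ln(r / b) + x)`,
#' whose stationary-phase mapping carries `(x, y)` to the log-polar point
#' `(u, v) = (-a ln(r/b), a atan2(y, x))` in the transformed plane.
#'
#' @param geom a [sorter_geometry()].
#' @return phase matrix (radians, unwrapped) on the element grid.
#' @export
unwrap_element <- function(geom) {
  stopifnot(inherits(geom, "sorter_geometry"))
  m <- grid_mesh(geom$grid)
  r <- sqrt(m$x^2 + m$y^2)
  r[r == 0] <- geom$grid$pitch * 1e-6     # origin guard: no energy there
  2 * pi * geom$a / (geom$wavelength * geom$f) *
    (m$y * atan2(m$y, m$x) - m$x * log(r / geom$b) + m$x)
}

#' Phase-correction element of the log-polar sorter
#'
#' Second element, applied in the transformed (log-polar) plane:
#' `phi2(u, v) = -(2 pi a b / lambda f) * exp(-u/a) * cos(v/a)`,
#' which cancels the residual phase of the coordinate mapping so the final
#' lens can focus each unwrapped charge to a sharp lateral spot.
#'
#' @param geom a [sorter_geometry()].
#' @return phase matrix (radians) on the transformed-plane grid.
#' @export
correct_element <- function(geom) {
  stopifnot(inherits(geom, "sorter_geometry"))
  g2 <- transformed_grid(geom)
  m <- grid_mesh(g2)
  -2 * pi * geom$a * geom$b / (geom$wavelength * geom$f) *
    exp(-m$x / geom$a) * cos(m$y / geom$a)
}

# grid of the transformed (Fourier) plane: pitch lambda*f/(N*pitch)
transformed_grid <- function(geom) {
  g <- geom$grid
  pixel_grid(g$nx, g$ny, geom$wavelength * geom$f / (g$nx * g$pitch))
}

#' Reference (l = 0) landing position of the sorter
#'
#' Sorts a plain Gaussian of the given waist through the geometry and
#' returns the centroid position of its output profile; charge readout is
#' measured from this zero-OAM reference.
#'
#' @param geom a [sorter_geometry()].
#' @param waist Gaussian waist, mm.
#' @return reference position, mm, in the sorted plane.
#' @export
sorter_reference <- function(geom, waist) {
  gauss <- field_map(function(x, y) exp(-(x^2 + y^2) / waist^2) + 0i,
                     geom$grid)
  sort_oam(gauss, geom, reference = 0, check_resolution = FALSE)$centroid
}

#' Sort a field by topological charge (log-polar transform)
#'
#' Applies the unwrapping element, propagates to the transformed plane with
#' an idealized lens Fourier transform, applies the phase-correction
#' element, and focuses with a second lens transform. The helical phase
#' `exp(-i l phi)` becomes a linear gradient `exp(-i l v / a)`, so charge l
#' lands at lateral position `-l * lambda f / (2 pi a)` along the unwrapped
#' (v-conjugate) axis. The charge estimate is the intensity-weighted
#' centroid of the output profile (within a window around its peak),
#' converted to charge units and snapped to the nearest integer (ties
#' toward 0).
#'
#' @param field a `field_map` (analytic or [mc_field()] from an MC image)
#'   on the sorter grid.
#' @param geom a [sorter_geometry()] on the same grid.
#' @param reference l = 0 landing position, mm (from [sorter_reference()];
#'   default 0, the ideal symmetric value).
#' @param check_resolution reject inputs whose phase elements are
#'   undersampled on this grid (default TRUE).
#' @return list with `l_hat` (integer charge estimate), `centroid` (mm),
#'   `displacement` (mm, centroid - reference), `profile` (data.frame
#'   `position`, `intensity`: output intensity summed over the transverse
#'   coordinate), `plane_intensity` (full output intensity matrix),
#'   `spacing` (mm per unit charge), `reference`.
#' @export
sort_oam <- function(field, geom, reference = 0, check_resolution = TRUE) {
  stopifnot(inherits(field, "field_map"), inherits(geom, "sorter_geometry"))
  g <- geom$grid
  if (field$grid$nx != g$nx || field$grid$ny != g$ny ||
      abs(field$grid$pitch - g$pitch) > 1e-12) {
    stop("field and sorter geometry must share one grid")
  }
  if (check_resolution) {
    m <- grid_mesh(g)
    r <- sqrt(m$x^2 + m$y^2)
    r[r == 0] <- g$pitch
    supp <- Mod(field$field) > 1e-3 * max(Mod(field$field))
    gradmax <- 2 * pi * geom$a / (geom$wavelength * geom$f) *
      max(sqrt(log(r / geom$b)^2 + atan2(m$y, m$x)^2)[supp])
    if (gradmax * g$pitch > pi) {
      stop("input grid does not resolve the sorter phase elements; ",
           "use a finer grid or a smaller 'a'")
    }
  }
  e1 <- field$field * exp(1i * unwrap_element(geom))
  t1 <- lens_ft(e1)
  e2 <- t1 * exp(1i * correct_element(geom))
  t2 <- lens_ft(e2)
  out_int <- Mod(t2)^2

  g3 <- pixel_grid(g$nx, g$ny,
                   geom$wavelength * geom$f /
                     (g$nx * transformed_grid(geom)$pitch))
  pos <- pixel_centers(g3)$y
  profile <- rowSums(out_int)

  s <- geom$spacing
  pk <- pos[which.max(profile)]
  win <- abs(pos - pk) <= 3 * s
  centroid <- sum(pos[win] * profile[win]) / sum(profile[win])
  est <- -(centroid - reference) / s
  l_hat <- round(est)
  if (abs(abs(est - trunc(est)) - 0.5) < 1e-12) l_hat <- trunc(est)

  list(l_hat = as.integer(l_hat), centroid = centroid,
       displacement = centroid - reference,
       profile = data.frame(position = pos, intensity = profile),
       plane_intensity = out_int, spacing = s, reference = reference)
}
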