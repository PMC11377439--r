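#' Detector pixel grid
#'
#' Square-pixel detector-plane grid. Pixel (1,1) is the lower-left pixel;
#' `origin` is the coordinate of its center (defaults to a grid centered on
#' the beam axis). Image matrices built on this grid have `ny` rows (y,
#' increasing upward) and `nx` columns (x, increasing rightward).
#'
#' @param nx,ny pixel counts (>= 1).
#' @param pitch pixel size, mm/pixel (> 0).
#' @param origin length-2 numeric, mm coordinates of the center of pixel
#'   (1,1); default centers the grid on (0, 0).
#' @return object of class `pixel_grid`.
#' @export
pixel_grid <- function(nx, ny = nx, pitch, origin = NULL) {
  if (nx < 1 || ny < 1) stop("pixel counts must be >= 1")
  if (pitch <= 0) stop("'pitch' must be positive")
  if (is.null(origin)) {
    origin <- c(-(nx - 1) / 2 * pitch, -(ny - 1) / 2 * pitch)
  }
  structure(list(nx = as.integer(nx), ny = as.integer(ny), pitch = pitch,
                 origin = origin),
            class = "pixel_grid")
}

#' Pixel center coordinates
#'
#' @param grid a [pixel_grid()].
#' @return list with vectors `x` (length nx) and `y` (length ny), mm.
#' @export
pixel_centers <- function(grid) {
  stopifnot(inherits(grid, "pixel_grid"))
  list(x = grid$origin[1] + (seq_len(grid$nx) - 1) * grid$pitch,
       y = grid$origin[2] + (seq_len(grid$ny) - 1) * grid$pitch)
}

# meshgrid matrices (ny x nx) of pixel-center coordinates
grid_mesh <- function(grid) {
  ctr <- pixel_centers(grid)
  list(x = matrix(ctr$x, nrow = grid$ny, ncol = grid$nx, byrow = TRUE),
       y = matrix(ctr$y, nrow = grid$ny, ncol = grid$nx))
}

#' Coherent pixel-wise image formation
#'
#' Bins detected photons onto the grid and forms, per pixel, the coherent
#' intensity
#' \deqn{I_{px} = \sum_j W_j + 2 \sum_{i<j} \sqrt{W_i W_j}
#'   \cos(\Psi_i - \Psi_j)}
#' and the ensemble phase
#' \deqn{\psi = \mathrm{atan2}\!\left(\sum_j \sqrt{W_j}\sin\Psi_j,
#'   \sum_j \sqrt{W_j}\cos\Psi_j\right),}
#' implemented through the complex accumulator `A = sum sqrt(W) exp(i Psi)`
#' with `I = |A|^2`, `psi = arg(A)` (algebraically identical to the pairwise
#' form, which is retained in [pairwise_intensity()] as a test oracle).
#' The incoherent weight sum `sum W` and the photon occupancy are returned
#' alongside; pixels with zero photons carry `NA` phase.
#'
#' @param records data.frame with columns `x`, `y`, `psi`, `w` (e.g. the
#'   `records` of a `transport_result`).
#' @param grid a [pixel_grid()].
#' @return object of class `image_pair`: list with matrices `intensity`
#'   (coherent I_px), `phase` (wrapped, NA where empty), `weight`
#'   (incoherent sum of W), `occupancy` (photon counts), scalar
#'   `n_excluded` (records falling outside the grid), and `grid`.
#' @export
accumulate_image <- function(records, grid) {
  stopifnot(inherits(grid, "pixel_grid"))
  nx <- grid$nx; ny <- grid$ny
  if (nrow(records) == 0) {
    z <- matrix(0, ny, nx)
    return(structure(list(intensity = z, phase = matrix(NA_real_, ny, nx),
                          weight = z, occupancy = z, n_excluded = 0L,
                          grid = grid),
                     class = "image_pair"))
  }
  ix <- floor((records$x - grid$origin[1]) / grid$pitch + 0.5)
  iy <- floor((records$y - grid$origin[2]) / grid$pitch + 0.5)
  ok <- ix >= 0 & ix < nx & iy >= 0 & iy < ny
  n_excluded <- sum(!ok)
  ix <- ix[ok]; iy <- iy[ok]
  w <- records$w[ok]; psi <- records$psi[ok]
  idx <- iy + ny * ix + 1          # column-major linear index into ny x nx
  amp <- sqrt(w)
  re <- rowsum(amp * cos(psi), idx)
  im <- rowsum(amp * sin(psi), idx)
  ws <- rowsum(w, idx)
  ct <- rowsum(rep(1, length(idx)), idx)
  lin <- as.integer(rownames(re))

  intensity <- matrix(0, ny, nx)
  weight <- matrix(0, ny, nx)
  occupancy <- matrix(0, ny, nx)
  phase <- matrix(NA_real_, ny, nx)
  intensity[lin] <- re^2 + im^2
  weight[lin] <- ws
  occupancy[lin] <- ct
  phase[lin] <- atan2(im, re)
  structure(list(intensity = intensity, phase = phase, weight = weight,
                 occupancy = occupancy, n_excluded = n_excluded, grid = grid),
            class = "image_pair")
}

#' @export
print.image_pair <- function(x, ...) {
  cat(sprintf(
    "image pair %dx%d px (%g mm/px): %d photons binned, %d excluded\n",
    x$grid$nx, x$grid$ny, x$grid$pitch, sum(x$occupancy), x$n_excluded))
  invisible(x)
}

#' Pairwise-interference intensity (test oracle)
#'
#' Direct evaluation of the double-sum interference form of the pixel
#' intensity. O(n^2) in the photons of one pixel; used to validate the
#' complex-accumulator implementation.
#'
#' @param w photon weights within one pixel.
#' @param psi photon phases within one pixel, radians.
#' @return scalar intensity.
#' @export
pairwise_intensity <- function(w, psi) {
  n <- length(w)
  total <- sum(w)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        total <- total +
          2 * sqrt(w[i] * w[j]) * cos(psi[i] - psi[j])
      }
    }
  }
  total
}

#' Analytic complex field map on a grid
#'
#' Samples an LG mode (or any complex-valued function of x, y) at the pixel
#' centers of a grid.
#'
#' @param beam a [beam_spec()], or a function `f(x, y)` returning complex.
#' @param grid a [pixel_grid()].
#' @param z axial plane, mm (used when `beam` is a `beam_spec`).
#' @return object of class `field_map`: list with complex matrix `field`
#'   (ny x nx), `grid`, `z`.
#' @export
field_map <- function(beam, grid, z = 0) {
  stopifnot(inherits(grid, "pixel_grid"))
  m <- grid_mesh(grid)
  fld <- if (inherits(beam, "beam_spec")) {
    rho <- sqrt(m$x^2 + m$y^2)
    phi <- atan2(m$y, m$x)
    matrix(lg_field(beam, as.vector(rho), as.vector(phi), z),
           nrow = grid$ny)
  } else if (is.function(beam)) {
    matrix(beam(as.vector(m$x), as.vector(m$y)), nrow = grid$ny)
  } else {
    stop("'beam' must be a beam_spec or a function of (x, y)")
  }
  structure(list(field = fld, grid = grid, z = z), class = "field_map")
}

#' Complex field from an MC image pair
#'
#' Reconstructs a per-pixel complex field `sqrt(I_px) * exp(i psi)` from a
#' coherent MC image; empty pixels contribute zero field. Intra-pixel field
#' structure is necessarily lost, so the grid pitch sets the resolution.
#'
#' @param image an `image_pair` from [accumulate_image()].
#' @return `field_map` on the same grid.
#' @export
mc_field <- function(image) {
  stopifnot(inherits(image, "image_pair"))
  ph <- image$phase
  ph[is.na(ph)] <- 0
  amp <- sqrt(pmax(image$intensity, 0))
  structure(list(field = amp * exp(1i * ph), grid = image$grid, z = NA_real_),
            class = "field_map")
}

#' Interferogram against a reference Gaussian
#'
#' Synthesizes the interference pattern `|E_s + E_r|^2` between a sample
#' field and an expanded reference Gaussian, optionally tilted for the
#' off-axis regime. On-axis (`tilt = 0`) an l-charged vortex produces an
#' l-armed spiral; off-axis it produces forked fringes with |l| extra
#' prongs.
#'
#' @param sample a `field_map` or `image_pair` (converted via [mc_field()]).
#' @param wavelength vacuum wavelength, mm (sets the tilt fringe period
#'   `wavelength / sin(tilt)`).
#' @param amplitude reference peak amplitude (0 returns the sample
#'   intensity exactly).
#' @param waist reference Gaussian 1/e^2 amplitude radius, mm (default:
#'   4x the grid half-width, i.e. effectively a plane wave).
#' @param tilt reference tilt about the y axis, radians (0 = on-axis).
#' @return intensity matrix (ny x nx).
#' @export
interferogram <- function(sample, wavelength, amplitude = 1, waist = NULL,
                          tilt = 0) {
  if (inherits(sample, "image_pair")) sample <- mc_field(sample)
  stopifnot(inherits(sample, "field_map"))
  grid <- sample$grid
  m <- grid_mesh(grid)
  if (is.null(waist)) waist <- 4 * grid$nx * grid$pitch / 2
  k <- 2 * pi / wavelength
  er <- amplitude * exp(-(m$x^2 + m$y^2) / waist^2) *
    exp(-1i * k * sin(tilt) * m$x)
  Mod(sample$field + er)^2
}

#' Annular analysis region
#'
#' @param inner,outer annulus radii, mm (0 <= inner < outer).
#' @param phi_min,phi_max azimuthal sector bounds, radians (default: full
#'   annulus).
#' @param center annulus center, mm (default on axis).
#' @return object of class `annulus_spec`.
#' @export
annulus_spec <- function(inner, outer, phi_min = -pi, phi_max = pi,
                         center = c(0, 0)) {
  if (inner < 0 || outer <= inner) stop("need 0 <= inner < outer")
  if (phi_max <= phi_min) stop("sector bounds must be ordered")
  structure(list(inner = inner, outer = outer, phi_min = phi_min,
                 phi_max = phi_max, center = center),
            class = "annulus_spec")
}

# logical mask of grid pixels inside the annulus
annulus_mask <- function(grid, annulus) {
  m <- grid_mesh(grid)
  dx <- m$x - annulus$center[1]
  dy <- m$y - annulus$center[2]
  r <- sqrt(dx^2 + dy^2)
  ph <- atan2(dy, dx)
  r >= annulus$inner & r <= annulus$outer &
    ph >= annulus$phi_min & ph <= annulus$phi_max
}

#' Annular phase-memory statistic
#'
#' Compares a measured (speckle) phase image with a reference phase map
#' over an annular region: per pixel the relative phase
#' `dpsi = wrap(psi_measured - psi_reference)` is formed, and the weighted
#' mean resultant length
#' \deqn{R = \left| \sum w e^{i \Delta\psi} \right| / \sum w \in [0, 1]}
#' summarizes how much of the initial helical phase modulation survives:
#' R near 1 means the OAM phase structure is retained (phase memory),
#' R near 0 means it is fully scrambled.
#'
#' Pixels are weighted by their photon occupancy by default: the circular
#' standard error of a pixel's phase estimate scales as `1/sqrt(N_px)`, so
#' occupancy is the natural reliability weight. Weighting by the coherent
#' pixel intensity is available but is unstable whenever the detected
#' statistical weights are heavy-tailed (deep multiple scattering under a
#' unit Rayleigh factor spreads weights over tens of decades, so the
#' intensity-weighted sum collapses onto one or two pixels and the
#' statistic degenerates to the phase of a single photon).
#'
#' @param measured an `image_pair`.
#' @param reference_phase matrix of reference phases on the same grid
#'   (e.g. `Arg` of an analytic [field_map()]).
#' @param annulus an [annulus_spec()].
#' @param weighting `"occupancy"` (default), `"intensity"`, or `"equal"`.
#' @param min_pixels minimum occupied pixel count required (default 10).
#' @return list with `delta_psi` (wrapped relative-phase matrix, NA outside
#'   the annulus or in empty pixels), `R` (mean resultant length),
#'   `mean_phase` (circular mean of dpsi), `n_pixels`, `weighting`.
#' @export
phase_memory <- function(measured, reference_phase, annulus,
                         weighting = c("occupancy", "intensity", "equal"),
                         min_pixels = 10) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(measured, "image_pair"),
            inherits(annulus, "annulus_spec"))
  if (!all(dim(reference_phase) == dim(measured$phase))) {
    stop("reference phase and measured image must share one grid")
  }
  mask <- annulus_mask(measured$grid, annulus) & !is.na(measured$phase)
  if (sum(mask) < min_pixels) {
    stop(sprintf("annulus contains only %d occupied pixels (need >= %d)",
                 sum(mask), min_pixels))
  }
  dpsi <- matrix(NA_real_, nrow = nrow(measured$phase),
                 ncol = ncol(measured$phase))
  dpsi[mask] <- wrap_phase(measured$phase[mask] - reference_phase[mask])
  wts <- switch(weighting,
                occupancy = measured$occupancy[mask],
                intensity = measured$intensity[mask],
                equal = rep(1, sum(mask)))
  z <- sum(wts * exp(1i * dpsi[mask]))
  list(delta_psi = dpsi, R = Mod(z) / sum(wts), mean_phase = Arg(z),
       n_pixels = sum(mask), weighting = weighting)
}
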