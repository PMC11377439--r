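test_that("lg_field reproduces closed-form values and extrema", {
  w0 <- 0.8
  b0 <- beam_spec(0, 0, w0, 633e-6)
  b3 <- beam_spec(3, 0, w0, 633e-6)
  b5 <- beam_spec(5, 0, w0, 633e-6)

  # vortex null on axis
  expect_equal(Mod(lg_field(b5, 0, 0, 0)), 0)
  expect_equal(Mod(lg_field(b5, 0, 1.3, 2)), 0)
  # fundamental mode peak value sqrt(2/pi)/w0 with zero phase at the waist
  v <- lg_field(b0, 0, 0, 0)
  expect_equal(Mod(v), sqrt(2 / pi) / w0, tolerance = 1e-12)
  expect_equal(Arg(v), 0)
  # ring radius of a p = 0 vortex: rho = w0 sqrt(|l|/2)
  rho <- seq(0.01, 3, by = 1e-4)
  peak <- rho[which.max(Mod(lg_field(b3, rho, 0, 0)))]
  expect_equal(peak, w0 * sqrt(3 / 2), tolerance = 1e-3)
  # non-finite input rejected
  expect_error(lg_field(b3, NaN, 0, 0), "non-finite")
})

test_that("LG modes are normalized and mutually orthogonal", {
  modes <- expand.grid(l = 0:5, p = 0:2)
  for (z in c(0, pi * 0.8^2 / 633e-6, 3 * pi * 0.8^2 / 633e-6)) {
    for (i in sample(nrow(modes), 6)) {
      b <- beam_spec(modes$l[i], modes$p[i], 0.8, 633e-6)
      nrm <- stats::integrate(
        function(r) Mod(lg_field(b, r, 0, z))^2 * 2 * pi * r,
        0, Inf, rel.tol = 1e-9)$value
      expect_equal(nrm, 1, tolerance = 1e-6)
    }
  }
  # radial (same l, different p) and azimuthal orthogonality
  b30 <- beam_spec(3, 0, 0.8, 633e-6)
  b31 <- beam_spec(3, 1, 0.8, 633e-6)
  cross_rad <- stats::integrate(
    function(r) Re(Conj(lg_field(b30, r, 0, 0)) * lg_field(b31, r, 0, 0)) *
      2 * pi * r, 0, Inf, rel.tol = 1e-10)$value
  expect_lt(abs(cross_rad), 1e-6)
  # different l: azimuthal integral of exp(i(l2 - l1)phi) vanishes exactly
  phi <- seq(-pi, pi, length.out = 721)[-1]
  b20 <- beam_spec(2, 0, 0.8, 633e-6)
  az <- mean(Conj(lg_field(b30, 1, phi, 0)) * lg_field(b20, 1, phi, 0))
  expect_lt(Mod(az), 1e-12)
})

test_that("lg_phase follows the phase-evolution formula", {
  b3 <- hene_beam(3)
  # worked example: l = 3, z = 0, phi = -pi/10 -> +3pi/10
  expect_equal(lg_phase(b3, 0.9, -pi / 10, 0), 3 * pi / 10,
               tolerance = 1e-12)
  expect_equal(3 * pi / 10, 0.9425, tolerance = 1e-4)
  # all terms vanish at the origin of the waist plane
  expect_equal(lg_phase(hene_beam(-2), 1.1, 0, 0), 0)
  # Gouy phase at one Rayleigh range: (2p+|l|+1) * pi/4
  b1 <- beam_spec(1, 0, 0.8, 633e-6)
  expect_equal(gouy_phase(b1, b1$z_r), 2 * (pi / 4), tolerance = 1e-12)
  # Gouy limit z -> infinity (arctan approaches pi/2 as z_R/z)
  expect_equal(gouy_phase(b3, 1e9), (abs(3) + 1) * pi / 2, tolerance = 1e-5)
  # phase equals the field argument where the envelope is positive; at
  # moderate z the unwrapped -kz term stays small enough for full double
  # precision after wrapping
  set.seed(4)
  rho <- runif(200, 0.05, 2); phi <- runif(200, -pi, pi)
  z <- runif(200, 0, 10)
  dd <- wrap_phase(lg_phase(b3, rho, phi, z) -
                   Arg(lg_field(b3, rho, phi, z)))
  expect_lt(max(abs(dd)), 1e-9)
  # around the Rayleigh range the unwrapped phase is ~1e7 rad, so the
  # agreement is limited by float rounding of the wrap, not by the formula
  z2 <- runif(100, 0, 2 * b3$z_r)
  dd2 <- wrap_phase(lg_phase(b3, rho[1:100], phi[1:100], z2) -
                    Arg(lg_field(b3, rho[1:100], phi[1:100], z2)))
  expect_lt(max(abs(dd2)), 1e-6)
})

test_that("launch directions follow the Poynting skew and are unit length", {
  b0 <- hene_beam(0)
  b1 <- hene_beam(1)
  # plane-wave limit: l = 0 at the waist
  expect_equal(as.numeric(launch_direction(b0, 0.4, -0.2, 0)), c(0, 0, 1))
  # l = 1 at (r, 0, 0): direction proportional to (0, 1/r, k)
  r <- 0.7
  s <- as.numeric(launch_direction(b1, r, 0, 0))
  expect_equal(s[1], 0)
  expect_equal(atan2(sqrt(s[1]^2 + s[2]^2), s[3]), atan(1 / (b1$k * r)),
               tolerance = 1e-12)
  # mirror symmetry under l -> -l
  bm <- hene_beam(-1)
  sm <- as.numeric(launch_direction(bm, r, 0, 0))
  expect_equal(sm[2], -s[2])
  # invariant under the angular-frequency scale factor
  b_om <- beam_spec(1, 0, 0.8, 633e-6, omega = 7.3e11)
  expect_equal(launch_direction(b_om, 0.3, 0.2, 0.5),
               launch_direction(b1, 0.3, 0.2, 0.5))
  # unit norm everywhere
  set.seed(2)
  sv <- launch_direction(b1, runif(50, -2, 2), runif(50, 0.1, 2),
                         runif(50, 0, 5))
  expect_lt(max(abs(sqrt(rowSums(sv^2)) - 1)), 1e-12)
  # on-axis singularity
  expect_error(launch_direction(b1, 0, 0, 1), "singular")
})

test_that("sample_source draws positions from the mode intensity", {
  b5 <- hene_beam(5)
  src <- sample_source(b5, 1e5, seed = 99)
  # direction unit norm and polarization triad orthogonality
  expect_lt(max(abs(sqrt(src$sx^2 + src$sy^2 + src$sz^2) - 1)), 1e-12)
  expect_lt(max(abs(src$sx * src$pxx + src$sy * src$pxy + src$sz * src$pxz)),
            1e-9)
  expect_lt(max(abs(src$sx * src$pyx + src$sy * src$pyy + src$sz * src$pyz)),
            1e-9)
  # initial phase equals the mode phase at the sampled point, exactly
  rho <- sqrt(src$x^2 + src$y^2)
  expect_equal(src$psi0, lg_phase(b5, rho, atan2(src$y, src$x), 0))
  # radial histogram against the analytic density (chi-squared)
  edges <- seq(0, 3, length.out = 31)
  obs <- table(cut(rho, edges))
  pexp <- vapply(seq_len(30), function(i) {
    stats::integrate(function(r) Mod(lg_field(b5, r, 0, 0))^2 * 2 * pi * r,
                     edges[i], edges[i + 1])$value
  }, numeric(1))
  keep <- pexp * nrow(src) > 5
  chi <- sum((obs[keep] - nrow(src) * pexp[keep])^2 /
             (nrow(src) * pexp[keep]))
  pval <- stats::pchisq(chi, df = sum(keep) - 1, lower.tail = FALSE)
  expect_gt(pval, 0.01)
})

test_that("l = 0 source azimuths are uniform (Rayleigh test)", {
  src <- sample_source(hene_beam(0), 2e4, seed = 5)
  phi <- atan2(src$y, src$x)
  rbar <- Mod(mean(exp(1i * phi)))
  # Rayleigh statistic 2nR^2 ~ chi2(2) under uniformity
  pval <- exp(-nrow(src) * rbar^2)
  expect_gt(pval, 0.01)
})

test_that("fork holograms carry an l-pronged dislocation", {
  grid <- pixel_grid(128, 128, 0.02)
  # l = 0: pure blazed grating with the configured period
  h0 <- fork_hologram(0, period = 0.1, grid)
  x <- pixel_centers(grid)$x
  expect_equal(h0[10, ], wrap_phase(2 * pi * x / 0.1))
  # phase winding of the dislocation term around the origin equals l
  h5 <- fork_hologram(5, period = 0.1, grid)
  xm <- matrix(x, 128, 128, byrow = TRUE)
  disl <- wrap_phase(h5 - 2 * pi * xm / 0.1)
  th <- seq(-pi, pi, length.out = 256)
  ring <- cbind(0.8 * cos(th), 0.8 * sin(th))
  ix <- round((ring[, 1] - grid$origin[1]) / grid$pitch) + 1
  iy <- round((ring[, 2] - grid$origin[2]) / grid$pitch) + 1
  vals <- disl[cbind(iy, ix)]
  winding <- sum(wrap_phase(diff(vals))) / (2 * pi)
  expect_equal(round(winding), 5)
  # fringe endings: the fork terminates |l| fringes at the origin, so a
  # horizontal cut just below the dislocation carries 5 more full fringes
  # (2 pi of accumulated phase each) than one just above it
  # (rows at |y| = 0.08 mm: close enough to the fork that the azimuthal
  # span is ~pi per side, far enough that the phase is sampled below the
  # Nyquist limit of the 20 um grid)
  fringe_span <- function(h, row) sum(wrap_phase(diff(h[row, ])))
  ys <- pixel_centers(grid)$y
  below <- which.min(abs(ys + 0.08)); above <- which.min(abs(ys - 0.08))
  extra <- (fringe_span(h5, below) - fringe_span(h5, above)) / (2 * pi)
  expect_equal(round(extra), 5)
  # conjugate symmetry modulo the linear term
  hm5 <- fork_hologram(-5, period = 0.1, grid)
  dm <- wrap_phase(hm5 - 2 * pi * xm / 0.1)
  expect_lt(max(abs(wrap_phase(dm + disl))), 1e-9)
})
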