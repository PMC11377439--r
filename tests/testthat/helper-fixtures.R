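# shared test fixtures: the experimental beam and desk-scale detector
hene_beam <- function(l = 3, p = 0) beam_spec(l, p, w0 = 0.8,
                                              wavelength = 633e-6)

# index-matched non-scattering slab for ballistic oracles
vacuum_slab <- function(d = 1) {
  medium_optics(mus = 1e-12, mua = 0, g = 0.8, n = 1, d = d, n_ambient = 1)
}

detector_grid <- function() pixel_grid(128, 128, pitch = 0.2)

# pixel-averaged analytic mode intensity (counts expected per pixel for
# n_total photons), via sub-pixel quadrature
analytic_pixel_counts <- function(beam, grid, z, n_total, sub = 4) {
  gs <- pixel_grid(grid$nx * sub, grid$ny * sub, grid$pitch / sub)
  fa <- field_map(beam, gs, z = z)
  ia <- Mod(fa$field)^2
  av <- matrix(0, grid$ny, grid$nx)
  for (i in seq_len(sub)) {
    for (j in seq_len(sub)) {
      av <- av + ia[seq(i, grid$ny * sub, sub), seq(j, grid$nx * sub, sub)]
    }
  }
  av / sub^2 * grid$pitch^2 * n_total
}

# closed-form Henyey-Greenstein CDF in cos(theta') for KS tests
hg_cdf <- function(ct, g) {
  if (g == 0) return((ct + 1) / 2)
  (1 - g^2) / (2 * g) *
    (1 / sqrt(1 + g^2 - 2 * g * ct) - 1 / (1 + g))
}
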