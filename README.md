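# vortexmc

Coherent, polarization-tracking Monte Carlo simulation of
Laguerre–Gaussian (LG) vortex beams propagating through turbid,
tissue-like slabs, written for researchers in biophotonics and structured
light who need a quantitative handle on **orbital angular momentum (OAM)
phase memory**: how much of a beam's helical phase structure
`exp(-i l phi)` survives multiple scattering, and how to read the
topological charge `l` back out of the scattered speckle.

## What it computes

The source is the paraxial LG mode

    LG_p^l(rho, phi, z) ∝ (√2 rho / w(z))^|l| L_p^|l|(2 rho²/w²)
                          exp(-rho²/w²) e^{iG(z)}
                          e^{-ik rho² z / 2(z²+z_R²)} e^{-il phi} e^{-ikz}

sampled photon-by-photon: positions from `|LG|²`, initial phase from the
mode's phase evolution `Ψ = -k rho² z/2(z²+z_R²) - l phi - kz + G(z)`, and
launch directions from the Poynting vector (the OAM skew). Transport
through a slab (`mu_s`, `mu_a`, `g`, `n`, thickness `d`) uses exponential
free paths, Beer–Lambert weights, closed-form inverse-CDF
Henyey–Greenstein scattering, Snell/Fresnel boundaries, per-event
transverse projection of a polarization pair (`P_i = [I - s⊗s] P_{i-1}`),
and coherent optical-path phase. Detected photons are summed coherently
per detector pixel,

    I_px = |Σ_j √W_j e^{iΨ_j}|²,   ψ = arg Σ_j √W_j e^{iΨ_j},

yielding paired intensity/phase speckle images, from which the package
builds interferograms against a reference Gaussian, a log-polar OAM
**mode sorter** that focuses each charge to a distinct lateral position
(spacing `λf/2πa`), and an annular **phase-memory statistic**
`R = |Σ w e^{iΔψ}| / Σ w ∈ [0, 1]` comparing the speckle phase with the
free-space helical phase.

The transport core is compiled (Rcpp), single-threaded, and
bit-reproducible from a seed.

## Worked example

An `LG_0^3` beam (633 nm, 0.8 mm waist) through a 1 mm slab with
`mu_s = 4 /mm`, `mu_a = 0.01 /mm`, `g = 0.8`:

```r
library(vortexmc)

beam <- beam_spec(l = 3, p = 0, w0 = 0.8, wavelength = 633e-6)
slab <- medium_optics(mus = 4, mua = 0.01, g = 0.8, n = 1.4, d = 1)
cfg  <- run_config(n_photons = 1e6, n_detect = 1e5, seed = 42)

res <- simulate_run(beam, slab, cfg)
print(res)
#> transport run: 622096 launched, 100000 detected
#>   weight ledger: launched 6.221e+05 = detected 5.203e+04 + absorbed 2.22e+04
#>     + reflected(entry) 1.728e+04 + exited(undetected) 5.306e+05 + terminated 19.18

grid <- pixel_grid(128, 128, pitch = 0.05)
img  <- accumulate_image(res$records, grid)

# read the topological charge out of the scattered speckle
geom <- sorter_geometry(grid, beam$wavelength, waist = beam$w0)
ref  <- sorter_reference(geom, beam$w0)
srt  <- sort_oam(mc_field(img), geom, reference = ref)
srt$l_hat
#> [1] 3

# how much helical phase survived, over the vortex ring
refm <- field_map(beam, grid, z = slab$d)
pm   <- phase_memory(img, wrap_phase(Arg(refm$field)),
                     default_annulus(beam, slab$d))
round(pm$R, 3)
#> [1] 0.789
```

Reading: of 622k launched photons, 100k reached the detector (the ledger
accounts for every unit of launched weight); the sorter recovers the
charge `l = 3` from the speckle field, and the annular mean resultant
`R = 0.79` says the helical phase is still largely intact behind this
moderately scattering slab (`d/l* = 0.8`). Deeper slabs drive `R` toward
its noise floor — the package's phantom pair (`d/l* = 2` vs `9.6`) is
generated by `make_fixtures()`.

A command-line front end for scripted use lives at
`inst/scripts/vortexmc` (subcommands `simulate`, `freespace`, `sort`,
`interfere`, `analyze-phase-memory`, `make-fixtures`).

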