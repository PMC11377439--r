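#' Assemble a named simulation scenario
#'
#' A scenario bundles everything one run needs: beam, medium, detector and
#' photon budget, plus a mandatory seed. Scenarios serialize to YAML (see
#' [write_scenario()]) with wavelengths in nm converted once at parse time;
#' internally everything is millimetres and radians.
#'
#' @param name scenario name.
#' @param beam a [beam_spec()].
#' @param medium a [medium_optics()].
#' @param config a [run_config()].
#' @param grid a [pixel_grid()] for the detector image.
#' @param flags character vector marking parameters that are package
#'   defaults rather than published values.
#' @return object of class `scenario`.
#' @export
scenario <- function(name, beam, medium, config, grid, flags = character()) {
  stopifnot(inherits(beam, "beam_spec"), inherits(medium, "medium_optics"),
            inherits(config, "run_config"), inherits(grid, "pixel_grid"))
  structure(list(name = name, beam = beam, medium = medium, config = config,
                 grid = grid, flags = flags),
            class = "scenario")
}

#' Serialize a scenario to YAML
#'
#' @param sc a [scenario()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(sc, path) {
  stopifnot(inherits(sc, "scenario"))
  lst <- list(
    name = sc$name,
    beam = list(l = sc$beam$l, p = sc$beam$p, w0_mm = sc$beam$w0,
                wavelength_nm = sc$beam$wavelength * 1e6),
    medium = list(mus_per_mm = sc$medium$mus, mua_per_mm = sc$medium$mua,
                  g = sc$medium$g, n = sc$medium$n,
                  thickness_mm = sc$medium$d,
                  n_ambient = sc$medium$n_ambient,
                  gamma_r = sc$medium$gamma_r),
    detector = list(nx = sc$grid$nx, ny = sc$grid$ny,
                    pitch_mm = sc$grid$pitch, r_d_mm = sc$config$r_d,
                    na_rad = sc$config$na, theta_d_rad = sc$config$theta_d,
                    geometry = sc$config$geometry),
    run = list(n_photons = sc$config$n_photons,
               n_detect = sc$config$n_detect,
               weight_floor = sc$config$weight_floor,
               event_cap = sc$config$event_cap,
               seed = sc$config$seed),
    flags = as.list(sc$flags))
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' Read a scenario from YAML
#'
#' Validates on read: a missing seed, negative scattering coefficient,
#' out-of-range anisotropy or acceptance angle all raise errors rather than
#' silently running.
#'
#' @param path YAML file written by [write_scenario()] (or hand-written in
#'   the same layout).
#' @return a [scenario()].
#' @export
read_scenario <- function(path) {
  lst <- yaml::read_yaml(path)
  for (sect in c("name", "beam", "medium", "detector", "run")) {
    if (is.null(lst[[sect]])) stop("scenario is missing section '", sect, "'")
  }
  if (is.null(lst$run$seed)) {
    stop("scenario has no seed: refusing to run irreproducibly")
  }
  b <- lst$beam
  beam <- beam_spec(l = b$l, p = b$p, w0 = b$w0_mm,
                    wavelength = b$wavelength_nm * 1e-6)
  m <- lst$medium
  medium <- medium_optics(mus = m$mus_per_mm, mua = m$mua_per_mm, g = m$g,
                          n = m$n, d = m$thickness_mm,
                          n_ambient = if (is.null(m$n_ambient)) 1 else m$n_ambient,
                          gamma_r = if (is.null(m$gamma_r)) 1 else m$gamma_r)
  dt <- lst$detector
  grid <- pixel_grid(dt$nx, dt$ny, dt$pitch_mm)
  r <- lst$run
  config <- run_config(n_photons = r$n_photons, n_detect = r$n_detect,
                       seed = r$seed, weight_floor = r$weight_floor,
                       event_cap = r$event_cap, r_d = dt$r_d_mm,
                       na = dt$na_rad, theta_d = dt$theta_d_rad,
                       geometry = dt$geometry)
  scenario(lst$name, beam, medium, config, grid,
           flags = unlist(lst$flags))
}

# shared fixture constants: the experimental beam (633 nm HeNe-class diode,
# 1.6 mm waist diameter) and the desk-scale detector
fixture_beam <- function(l) beam_spec(l = l, p = 0, w0 = 0.8,
                                      wavelength = 633e-6)
fixture_grid <- function() pixel_grid(128, 128, pitch = 0.2)
fixture_config <- function(seed, n_photons = 1e6, n_detect = 1e5) {
  run_config(n_photons = n_photons, n_detect = n_detect, seed = seed,
             r_d = 12.8, na = asin(0.25), geometry = "transmission")
}

#' Generate the fixture scenario files
#'
#' Writes the YAML scenarios reproducing the study's parameter grid at desk
#' scale: an LG_0^5 beam imaged at optical depths 0 / 2.5 / 5, an LG_0^3
#' beam behind 1 mm slabs with scattering coefficients 2, 4, 6, 10 /mm
#' (mua = 0.01 /mm, g = 0.8), the low- and multiple-scattering phantom pair
#' (d/l* = 2: d = 1 mm, mus = 10 /mm; d/l* = 9.6: d = 8 mm, mus = 6 /mm),
#' and the simulation-vs-experiment slab (mus = 4 /mm, mua = 0.05 /mm).
#' All share the 633 nm, 0.8 mm-waist beam. Photon budgets are desk-scale
#' and every scenario has a fixed seed.
#'
#' @param out_dir writable output directory (created if absent).
#' @return character vector of written file paths, invisibly.
#' @export
make_fixtures <- function(out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory ", out_dir)
  }
  if (file.access(out_dir, 2) != 0) stop("directory not writable: ", out_dir)
  grid <- fixture_grid()
  paths <- character()
  add <- function(sc) {
    p <- file.path(out_dir, paste0(sc$name, ".yaml"))
    write_scenario(sc, p)
    paths <<- c(paths, p)
  }
  # beam-spreading series: optical depths 0, 2.5, 5 (d = 1 mm, g = 0.8,
  # mus derived from the target depth; depth 0 is free space)
  depths <- c(0, 2.5, 5)
  for (i in seq_along(depths)) {
    dl <- depths[i]
    mus <- dl / (1 * (1 - 0.8))
    med <- medium_optics(mus = max(mus, 1e-9), mua = if (dl == 0) 0 else 0.01,
                         g = 0.8, n = 1.4, d = 1)
    add(scenario(sprintf("spread-lg05-depth%g", dl), fixture_beam(5), med,
                 fixture_config(seed = 101 + i), grid,
                 flags = c("mus derived from d/l* with g = 0.8, d = 1 mm",
                           "mua default 0.01 /mm", "n default 1.4")))
  }
  # scattering-coefficient series
  for (mus in c(2, 4, 6, 10)) {
    med <- medium_optics(mus = mus, mua = 0.01, g = 0.8, n = 1.4, d = 1)
    add(scenario(sprintf("musgrid-lg03-mus%g", mus), fixture_beam(3), med,
                 fixture_config(seed = 200 + mus), grid,
                 flags = "n default 1.4"))
  }
  # phantom pair: low vs multiple scattering
  add(scenario("phantom-lg03-low", fixture_beam(3),
               medium_optics(mus = 10, mua = 0.01, g = 0.8, n = 1.4, d = 1),
               fixture_config(seed = 301), grid,
               flags = c("mua default 0.01 /mm", "n default 1.4")))
  add(scenario("phantom-lg03-multi", fixture_beam(3),
               medium_optics(mus = 6, mua = 0.01, g = 0.8, n = 1.4, d = 8),
               fixture_config(seed = 302), grid,
               flags = c("mua default 0.01 /mm", "n default 1.4")))
  # simulation-vs-experiment slab
  add(scenario("validation-lg03", fixture_beam(3),
               medium_optics(mus = 4, mua = 0.05, g = 0.8, n = 1.4, d = 1),
               fixture_config(seed = 401), grid,
               flags = "n default 1.4"))
  invisible(paths)
}

#' Write a real-valued image as 32-bit float TIFF with a metadata sidecar
#'
#' Writes a two-channel 32-bit float TIFF: channel 1 holds the image values
#' affinely mapped to \[0, 1\] (the mapping `value = offset + scale * stored`
#' is recorded in the sidecar), channel 2 is a validity mask (0 marks `NA`
#' pixels, e.g. phase in pixels that collected no photons). The sidecar
#' `<path>.meta.txt` records the grid pitch, origin, the affine mapping and
#' any extra metadata.
#'
#' @param img numeric matrix (ny x nx, row 1 = lowest y).
#' @param path output TIFF path.
#' @param grid the [pixel_grid()] of the image.
#' @param meta named list of extra key-value metadata lines.
#' @return `path`, invisibly.
#' @export
write_field_tiff <- function(img, path, grid, meta = list()) {
  stopifnot(inherits(grid, "pixel_grid"))
  valid <- is.finite(img)
  rng <- if (any(valid)) range(img[valid]) else c(0, 1)
  scale <- if (diff(rng) > 0) diff(rng) else 1
  stored <- (img - rng[1]) / scale
  stored[!valid] <- 0
  arr <- array(0, dim = c(nrow(img), ncol(img), 2))
  # TIFF rows run top-down; our rows run bottom-up
  flip <- rev(seq_len(nrow(img)))
  arr[, , 1] <- stored[flip, , drop = FALSE]
  arr[, , 2] <- (valid * 1)[flip, , drop = FALSE]
  tiff::writeTIFF(arr, path, bits.per.sample = 32, reduce = FALSE)
  lines <- c(sprintf("nx: %d", grid$nx), sprintf("ny: %d", grid$ny),
             sprintf("pitch_mm_per_px: %.9g", grid$pitch),
             sprintf("origin_mm: %.9g %.9g", grid$origin[1], grid$origin[2]),
             sprintf("value_offset: %.9g", rng[1]),
             sprintf("value_scale: %.9g", scale),
             vapply(names(meta),
                    function(k) sprintf("%s: %s", k, format(meta[[k]])),
                    character(1)))
  writeLines(lines, paste0(path, ".meta.txt"))
  invisible(path)
}

#' Read a float TIFF written by [write_field_tiff()]
#'
#' Undoes the affine \[0, 1\] mapping using the sidecar and restores `NA`
#' pixels from the validity channel.
#'
#' @param path TIFF path (the sidecar `<path>.meta.txt` must sit beside it).
#' @return numeric matrix, rows bottom-up (matching package convention).
#' @export
read_field_tiff <- function(path) {
  # libtiff flags the validity channel as a non-color ExtraSample; harmless
  arr <- suppressWarnings(tiff::readTIFF(path))
  side <- readLines(paste0(path, ".meta.txt"))
  getval <- function(key) {
    ln <- grep(paste0("^", key, ":"), side, value = TRUE)[1]
    as.numeric(sub(".*: *", "", ln))
  }
  off <- getval("value_offset")
  scl <- getval("value_scale")
  m <- off + scl * arr[, , 1]
  m[arr[, , 2] < 0.5] <- NA_real_
  m[rev(seq_len(nrow(m))), , drop = FALSE]
}

#' Run the full pipeline for a scenario
#'
#' Source sampling, transport, coherent image formation, and optionally the
#' OAM sorter, interferogram and phase-memory analysis; writes float TIFFs
#' (intensity, phase, occupancy), a CSV run summary, and a YAML manifest
#' (scenario, seed, package version) into `out_dir`. Re-running the same
#' scenario reproduces the outputs bit-identically.
#'
#' @param sc a [scenario()].
#' @param out_dir output directory (created if absent).
#' @param sorter run the OAM sorter on the MC image (default FALSE).
#' @param interfere synthesize an on-axis interferogram (default FALSE).
#' @param memory run the annular phase-memory analysis against the analytic
#'   free-space phase (default FALSE).
#' @param dump_photons write the detected-photon table (one row per
#'   detection: exit position, direction, phase, weights, event count) as
#'   CSV (default FALSE).
#' @return list with `result` (transport_result), `image` (image_pair),
#'   and any analysis outputs, invisibly.
#' @export
run_pipeline <- function(sc, out_dir, sorter = FALSE, interfere = FALSE,
                         memory = FALSE, dump_photons = FALSE) {
  stopifnot(inherits(sc, "scenario"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stage <- function(tag, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", tag, conditionMessage(e)), call. = FALSE)
    })
  }
  free_space <- sc$medium$mus <= 1e-8
  if (free_space) {
    fm <- stage("freespace", field_map(sc$beam, sc$grid, z = sc$medium$d))
    img <- structure(list(intensity = Mod(fm$field)^2,
                          phase = wrap_phase(Arg(fm$field)),
                          weight = Mod(fm$field)^2,
                          occupancy = array(1, dim(fm$field)),
                          n_excluded = 0L, grid = sc$grid),
                     class = "image_pair")
    res <- NULL
  } else {
    res <- stage("transport", simulate_run(sc$beam, sc$medium, sc$config))
    img <- stage("detector", accumulate_image(res$records, sc$grid))
  }
  base <- file.path(out_dir, sc$name)
  meta <- list(scenario = sc$name, seed = sc$config$seed,
               l = sc$beam$l, p = sc$beam$p, w0_mm = sc$beam$w0,
               wavelength_nm = sc$beam$wavelength * 1e6)
  stage("io", {
    write_field_tiff(img$intensity, paste0(base, "-intensity.tif"),
                     sc$grid, meta)
    write_field_tiff(img$phase, paste0(base, "-phase.tif"), sc$grid, meta)
    write_field_tiff(img$occupancy, paste0(base, "-occupancy.tif"),
                     sc$grid, meta)
  })
  out <- list(result = res, image = img)

  if (dump_photons && !is.null(res)) {
    stage("io", utils::write.csv(res$records, paste0(base, "-photons.csv"),
                                 row.names = FALSE))
  }
  if (sorter) {
    out$sorter <- stage("sorter", {
      geom <- sorter_geometry(sc$grid, sc$beam$wavelength,
                              waist = sc$beam$w0)
      ref <- sorter_reference(geom, sc$beam$w0)
      srt <- sort_oam(mc_field(img), geom, reference = ref)
      utils::write.csv(srt$profile, paste0(base, "-sorter-profile.csv"),
                       row.names = FALSE)
      srt
    })
  }
  if (interfere) {
    out$interferogram <- stage("interfere", {
      ig <- interferogram(img, sc$beam$wavelength,
                          amplitude = sqrt(max(img$intensity)))
      write_field_tiff(ig, paste0(base, "-interferogram.tif"), sc$grid, meta)
      ig
    })
  }
  if (memory) {
    out$memory <- stage("phase-memory", {
      ref <- field_map(sc$beam, sc$grid, z = sc$medium$d)
      ann <- default_annulus(sc$beam, sc$medium$d)
      phase_memory(img, wrap_phase(Arg(ref$field)), ann)
    })
  }

  summary_df <- data.frame(
    scenario = sc$name,
    n_launched = if (is.null(res)) NA else res$n_launched,
    n_detected = if (is.null(res)) NA else nrow(res$records),
    mean_path_mm = if (is.null(res)) NA else mean(res$records$path),
    optical_depth = optical_depth(sc$medium),
    R_phase_memory = if (memory) out$memory$R else NA)
  utils::write.csv(summary_df, paste0(base, "-summary.csv"),
                   row.names = FALSE)
  manifest <- list(scenario = sc$name, seed = sc$config$seed,
                   package_version = as.character(utils::packageVersion("vortexmc")),
                   optical_depth = optical_depth(sc$medium),
                   n_detected = summary_df$n_detected)
  yaml::write_yaml(manifest, paste0(base, "-manifest.yaml"))
  invisible(out)
}

#' Default annular analysis region for a vortex beam
#'
#' The annulus bracketing the bright ring of an LG_0^l beam at plane z:
#' radii `[0.7, 1.3] * w(z) * sqrt(|l| / 2)` (the peak-intensity radius of
#' a p = 0 mode is `w(z) sqrt(|l|/2)`).
#'
#' @param beam a [beam_spec()] with `l != 0`.
#' @param z plane of analysis, mm.
#' @return an [annulus_spec()].
#' @export
default_annulus <- function(beam, z) {
  if (beam$l == 0) stop("annulus default is defined for vortex modes only")
  r0 <- beam_radius(beam, z) * sqrt(abs(beam$l) / 2)
  annulus_spec(0.7 * r0, 1.3 * r0)
}
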