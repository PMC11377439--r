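#' Transverse polarization projection (Bethe-Salpeter step)
#'
#' At every scattering event the tracked polarization vectors are projected
#' onto the plane transverse to the new propagation direction,
#' `P_i = -s_i x (s_i x P_(i-1)) = (I - s_i (x) s_i) P_(i-1)`,
#' i.e. the component along the direction is removed. The norm of `P`
#' shrinks accordingly; the cumulative shrinkage is the depolarization
#' factor entering the detected weights.
#'
#' @param p real 3-vector or n x 3 matrix of polarization vectors.
#' @param s unit 3-vector or n x 3 matrix of directions.
#' @return projected vector(s), same shape as `p`.
#' @export
project_polarization <- function(p, s) {
  pv <- if (is.matrix(p)) p else matrix(p, ncol = 3)
  sv <- if (is.matrix(s)) s else matrix(s, ncol = 3, nrow = nrow(pv),
                                        byrow = TRUE)
  nrm <- sqrt(rowSums(sv^2))
  if (any(abs(nrm - 1) > 1e-9)) stop("'s' must be unit length")
  dp <- rowSums(pv * sv)
  out <- pv - dp * sv
  if (is.matrix(p)) out else as.numeric(out)
}

#' Transport run configuration
#'
#' Photon budget, termination rules and detection geometry for a Monte
#' Carlo transport run. The detector is a square window of half-width `r_d`
#' on one slab face; an exiting photon is detected when its refracted exit
#' direction lies within the acceptance cone
#' `acos(s_N . s_d) < na`, where `s_d` is the detector axis (tilted by
#' `theta_d` in the x-z plane) and `na` is the acceptance half-angle in
#' radians, used directly as printed rather than as `n sin(theta)`.
#'
#' @param n_photons total photon launch budget (N_inc).
#' @param n_detect detector quota (N_ph <= N_inc): the run stops once this
#'   many photons have been detected.
#' @param seed integer seed; mandatory, every run is reproducible.
#' @param weight_floor photon terminated when its weight drops below this
#'   (default 1e-4, a hard floor; no Russian roulette).
#' @param event_cap maximum number of scattering events per photon
#'   (default 1000).
#' @param r_d detector half-width, mm.
#' @param na acceptance half-angle, radians, in (0, pi/2].
#' @param theta_d detector axis tilt, radians.
#' @param geometry `"transmission"` (detector on the z = d face, default)
#'   or `"reflection"` (z = 0 face).
#' @param source_tilt source tilt angle about the y axis, radians.
#' @param fresnel_exit apply Fresnel refraction/weighting at the exit face
#'   before detection (default TRUE; off switch for sensitivity checks).
#' @return object of class `run_config`.
#' @export
run_config <- function(n_photons = 1e6, n_detect = 1e5, seed,
                       weight_floor = 1e-4, event_cap = 1000L,
                       r_d = 12.8, na = asin(0.25), theta_d = 0,
                       geometry = c("transmission", "reflection"),
                       source_tilt = 0, fresnel_exit = TRUE) {
  geometry <- match.arg(geometry)
  if (missing(seed) || is.null(seed) || !is.finite(seed)) {
    stop("'seed' is mandatory: every transport run must be reproducible")
  }
  if (n_photons < n_detect || n_detect < 1) {
    stop("need n_photons >= n_detect >= 1")
  }
  if (weight_floor <= 0 || weight_floor >= 1) {
    stop("'weight_floor' must lie in (0, 1)")
  }
  if (na <= 0 || na > pi / 2) stop("'na' must lie in (0, pi/2]")
  if (r_d <= 0) stop("'r_d' must be positive")
  structure(
    list(n_photons = n_photons, n_detect = n_detect, seed = as.integer(seed),
         weight_floor = weight_floor, event_cap = as.integer(event_cap),
         r_d = r_d, na = na, theta_d = theta_d, geometry = geometry,
         source_tilt = source_tilt, fresnel_exit = isTRUE(fresnel_exit)),
    class = "run_config")
}

#' One interior propagation step of a photon packet (reference path)
#'
#' Advances a single photon by one free path inside the slab: samples the
#' path length, moves the packet, attenuates the weight by Beer-Lambert,
#' accumulates the optical-path phase `-k * n * l` (the mode uses the
#' `exp(-ikz)` sign convention, so phase decreases along the optical path), scatters into a new
#' direction drawn from the Henyey-Greenstein kernel, projects both
#' polarization vectors transverse to the new direction and applies the
#' per-event factor `gamma_r`. If the sampled segment would cross a slab
#' face the packet is truncated at the face and returned with
#' `at_boundary = TRUE` (the caller then invokes [boundary_interact()]).
#'
#' This is the plain-R reference implementation of the compiled transport
#' kernel used by [run_transport()]; it consumes the same RNG stream layout
#' (xi_path, xi_cos, xi_azimuth per event) and exists chiefly for unit
#' testing and instrumented traces.
#'
#' @param packet list with `pos` (3-vector), `dir` (unit 3-vector),
#'   `weight`, `phase`, `px`, `py`, `events`, `path`.
#' @param medium a [medium_optics()].
#' @param beam_k vacuum wavenumber (1/mm) for phase accumulation.
#' @return updated packet, with `at_boundary` and `boundary_face`
#'   (0 or d) set when the step hit a face.
#' @export
step_photon <- function(packet, medium, beam_k) {
  stopifnot(inherits(medium, "medium_optics"))
  if (packet$weight <= 0) stop("dead packet")
  l <- if (medium$mus > 0) {
    sample_free_path(medium$mus, max(1 - runif(1), 1e-15))
  } else {
    Inf
  }
  sz <- packet$dir[3]
  t_face <- if (sz > 0) {
    (medium$d - packet$pos[3]) / sz
  } else if (sz < 0) {
    -packet$pos[3] / sz
  } else {
    Inf
  }
  if (t_face <= l) {                       # truncate at the face
    move <- t_face
    packet$pos <- packet$pos + packet$dir * move
    packet$weight <- packet$weight * exp(-medium$mua * move)
    packet$phase <- packet$phase - beam_k * medium$n * move
    packet$path <- packet$path + move
    packet$at_boundary <- TRUE
    packet$boundary_face <- if (sz > 0) medium$d else 0
    return(packet)
  }
  packet$pos <- packet$pos + packet$dir * l
  packet$weight <- packet$weight * exp(-medium$mua * l)
  packet$phase <- packet$phase - beam_k * medium$n * l
  packet$path <- packet$path + l
  ang <- sample_scatter_angles(medium$g, max(1 - runif(1), 1e-15), runif(1))
  packet$dir <- rotate_direction(packet$dir, ang$cos_theta, ang$azimuth)
  packet$px <- project_polarization(packet$px, packet$dir)
  packet$py <- project_polarization(packet$py, packet$dir)
  packet$weight <- packet$weight * medium$gamma_r
  packet$events <- packet$events + 1L
  packet$at_boundary <- FALSE
  packet
}

#' Rotate a direction by polar/azimuthal scattering angles
#'
#' Standard local-frame rotation used in photon-transport codes, with the
#' usual singularity guard when the direction is nearly along +-z.
#'
#' @param s unit 3-vector.
#' @param cos_theta cosine of the polar deflection.
#' @param azimuth azimuthal angle, radians.
#' @return new unit 3-vector.
#' @export
rotate_direction <- function(s, cos_theta, azimuth) {
  st <- sqrt(max(0, 1 - cos_theta^2))
  cp <- cos(azimuth); sp <- sin(azimuth)
  if (abs(s[3]) > 1 - 1e-12) {
    out <- c(st * cp, st * sp, sign(s[3]) * cos_theta)
  } else {
    den <- sqrt(1 - s[3]^2)
    out <- c(st * (s[1] * s[3] * cp - s[2] * sp) / den + s[1] * cos_theta,
             st * (s[2] * s[3] * cp + s[1] * sp) / den + s[2] * cos_theta,
             -st * cp * den + s[3] * cos_theta)
  }
  out / sqrt(sum(out^2))
}

#' Run Monte Carlo photon transport through the slab
#'
#' Launches the given source photons through the entry face (Snell
#' refraction and Fresnel weighting at z = 0), iterates the
#' move/attenuate/scatter loop until each photon terminates (weight below
#' the floor, event cap exceeded, or exit through a face), and collects
#' photons that exit through the detector face inside the detection window
#' and acceptance cone. Detected photons carry their accumulated phase
#' `Psi_N = psi_0 - k n sum(l_i)` and the weight triplet
#' `(W_N, W_par, W_perp)` built from the transverse components of the
#' polarization pair (normalized per photon so an unscattered,
#' index-matched photon retains its launch weight exactly);
#' `W_par + W_perp = W_N` holds identically.
#'
#' @param source data.frame from [sample_source()] (or same columns).
#' @param medium a [medium_optics()].
#' @param config a [run_config()]; `config$seed` seeds the run.
#' @param beam_k vacuum wavenumber, 1/mm (taken from `beam$k`).
#' @param set_seed if `FALSE`, the current RNG stream is used instead of
#'   seeding from the config (used by [simulate_run()] which seeds once).
#' @param warn_empty warn when nothing is detected (default TRUE;
#'   [simulate_run()] silences per-chunk warnings and warns once itself).
#' @return object of class `transport_result`: list with `records` (one row
#'   per detected photon: `x, y, sx, sy, sz, psi, w, w_par, w_perp,
#'   n_events, path`), `accounting` (named weight ledger), `n_launched`,
#'   and `no_detections` flag.
#' @export
run_transport <- function(source, medium, config, beam_k,
                          set_seed = TRUE, warn_empty = TRUE) {
  stopifnot(inherits(medium, "medium_optics"), inherits(config, "run_config"))
  need <- c("x", "y", "sx", "sy", "sz", "psi0", "w",
            "pxx", "pxy", "pxz", "pyx", "pyy", "pyz")
  if (!all(need %in% names(source))) stop("malformed source photon table")
  if (set_seed) set.seed(config$seed)
  src <- as.matrix(source[, need])
  if (config$source_tilt != 0) {
    ct <- cos(config$source_tilt); st <- sin(config$source_tilt)
    rot <- function(m) cbind(ct * m[, 1] + st * m[, 3], m[, 2],
                             -st * m[, 1] + ct * m[, 3])
    src[, c("sx", "sy", "sz")] <- rot(src[, c("sx", "sy", "sz")])
    src[, c("pxx", "pxy", "pxz")] <- rot(src[, c("pxx", "pxy", "pxz")])
    src[, c("pyx", "pyy", "pyz")] <- rot(src[, c("pyx", "pyy", "pyz")])
  }
  res <- cpp_transport(
    src,
    c(mus = medium$mus, mua = medium$mua, g = medium$g, n = medium$n,
      n_ambient = medium$n_ambient, d = medium$d, gamma_r = medium$gamma_r),
    c(weight_floor = config$weight_floor, event_cap = config$event_cap,
      r_d = config$r_d, na = config$na, theta_d = config$theta_d,
      transmission = as.numeric(config$geometry == "transmission"),
      n_detect = config$n_detect, fresnel_exit = as.numeric(config$fresnel_exit),
      k = beam_k))
  rec <- as.data.frame(res$records)
  names(rec) <- c("x", "y", "sx", "sy", "sz", "psi", "w", "w_par", "w_perp",
                  "n_events", "path")
  out <- structure(
    list(records = rec, accounting = res$accounting,
         n_launched = res$accounting[["photons_consumed"]],
         no_detections = nrow(rec) == 0,
         medium = medium, config = config),
    class = "transport_result")
  if (out$no_detections && warn_empty) {
    warning("no photons detected after exhausting the source set")
  }
  out
}

#' @export
print.transport_result <- function(x, ...) {
  cat(sprintf("transport run: %d launched, %d detected\n",
              x$n_launched, nrow(x$records)))
  acc <- x$accounting
  cat(sprintf("  weight ledger: launched %.4g = detected %.4g + absorbed %.4g + reflected(entry) %.4g + exited(undetected) %.4g + terminated %.4g\n",
              acc[["launched"]], acc[["detected"]], acc[["absorbed"]],
              acc[["entry_reflected"]],
              acc[["exited_undetected"]],
              acc[["terminated_floor"]] + acc[["terminated_cap"]]))
  invisible(x)
}

#' Simulate a full beam-through-slab run in photon chunks
#'
#' Seeds the RNG once from the config, then alternates source sampling and
#' compiled transport in fixed-size chunks until the detector quota is
#' reached or the launch budget `n_photons` is exhausted. Chunking keeps
#' memory bounded for large budgets while remaining bit-reproducible for a
#' given seed (the chunk size is part of the fixed algorithm).
#'
#' @param beam a [beam_spec()].
#' @param medium a [medium_optics()].
#' @param config a [run_config()].
#' @param z_launch launch plane, mm (default 0: waist at the entry face).
#' @param chunk_size photons sampled per chunk (default 1e6).
#' @return `transport_result` with merged records and summed accounting.
#' @export
simulate_run <- function(beam, medium, config, z_launch = 0,
                         chunk_size = 1e6) {
  stopifnot(inherits(beam, "beam_spec"))
  set.seed(config$seed)
  remaining <- config$n_photons
  quota <- config$n_detect
  recs <- list()
  acc <- NULL
  launched <- 0
  detected <- 0
  while (remaining > 0 && detected < quota) {
    m <- min(chunk_size, remaining)
    src <- sample_source(beam, m, z_launch = z_launch)
    cfg <- config
    cfg$n_detect <- quota - detected
    tr <- run_transport(src, medium, cfg, beam_k = beam$k, set_seed = FALSE,
                        warn_empty = FALSE)
    recs[[length(recs) + 1L]] <- tr$records
    acc <- if (is.null(acc)) tr$accounting else acc + tr$accounting
    launched <- launched + tr$n_launched
    detected <- detected + nrow(tr$records)
    remaining <- remaining - m
  }
  out <- structure(
    list(records = do.call(rbind, recs), accounting = acc,
         n_launched = launched, no_detections = detected == 0,
         medium = medium, config = config, beam = beam),
    class = "transport_result")
  if (out$no_detections) {
    warning("no photons detected after exhausting the launch budget")
  }
  out
}
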