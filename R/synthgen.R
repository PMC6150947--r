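#' Generate a folded, closed genus-0 "cortex" surface
#'
#' Builds a subdivided icosphere (the smallest with at least `n_vertices`
#' vertices: 12, 42, 162, 642, 2562, ...) and radially perturbs it with a
#' band-limited random spherical-harmonic field emulating mesh-scale cortical
#' folds. The fold field is a zero-mean Gaussian random field with harmonic
#' content over degrees 2..`fold_frequency` and per-degree RMS amplitude
#' proportional to 1/l (a red spectrum, so that every harmonic order of a
#' subsequent weighted Fourier series reconstruction carries shape
#' information), normalized to unit RMS over the vertices and scaled by
#' `fold_amplitude`.
#'
#' @param n_vertices minimum vertex count (>= 12); the realized count is the
#'   nearest icosphere size above it.
#' @param fold_amplitude RMS radial fold depth in mm (>= 0; 0 gives a sphere).
#' @param fold_frequency highest harmonic degree of the fold field.
#' @param radius base sphere radius in mm (> 0).
#' @param seed integer RNG seed; the mesh is deterministic given the seed.
#' @return a [cortical_mesh()] with attribute `sphere_coords` (the exact unit
#'   sphere parameterization it was generated from).
#' @export
gen_mesh <- function(n_vertices = 642, fold_amplitude = 5, fold_frequency = 12,
                     radius = 70, seed = 1) {
  if (radius <= 0) stop("radius must be positive")
  stopifnot(n_vertices >= 12, fold_amplitude >= 0, fold_frequency >= 2)
  s <- icosphere(n_vertices)
  u <- s$vertices
  r <- rep(radius, nrow(u))
  if (fold_amplitude > 0) {
    h <- withr::with_seed(seed, {
      L <- fold_frequency
      B <- real_sph_harm(u, L)
      l_of <- sph_degree_index(L)
      keep <- l_of >= 2
      coef <- rnorm(sum(keep)) / l_of[keep]
      drop(B[, keep, drop = FALSE] %*% coef)
    })
    h <- h / sqrt(mean(h^2))
    r <- radius + fold_amplitude * h
    if (any(r <= 0)) stop("fold_amplitude too large: surface self-intersects")
  }
  m <- cortical_mesh(u * r, s$faces)
  attr(m, "sphere_coords") <- u
  m
}

#' Generate a quasi-uniform sensor cap
#'
#' Places point magnetometers quasi-uniformly (Fibonacci lattice) on the
#' upper cap of a sphere of radius `cap_radius`, with radial pickup
#' orientations, outside a spherical conductor of radius `conductor_radius`
#' centred at the origin. A small seeded azimuthal rotation decorrelates
#' arrays generated with different seeds.
#'
#' @param n_channels number of sensors.
#' @param cap_radius sensor shell radius, mm (> conductor_radius).
#' @param conductor_radius conductor sphere radius, mm (> 0).
#' @param seed integer RNG seed.
#' @param cap_zmin lowest z/r of the cap (default -0.3, a helmet-like cap).
#' @return a `sensor_array`: list with `labels`, `positions` (C x 3, mm),
#'   `orientations` (C x 3 unit), `conductor_center`, `conductor_radius`.
#' @export
gen_sensor_array <- function(n_channels = 64, cap_radius = 110,
                             conductor_radius = 95, seed = 1, cap_zmin = -0.3) {
  if (!(cap_radius > conductor_radius && conductor_radius > 0))
    stop("need cap_radius > conductor_radius > 0")
  stopifnot(n_channels >= 1)
  i <- seq_len(n_channels)
  z <- cap_zmin + (1 - cap_zmin) * (i - 0.5) / n_channels
  golden <- pi * (3 - sqrt(5))
  rot <- withr::with_seed(seed, runif(1, 0, 2 * pi))
  phi <- golden * i + rot
  st <- sqrt(pmax(0, 1 - z^2))
  u <- unname(cbind(st * cos(phi), st * sin(phi), z))
  structure(list(
    labels = sprintf("MB%03d", i),
    positions = cap_radius * u,
    orientations = u,
    conductor_center = c(0, 0, 0),
    conductor_radius = conductor_radius
  ), class = "sensor_array")
}

#' @export
print.sensor_array <- function(x, ...) {
  cat(sprintf("sensor_array: %d radial magnetometers, shell %.0f mm, conductor %.0f mm\n",
              length(x$labels), sqrt(sum(x$positions[1, ]^2)), x$conductor_radius))
  invisible(x)
}

#' Simulation configuration for state-switching recordings
#'
#' @param n_states number of network states (>= 1).
#' @param state_dwell_ms mean state dwell time, ms (> 0).
#' @param sources_per_state active cortical sources per state.
#' @param source_amplitude dipole moment amplitude, nAm.
#' @param snr_db sensor-level SNR in dB (power convention, pooled over all
#'   channels and samples), or NULL for noiseless output.
#' @param duration_s recording length, s (> 0).
#' @param fs sampling rate, Hz (> 180 so the 1-90 Hz band is representable).
#' @param seed integer RNG seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_states = 2, state_dwell_ms = 200, sources_per_state = 3,
                       source_amplitude = 20, snr_db = 5, duration_s = 60,
                       fs = 600, seed = 1) {
  stopifnot(n_states >= 1, duration_s > 0, state_dwell_ms > 0,
            sources_per_state >= 1, fs > 180)
  structure(list(n_states = as.integer(n_states), state_dwell_ms = state_dwell_ms,
                 sources_per_state = as.integer(sources_per_state),
                 source_amplitude = source_amplitude, snr_db = snr_db,
                 duration_s = duration_s, fs = fs, seed = as.integer(seed)),
            class = "sim_config")
}

#' Construct a sensor recording object
#'
#' @param data C x T numeric matrix of field values (e.g. fT).
#' @param fs sampling rate, Hz.
#' @param labels channel names (length C).
#' @param state_truth optional per-sample ground-truth state index.
#' @return a `sensor_recording`.
#' @export
sensor_recording <- function(data, fs, labels, state_truth = NULL) {
  data <- as.matrix(data)
  stopifnot(fs > 0, length(labels) == nrow(data), all(is.finite(data)))
  if (!is.null(state_truth)) stopifnot(length(state_truth) == ncol(data))
  structure(list(data = data, fs = fs, labels = as.character(labels),
                 state_truth = state_truth),
            class = "sensor_recording")
}

#' @export
print.sensor_recording <- function(x, ...) {
  cat(sprintf("sensor_recording: %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  invisible(x)
}

# unit-variance 1-90 Hz band-limited Gaussian process (zero-phase Butterworth)
bandlimited_noise <- function(nt, fs, band = c(1, 90)) {
  hi <- min(band[2], 0.45 * fs)
  bf <- signal::butter(4, c(band[1], hi) / (fs / 2), type = "pass")
  x <- signal::filtfilt(bf, rnorm(nt))
  x / sd(x)
}

#' Simulate a state-switching MEG-like recording
#'
#' Draws a first-order Markov state sequence with geometric dwell times of
#' mean `cfg$state_dwell_ms`, assigns each state a fixed set of source
#' vertices carrying independent unit-variance 1-90 Hz band-limited Gaussian
#' time courses (scaled by `cfg$source_amplitude`, gated on while the state
#' is active), projects them through the gain matrix, and optionally adds
#' white sensor noise at `cfg$snr_db`.
#'
#' @param mesh the generating [cortical_mesh()].
#' @param sensors a `sensor_array` from [gen_sensor_array()].
#' @param cfg a [sim_config()].
#' @param gain the `gain_matrix` computed from `(mesh, sensors)`.
#' @return a [sensor_recording()] with `state_truth` filled in.
#' @export
simulate_recording <- function(mesh, sensors, cfg, gain) {
  if (ncol(gain$values) != nrow(mesh$vertices))
    stop("gain matrix and mesh vertex counts differ")
  nt <- round(cfg$duration_s * cfg$fs)
  K <- cfg$n_states
  dwell_samp <- cfg$state_dwell_ms * cfg$fs / 1000
  sim <- withr::with_seed(cfg$seed, {
    # Markov statepath: stay with prob 1 - 1/dwell, else jump uniformly
    states <- integer(nt)
    states[1] <- sample.int(K, 1)
    if (K > 1) {
      p_stay <- 1 - 1 / dwell_samp
      u <- runif(nt)
      jump <- runif(nt)
      for (t in 2:nt) {
        if (u[t] < p_stay) {
          states[t] <- states[t - 1]
        } else {
          others <- seq_len(K)[-states[t - 1]]
          states[t] <- others[ceiling(jump[t] * (K - 1))]
        }
      }
    } else states[] <- 1L
    verts <- matrix(sample.int(nrow(mesh$vertices), K * cfg$sources_per_state),
                    nrow = K)
    tc <- array(0, c(K, cfg$sources_per_state, nt))
    for (k in seq_len(K))
      for (j in seq_len(cfg$sources_per_state))
        tc[k, j, ] <- bandlimited_noise(nt, cfg$fs)
    list(states = states, verts = verts, tc = tc)
  })
  data <- matrix(0, nrow(gain$values), nt)
  for (k in seq_len(K)) {
    on <- sim$states == k
    if (!any(on)) next
    src <- matrix(sim$tc[k, , on], nrow = cfg$sources_per_state)
    data[, on] <- data[, on] +
      gain$values[, sim$verts[k, ], drop = FALSE] %*% (cfg$source_amplitude * src)
  }
  rec <- sensor_recording(data, cfg$fs, sensors$labels, sim$states)
  if (!is.null(cfg$snr_db))
    rec <- add_noise_db(rec, cfg$snr_db, seed = cfg$seed + 104729L)
  rec
}

#' Add white sensor noise at a target SNR
#'
#' SNR is defined on broadband power pooled over all channels and samples:
#' `10*log10(mean(signal^2) / mean(noise^2)) = snr_db`. Noise is iid Gaussian
#' across channels and samples.
#'
#' @param rec a [sensor_recording()].
#' @param snr_db target SNR in dB (finite).
#' @param seed integer RNG seed.
#' @return the recording with noise added; attribute `snr_db` records the
#'   target.
#' @export
add_noise_db <- function(rec, snr_db, seed = 1) {
  stopifnot(inherits(rec, "sensor_recording"), is.finite(snr_db))
  ps <- mean(rec$data^2)
  if (ps == 0) stop("all-zero recording: SNR undefined")
  sd_n <- sqrt(ps * 10^(-snr_db / 10))
  noise <- withr::with_seed(seed,
    matrix(rnorm(length(rec$data), sd = sd_n), nrow(rec$data)))
  out <- rec
  out$data <- rec$data + noise
  attr(out, "snr_db") <- snr_db
  out
}

#' Shuffle channel rows while keeping labels fixed
#'
#' Destroys the correspondence between channel labels/positions and their
#' data by applying a uniform random permutation to the data rows only. The
#' inverse permutation (stored in attribute `permutation`) restores the
#' input exactly.
#'
#' @param rec a [sensor_recording()].
#' @param seed integer RNG seed.
#' @return the permuted recording with attribute `permutation` such that
#'   `data[permutation, ] == original data`... i.e. row i of the output is
#'   original row `permutation[i]`.
#' @export
shuffle_channels <- function(rec, seed = 1) {
  C <- nrow(rec$data)
  if (C < 2) {
    warning("single channel: nothing to shuffle")
    return(rec)
  }
  perm <- withr::with_seed(seed, sample.int(C))
  out <- rec
  out$data <- rec$data[perm, , drop = FALSE]
  attr(out, "permutation") <- perm
  out
}
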