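test_that("unperturbed gen_mesh is an exact sphere with valid topology", {
  m <- fix_sphere_mesh(162, radius = 70)
  expect_true(max(abs(sqrt(rowSums(m$vertices^2)) - 70)) < 1e-9)
  expect_identical(euler_characteristic(m), 2L)
  expect_true(validate_mesh(m))
})

test_that("folded meshes stay closed, band-limited and amplitude-calibrated", {
  m <- fix_folded_mesh(162, amp = 5, freq = 8, seed = 7)
  expect_identical(euler_characteristic(m), 2L)
  dev <- sqrt(rowSums(m$vertices^2)) - 70
  # unit-RMS field scaled by fold_amplitude
  expect_equal(sqrt(mean(dev^2)), 5, tolerance = 1e-10)
  # band-limited: the radial deviation lies in the degree <= freq harmonic
  # space, so projecting onto that space reproduces it
  u <- attr(m, "sphere_coords")
  B <- real_sph_harm(u, 8)
  resid <- dev - B %*% qr.coef(qr(B), dev)
  expect_lt(max(abs(resid)), 1e-8)
  # deviation bounded by amplitude times the field maximum (trivially tight)
  expect_true(max(abs(dev)) <= 5 * max(abs(dev / 5)) + 1e-12)
})

test_that("gen_mesh is deterministic and rejects bad parameters", {
  a <- fix_folded_mesh(seed = 5)
  b <- fix_folded_mesh(seed = 5)
  expect_identical(a$vertices, b$vertices)
  expect_error(gen_mesh(162, radius = -1), "radius")
})

test_that("sensor arrays have unique labels, live outside the conductor, and are seed-deterministic", {
  sa <- gen_sensor_array(272, cap_radius = 110, conductor_radius = 95, seed = 1)
  expect_length(unique(sa$labels), 272)
  expect_true(min(sqrt(rowSums(sa$positions^2))) > 95)
  expect_equal(sqrt(rowSums(sa$orientations^2)), rep(1, 272), tolerance = 1e-12)
  sb <- gen_sensor_array(10, 110, 95, seed = 9)
  sc <- gen_sensor_array(10, 110, 95, seed = 9)
  expect_identical(sb$positions, sc$positions)
  expect_error(gen_sensor_array(10, 90, 95), "cap_radius")
})

test_that("simulated recordings honour amplitude linearity and zero-amplitude silence", {
  m <- fix_sphere_mesh(42)
  sa <- fix_sensors(8)
  g <- gain_matrix(m, sa)
  cfg0 <- sim_config(n_states = 1, sources_per_state = 1, source_amplitude = 0,
                     snr_db = NULL, duration_s = 2, fs = 300, seed = 4)
  expect_true(all(simulate_recording(m, sa, cfg0, g)$data == 0))
  cfg1 <- sim_config(n_states = 2, sources_per_state = 2, source_amplitude = 10,
                     snr_db = NULL, duration_s = 2, fs = 300, seed = 4)
  cfg2 <- cfg1; cfg2$source_amplitude <- 20
  r1 <- simulate_recording(m, sa, cfg1, g)
  r2 <- simulate_recording(m, sa, cfg2, g)
  expect_identical(r1$state_truth, r2$state_truth)
  expect_equal(r2$data, 2 * r1$data, tolerance = 1e-12)
})

test_that("Markov statepath has the configured mean dwell and visits all states", {
  m <- fix_sphere_mesh(42)
  sa <- fix_sensors(8)
  g <- gain_matrix(m, sa)
  dwells <- unlist(lapply(1:20, function(s) {
    cfg <- sim_config(n_states = 2, state_dwell_ms = 200, sources_per_state = 1,
                      snr_db = NULL, duration_s = 60, fs = 300, seed = s)
    r <- simulate_recording(m, sa, cfg, g)
    runs <- rle(r$state_truth)$lengths
    runs / cfg$fs * 1000
  }))
  expect_lt(abs(mean(dwells) - 200) / 200, 0.20)
  cfg <- sim_config(n_states = 4, state_dwell_ms = 150, sources_per_state = 1,
                    snr_db = NULL, duration_s = 600, fs = 300, seed = 2)
  r <- simulate_recording(m, sa, cfg, g)
  expect_setequal(unique(r$state_truth), 1:4)
})

test_that("add_noise_db calibrates pooled power at 0, +5 and -20 dB", {
  rec <- sensor_recording(matrix(sin(seq(0, 400 * pi, length.out = 1.2e5)),
                                 nrow = 2, ncol = 6e4, byrow = TRUE),
                          fs = 100, labels = c("a", "b"))
  ps <- mean(rec$data^2)
  for (snr in c(0, 5, -20)) {
    noisy <- add_noise_db(rec, snr, seed = 11)
    pn <- mean((noisy$data - rec$data)^2)
    expect_lt(abs(pn / (ps * 10^(-snr / 10)) - 1), 0.02)
  }
  zero <- sensor_recording(matrix(0, 2, 100), 100, c("a", "b"))
  expect_error(add_noise_db(zero, 0), "SNR undefined")
})

test_that("channel shuffling permutes rows, keeps labels, and is invertible", {
  rec <- sensor_recording(matrix(rnorm(200), 10, 20), 100, letters[1:10])
  sh <- shuffle_channels(rec, seed = 3)
  expect_identical(sh$labels, rec$labels)
  expect_equal(sh$data[order(attr(sh, "permutation")), ], rec$data)
  expect_identical(sh$data, shuffle_channels(rec, seed = 3)$data)
  # sorted rows are the same multiset
  expect_equal(sh$data[order(sh$data[, 1]), ], rec$data[order(rec$data[, 1]), ])
  one <- sensor_recording(matrix(rnorm(20), 1, 20), 100, "a")
  expect_warning(shuffle_channels(one), "nothing to shuffle")
})

test_that("shuffle fixed-point fraction matches the uniform-permutation rate", {
  rec <- sensor_recording(matrix(seq_len(10), 10, 1), 100, letters[1:10])
  fp <- vapply(1:1000, function(s) {
    perm <- attr(shuffle_channels(rec, seed = s), "permutation")
    mean(perm == seq_len(10))
  }, numeric(1))
  expect_lt(abs(mean(fp) - 0.1), 0.02)
})
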