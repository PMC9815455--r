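# Synthetic reading-MEG generator: gaze events, ocular sources, assembly.

test_that("sim_config validates its stated ranges", {
  expect_error(sim_config(regression_prob = 1.2), "regression_prob")
  expect_error(sim_config(regression_prob = -0.1), "regression_prob")
  expect_error(sim_config(blink_duration = 50), "blink_duration")
  expect_error(sim_config(blink_duration = 900), "blink_duration")
  expect_error(sim_config(fixation_mean = 0), "strictly positive")
  expect_error(sim_config(sfreq = -600), "strictly positive")
  # defaults state the world: 10-15% regressions, blink within range
  cfg <- sim_config()
  expect_true(cfg$regression_prob >= 0.10 && cfg$regression_prob <= 0.15)
  expect_true(cfg$blink_duration >= 100 && cfg$blink_duration <= 500)
})

test_that("gaze alternates fixations and saccades with the page geometry", {
  g <- tiny_sim()$gaze
  expect_s3_class(g, "gaze_trace")
  expect_true(all(abs(g$h_angle) <= 7.71))
  expect_true(all(abs(g$v_angle) <= 3.86))
  # blink samples carry the undefined-gaze flag and the blink label
  expect_true(all(g$label[g$blink] == "blink"))
})

test_that("regression_prob = 0 yields no regressions", {
  g <- generate_gaze(tiny_cfg(seed = 3, regression_prob = 0))
  expect_false(any(g$label == "regression"))
  expect_false(any(g$events$type == "regression"))
})

test_that("every page contains exactly lines_per_page return sweeps", {
  for (lines in c(5L, 8L)) {
    g <- generate_gaze(tiny_cfg(seed = 11, lines_per_page = lines))
    ev <- g$events[g$events$type == "return_sweep", ]
    expect_equal(unname(table(factor(ev$page, levels = 1:3))),
                 rep(lines, 3), ignore_attr = TRUE)
    # independent replay: count label runs of return_sweep samples
    runs <- rle(as.character(g$label))
    expect_equal(sum(runs$values == "return_sweep"), 3 * lines)
  }
})

test_that("infeasible page duration errors", {
  expect_error(generate_gaze(tiny_cfg(page_duration = 0.5)),
               "page too short")
})

test_that("regression fraction matches the stated rate", {
  # scaled down from the spec's 1e5 saccades to ~8e3 for runtime; the
  # binomial band below is computed at the achieved count
  cfg <- sim_config(n_sensor_sites = 20, n_pages = 60, page_duration = 18,
                    blink_rate = 0.05, rng_seed = 21)
  g <- generate_gaze(cfg)
  n_sac <- sum(g$events$type %in% c("saccade", "regression"))
  n_reg <- sum(g$events$type == "regression")
  expect_gt(n_sac, 4000)
  se <- sqrt(0.125 * 0.875 / n_sac)
  expect_lt(abs(n_reg / n_sac - 0.125), 3 * se)
})

test_that("ocular sources: supports, spectra and degenerate cases", {
  cfg <- tiny_cfg()
  sim <- tiny_sim()
  src <- sim$truth$artifact_sources
  fs <- cfg$sfreq
  # constant gaze, no blinks -> all sources constant zero
  n <- 1200L
  flat <- structure(list(
    time = (seq_len(n) - 1) / fs, h_angle = rep(1.5, n),
    v_angle = rep(-2, n),
    label = factor(rep("fixation", n), levels = levels(sim$gaze$label)),
    blink = rep(FALSE, n), page_spans = cbind(1L, n + 1L), sfreq = fs,
    events = data.frame(type = "fixation", onset = 1, dur = n, page = 1)),
    class = "gaze_trace")
  oc <- ocular_signals(flat, cfg, sensor_layout(20))
  expect_equal(max(abs(oc$sources)), 0)
  # one blink of 300 ms -> support confined to [t0, t0 + 0.3 s)
  nb <- round(0.3 * fs)
  t0 <- 301L
  blinky <- flat
  blinky$blink[t0:(t0 + nb - 1L)] <- TRUE
  oc2 <- ocular_signals(blinky, cfg, sensor_layout(20))
  b <- oc2$sources["blink", ]
  expect_true(all(b[t0:(t0 + nb - 1L)] > 0))
  expect_equal(sum(b[-(t0:(t0 + nb - 1L))]), 0)
  # saccade dynamics concentrated in 4-20 Hz.  The artifact itself follows
  # gaze position (baseline-offset model), whose spectrum is dominated by
  # the ~0.5 Hz line-sweep fundamental; the 4-20 Hz saccade band describes
  # the movement dynamics, so the surrogate is asserted on the first
  # difference of the source.  Blink pulses live below 5 Hz directly.
  expect_gte(band_fraction(diff(src["saccade_h", ]), fs, c(4, 20)), 0.6)
  expect_gte(band_fraction(src["blink", ], fs, c(0.1, 5)), 0.6)
})

test_that("recording assembly satisfies the construction identity", {
  sim <- tiny_sim()
  rec <- sim$recording; tr <- sim$truth
  g <- rec$info$type == "grad"
  recon <- tr$artifact_mixing %*% tr$artifact_sources +
    tr$brain_mixing %*% tr$brain_sources + tr$sensor_noise
  expect_equal(rec$data[g, ], recon, ignore_attr = TRUE, tolerance = 0)
  expect_equal(nrow(rec$page_spans), sim$config$n_pages)
  expect_true(all(table(rec$info$site[g]) == 2))
})

test_that("seeded determinism and the silent-artifact limit", {
  a <- simulate_reading_dataset(tiny_cfg(seed = 12))
  b <- simulate_reading_dataset(tiny_cfg(seed = 12))
  expect_identical(a$recording$data, b$recording$data)
  expect_identical(a$truth$artifact_mixing, b$truth$artifact_mixing)
  # snr_artifact = -Inf: gradiometers carry no gaze signal
  s <- simulate_reading_dataset(tiny_cfg(seed = 5, snr_artifact = -Inf))
  g <- s$recording$info$type == "grad"
  cors <- abs(cor(t(s$recording$data[g, ]), s$gaze$h_angle))
  expect_lt(max(cors), 0.1)
  expect_equal(max(abs(s$truth$artifact_mixing)), 0)
})

test_that("ocular topographies have the stated spatial structure", {
  sim <- tiny_sim()
  sens <- sim$recording$sensors
  tr <- sim$truth
  # mirror pairing of sites about x = 0
  mir <- apply(sens$pos, 1, function(p) {
    which.min(colSums((t(sens$pos) - c(-p[1], p[2], p[3]))^2))
  })
  expect_true(all(abs(sens$pos[mir, 1] + sens$pos[, 1]) < 1e-9))
  # horizontal-saccade pattern: azimuthal-gradiometer weights are
  # sign-antisymmetric across the midline (global-handedness convention)
  a_h <- tr$artifact_mixing[, "saccade_h"]
  azi <- sens$channel_ori == 2L
  w <- a_h[azi]
  expect_equal(w[mir], -w, tolerance = 1e-6, ignore_attr = TRUE)
  # blink topography maximal at the most anterior sites bilaterally
  a_b <- tr$artifact_mixing[, "blink"]
  rms <- site_rms_topography(a_b, sens)
  anterior <- sens$pos[, 2] > quantile(sens$pos[, 2], 0.75)
  expect_gt(mean(rank(rms)[anterior]), mean(rank(rms)[!anterior]))
  top_site <- which.max(rms)
  expect_gt(sens$pos[top_site, 2], 0.05)
})
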