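# Synthetic continuous-reading MEG generator with ground truth.
#
# The generator states a world: a reader scans pages of 8 lines spanning
# 15.4 x 7.7 degrees of visual angle with ~2-degree forward saccades,
# 10-15% regressions, end-of-line return sweeps, lognormal fixation
# durations (mean 220 ms, sd 60 ms) and Poisson blinks (0.2/s, ~300 ms).
# Ocular artifact sources follow gaze position (baseline-offset model,
# roughly linear in saccade size); blink pulses are squared half-sines.
# Sensor data are x(t) = A s(t) + n(t): ocular mixing columns come from
# corneo-retinal dipoles through the spherical forward model, brain sources
# are oscillations + 1/f noise at grid locations, and the sensor noise is
# white.  A single integer seed drives all draws in documented order:
# (1) gaze events, (2) blink onsets, (3) brain source locations/frequencies,
# (4) brain time courses, (5) sensor and EOG noise.

#' Simulation configuration
#'
#' @param n_sensor_sites Sensor sites, each with 2 planar gradiometers.
#' @param sfreq Sampling rate (Hz).
#' @param n_pages Number of page units.
#' @param page_duration Nominal page duration (s); a page lasts at least as
#'   long as reading its lines takes, and is padded with a terminal
#'   fixation otherwise.
#' @param fixation_mean,fixation_sd Lognormal fixation duration moments (ms).
#' @param saccade_amplitude_mean Mean forward-saccade amplitude (degrees).
#' @param regression_prob Probability that a within-line saccade is a
#'   regression (backward); must lie in `[0, 1]`, default 0.125 (the
#'   midpoint of the 10-15% range typical of skilled readers).
#' @param lines_per_page Text lines per page.
#' @param blink_rate Blink events per second (Poisson).
#' @param blink_duration Blink duration (ms); constrained to 100-500 ms.
#' @param n_brain_sources Number of brain sources (the first is always an
#'   occipital 10-Hz oscillator so posterior-power retention is testable).
#' @param snr_artifact Artifact-to-brain power ratio at frontal sensors (dB).
#' @param blink_amplitude Blink pulse amplitude in gaze-degree equivalents
#'   (relative to the saccade sources, which live on the +-7.7 degree gaze
#'   scale).  Default 25: blinks are the largest single deflections on
#'   frontal channels, roughly three times a full-line saccade ramp.
#' @param noise_rel RMS of white sensor noise relative to the median total
#'   signal RMS per channel.  Default 0.05: the effective white-noise
#'   floor of bandpassed, interference-suppressed planar-gradiometer data
#'   relative to the combined cortical + artifact signal.  Raising this
#'   noticeably above ~0.1 makes the brief blink source only partially
#'   recoverable by any linear unmixing (see the methods vignette).
#' @param page_width,page_height Visual angle of the text block (degrees).
#' @param rng_seed Integer seed for all stochastic draws.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_sensor_sites = 102, sfreq = 600, n_pages = 20,
                       page_duration = 30, fixation_mean = 220,
                       fixation_sd = 60, saccade_amplitude_mean = 2.0,
                       regression_prob = 0.125, lines_per_page = 8,
                       blink_rate = 0.2, blink_duration = 300,
                       n_brain_sources = 10, snr_artifact = 0,
                       blink_amplitude = 25, noise_rel = 0.05,
                       page_width = 15.4, page_height = 7.7,
                       rng_seed = 1L) {
  cfg <- list(n_sensor_sites = n_sensor_sites, sfreq = sfreq,
              n_pages = n_pages, page_duration = page_duration,
              fixation_mean = fixation_mean, fixation_sd = fixation_sd,
              saccade_amplitude_mean = saccade_amplitude_mean,
              regression_prob = regression_prob,
              lines_per_page = lines_per_page, blink_rate = blink_rate,
              blink_duration = blink_duration,
              n_brain_sources = n_brain_sources,
              snr_artifact = snr_artifact,
              blink_amplitude = blink_amplitude, noise_rel = noise_rel,
              page_width = page_width, page_height = page_height,
              rng_seed = as.integer(rng_seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  pos <- c("sfreq", "n_pages", "page_duration", "fixation_mean",
           "fixation_sd", "saccade_amplitude_mean", "lines_per_page",
           "blink_duration", "page_width", "page_height")
  for (f in pos)
    if (cfg[[f]] <= 0) stop(sprintf("'%s' must be strictly positive", f))
  if (cfg$regression_prob < 0 || cfg$regression_prob > 1)
    stop("regression_prob must lie in [0, 1]")
  if (cfg$blink_duration < 100 || cfg$blink_duration > 500)
    stop("blink_duration must lie within 100-500 ms (some hundreds of ms)")
  if (cfg$blink_rate < 0) stop("blink_rate must be non-negative")
  invisible(TRUE)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %d sites @ %g Hz, %d pages x %gs, seed %d\n",
              x$n_sensor_sites, x$sfreq, x$n_pages, x$page_duration,
              x$rng_seed))
  invisible(x)
}

# gaze event labels
GAZE_LEVELS <- c("fixation", "saccade", "regression", "return_sweep", "blink")

#' Generate a reading gaze trace
#'
#' Alternates fixations (lognormal durations) and saccades: forward
#' saccades advance the gaze rightward along the current line, regressions
#' (with probability `regression_prob`) move it backward, and when the line
#' end is reached a return sweep takes the gaze to the start of the next
#' line (the last line of a page sweeps to the top-left of the next page,
#' so every page contains exactly `lines_per_page` return sweeps).  Blinks
#' are inserted as a Poisson process; blink samples are labelled and
#' flagged as undefined gaze.
#'
#' @param config A [sim_config()].
#' @return Object of class `gaze_trace`: `time` (s), `h_angle`, `v_angle`
#'   (degrees), `label` (factor with levels fixation/saccade/regression/
#'   return_sweep/blink), `blink` (logical undefined-gaze flag),
#'   `page_spans`, `sfreq`, and an `events` data frame (type, onset sample,
#'   duration in samples, page).
#' @export
generate_gaze <- function(config) {
  validate_sim_config(config)
  fs <- config$sfreq
  half_w <- config$page_width / 2
  half_h <- config$page_height / 2
  est_line <- (config$page_width / config$saccade_amplitude_mean) *
    (config$fixation_mean / 1000)
  if (config$page_duration < est_line)
    stop("page too short to hold one line of reading")
  set.seed(config$rng_seed)

  # lognormal parameterized by desired mean/sd (ms)
  cv2 <- (config$fixation_sd / config$fixation_mean)^2
  sdlog <- sqrt(log(1 + cv2))
  meanlog <- log(config$fixation_mean) - sdlog^2 / 2

  v_lines <- seq(half_h, -half_h, length.out = config$lines_per_page)
  sac_dur <- function(amp) max(12e-3, 21e-3 + 2.2e-3 * amp) # main sequence

  h <- v <- numeric(0)
  lab <- integer(0)
  events <- list()
  spans <- matrix(0L, config$n_pages, 2)
  samp <- 0L
  ev <- 0L

  add_seg <- function(n, hv, vv, code) {
    h <<- c(h, hv); v <<- c(v, vv); lab <<- c(lab, rep(code, n))
    samp <<- samp + n
  }
  log_event <- function(type, onset, dur, page) {
    ev <<- ev + 1L
    events[[ev]] <<- data.frame(type = type, onset = onset, dur = dur,
                                page = page)
  }

  for (pg in seq_len(config$n_pages)) {
    p0 <- samp + 1L
    for (ln in seq_len(config$lines_per_page)) {
      x <- -half_w + abs(rnorm(1, 0, 0.3))
      vl <- v_lines[ln]
      repeat {
        # fixation
        fd <- rlnorm(1, meanlog, sdlog) / 1000
        nf <- max(1L, round(fd * fs))
        log_event("fixation", samp + 1L, nf, pg)
        add_seg(nf, rep(x, nf), rep(vl, nf), 1L)
        if (x >= half_w - 1.2 * config$saccade_amplitude_mean) break
        # saccade: forward or regression
        is_reg <- runif(1) < config$regression_prob
        amp <- pmin(4, pmax(0.5,
                            rnorm(1, config$saccade_amplitude_mean, 0.5)))
        x1 <- if (is_reg) max(-half_w, x - amp) else min(half_w, x + amp)
        ns <- max(2L, round(sac_dur(abs(x1 - x)) * fs))
        ramp <- (1 - cos(pi * seq_len(ns) / ns)) / 2
        log_event(if (is_reg) "regression" else "saccade", samp + 1L, ns, pg)
        add_seg(ns, x + (x1 - x) * ramp, rep(vl, ns),
                if (is_reg) 3L else 2L)
        x <- x1
      }
      # return sweep to next line (or top of next page after the last line)
      v1 <- if (ln < config$lines_per_page) v_lines[ln + 1L] else v_lines[1L]
      x1 <- -half_w
      ns <- max(2L, round(sac_dur(abs(x - x1)) * fs))
      ramp <- (1 - cos(pi * seq_len(ns) / ns)) / 2
      log_event("return_sweep", samp + 1L, ns, pg)
      add_seg(ns, x + (x1 - x) * ramp, vl + (v1 - vl) * ramp, 4L)
    }
    # pad to nominal page duration with a terminal fixation
    need <- p0 - 1L + round(config$page_duration * fs) - samp
    if (need > 0L) {
      log_event("fixation", samp + 1L, need, pg)
      add_seg(need, rep(h[samp], need), rep(v[samp], need), 1L)
    }
    spans[pg, ] <- c(p0, samp + 1L)
  }

  n <- samp
  blink <- logical(n)
  # Poisson blink process over the whole trace
  n_blinks <- rpois(1, config$blink_rate * n / fs)
  nb <- max(1L, round(config$blink_duration / 1000 * fs))
  if (n_blinks > 0) {
    onsets <- sort(sample.int(n - nb, n_blinks))
    # enforce non-overlap
    keep <- c(TRUE, diff(onsets) > nb)
    onsets <- onsets[keep]
    for (o in onsets) {
      idx <- o:(o + nb - 1L)
      blink[idx] <- TRUE
      lab[idx] <- 5L
      log_event("blink", o, nb, findInterval(o, spans[, 1]))
    }
  }

  structure(list(time = (seq_len(n) - 1) / fs, h_angle = h, v_angle = v,
                 label = factor(GAZE_LEVELS[lab], levels = GAZE_LEVELS),
                 blink = blink, page_spans = spans, sfreq = fs,
                 events = do.call(rbind, events)),
            class = "gaze_trace")
}

#' @export
print.gaze_trace <- function(x, ...) {
  cat(sprintf("<gaze_trace> %.1f s @ %g Hz, %d pages, %d events\n",
              length(x$h_angle) / x$sfreq, x$sfreq, nrow(x$page_spans),
              nrow(x$events)))
  invisible(x)
}

#' Ocular artifact sources from a gaze trace
#'
#' Builds the artifact part of the ground truth: saccade sources follow the
#' (demeaned) horizontal and vertical gaze angles -- a baseline-offset
#' model in which the artifact tracks eye position, scaled linearly with
#' gaze angle -- and the blink source is a sum of squared half-sine pulses
#' of `blink_duration` at the blink onsets.  Each source is assigned a
#' sensor-space mixing column from corneo-retinal dipoles at the two eye
#' positions through the spherical forward model: horizontal rotation tilts
#' the (gaze-aligned) dipole sideways (x-directed moment at both eyes),
#' vertical rotation tilts it up (z-directed), and the eyelid slide of a
#' blink is modelled as an upward/anterior moment change, bilaterally
#' symmetric.
#'
#' @param gaze A [generate_gaze()] result sampled at `config$sfreq`.
#' @param config The matching [sim_config()].
#' @param sensors A [sensor_layout()]; defaults to one built from `config`.
#' @return List with `sources` (3 x samples matrix, rows `saccade_h`,
#'   `saccade_v`, `blink`, in gaze-degree equivalents), `mixing`
#'   (channels x 3 unit-calibrated columns), `blink_onsets`, `sensors`.
#' @export
ocular_signals <- function(gaze, config,
                           sensors = sensor_layout(config$n_sensor_sites)) {
  if (gaze$sfreq != config$sfreq)
    stop("gaze must be sampled at config$sfreq")
  n <- length(gaze$h_angle)
  s_h <- gaze$h_angle - mean(gaze$h_angle)
  s_v <- gaze$v_angle - mean(gaze$v_angle)
  nb <- max(1L, round(config$blink_duration / 1000 * config$sfreq))
  onsets <- which(diff(c(FALSE, gaze$blink)) > 0)
  s_b <- numeric(n)
  pulse <- sin(pi * (seq_len(nb) - 0.5) / nb)^2
  for (o in onsets) {
    idx <- o:min(n, o + nb - 1L)
    amp <- if (is.null(config$blink_amplitude)) 25 else config$blink_amplitude
    s_b[idx] <- s_b[idx] + amp * pulse[seq_along(idx)]
  }
  eyes <- eye_positions(sensors)
  col_for <- function(q) {
    leadfield_sphere(eyes[1, ], q, sensors) +
      leadfield_sphere(eyes[2, ], q, sensors)
  }
  q_b <- c(0, 0.45, 0.9); q_b <- q_b / sqrt(sum(q_b^2))
  mixing <- cbind(saccade_h = col_for(c(1, 0, 0)),
                  saccade_v = col_for(c(0, 0, 1)),
                  blink = col_for(q_b))
  # unit-norm columns; physical amplitude is set at assembly via the
  # frontal-sensor SNR calibration
  mixing <- sweep(mixing, 2, sqrt(colSums(mixing^2)), "/")
  list(sources = rbind(saccade_h = s_h, saccade_v = s_v, blink = s_b),
       mixing = mixing, blink_onsets = onsets, sensors = sensors)
}

#' Assemble a synthetic recording from ground-truth pieces
#'
#' Mixes the ocular artifact sources, brain sources (oscillations with 1/f
#' background at random intracranial locations, tangential orientations)
#' and white sensor noise into gradiometer data; adds EOG channels (gaze
#' plus blink leakage and noise) and eye-tracker channels; calibrates the
#' global artifact gain so the frontal-sensor artifact RMS matches
#' `snr_artifact` (dB) relative to the frontal-sensor brain RMS.  The
#' construction identity `data = A_art s_art + A_brain s_brain + n` holds
#' exactly on the gradiometer channels.
#'
#' @param ocular Result of [ocular_signals()].
#' @param gaze The matching [generate_gaze()] result.
#' @param config The [sim_config()].
#' @return List with `recording` (a [meg_recording()]) and `truth`
#'   (class `simulation_truth`).
#' @export
assemble_recording <- function(ocular, gaze, config) {
  sensors <- ocular$sensors
  m <- 2 * sensors$n_sites
  n <- ncol(ocular$sources)
  fs <- config$sfreq
  set.seed(config$rng_seed + 1L)

  # brain sources: random tangential dipoles inside the head; source 1 is
  # a fixed occipital alpha oscillator
  nb <- config$n_brain_sources
  brain_pos <- matrix(0, max(nb, 1), 3)
  brain_mix <- matrix(0, m, max(nb, 1))
  S_brain <- matrix(0, max(nb, 1), n)
  if (nb > 0) {
    for (i in seq_len(nb)) {
      if (i == 1) {
        p <- c(0, -0.065, 0.02) + rnorm(3, 0, 0.004)
        f0 <- 10
      } else {
        repeat {
          p <- runif(3, -0.07, 0.07)
          r <- sqrt(sum(p^2))
          if (r < 0.07 && p[2] < 0.05) break # intracranial, not ocular
        }
        f0 <- runif(1, 3, 40)
      }
      brain_pos[i, ] <- p
      tb <- tangential_basis(p)
      ang <- runif(1, 0, 2 * pi)
      q <- cos(ang) * tb[1, ] + sin(ang) * tb[2, ]
      brain_mix[, i] <- leadfield_sphere(p, q, sensors)
      # amplitude-modulated oscillation + pink background
      t <- (seq_len(n) - 1) / fs
      am <- 1 + 0.5 * sin(2 * pi * runif(1, 0.05, 0.2) * t + runif(1, 0, 2 * pi))
      osc <- am * sin(2 * pi * f0 * t + runif(1, 0, 2 * pi))
      pink <- pink_noise(n)
      x <- osc + 0.7 * pink
      S_brain[i, ] <- x / sd(x)
    }
    # normalize columns, then scale brain projection to a realistic
    # planar-gradiometer level (median channel RMS 1e-11 T/m ~ 100 fT/cm)
    brain_mix <- sweep(brain_mix, 2, sqrt(colSums(brain_mix^2)), "/")
    proj <- brain_mix %*% S_brain
    g_b <- 1e-11 / median(sqrt(rowMeans(proj^2)))
    brain_mix <- brain_mix * g_b
  }
  brain_contrib <- brain_mix %*% S_brain

  # artifact gain calibration at frontal sensors
  frontal <- rep(sensors$pos[, 2] > 0.05, each = 2)
  art_raw <- ocular$mixing %*% ocular$sources
  rms <- function(x) sqrt(mean(x^2))
  brain_frontal_rms <- max(rms(brain_contrib[frontal, ]), 1e-30)
  target <- 10^(config$snr_artifact / 20) * brain_frontal_rms
  g_a <- if (is.finite(config$snr_artifact)) {
    target / max(rms(art_raw[frontal, ]), 1e-30)
  } else 0 # snr_artifact = -Inf: no artifact
  art_mixing <- ocular$mixing * g_a
  art_contrib <- art_mixing %*% ocular$sources

  noise_sd <- config$noise_rel *
    median(sqrt(rowMeans((brain_contrib + art_contrib)^2)))
  if (!is.finite(noise_sd) || noise_sd <= 0) noise_sd <- 1e-12
  noise <- matrix(rnorm(m * n, 0, noise_sd), m, n)

  meg <- art_contrib + brain_contrib + noise

  # EOG: electrical gaze signal + blink leakage + frontal brain leakage
  sac_h <- ocular$sources["saccade_h", ]
  sac_v <- ocular$sources["saccade_v", ]
  bl <- ocular$sources["blink", ]
  leak <- if (nrow(S_brain) > 0) colSums(S_brain) / max(1, nrow(S_brain)) else 0
  heog <- sac_h + 0.1 * bl + 0.05 * leak +
    rnorm(n, 0, 0.05 * max(sd(sac_h), 1e-12))
  # VEOG blink deflections slightly exceed the vertical-gaze span
  # (~400 uV blink peaks vs ~16 uV/deg gaze sensitivity)
  veog_clean <- sac_v + 1.2 * bl
  veog <- veog_clean + 0.05 * leak +
    rnorm(n, 0, 0.05 * max(sd(veog_clean), 1e-12))

  data <- rbind(meg, heog, veog, gaze$h_angle, gaze$v_angle,
                as.numeric(gaze$blink))
  info <- data.frame(
    name = c(sensors$channel_names, "EOG_H", "EOG_V", "ET_X", "ET_Y",
             "ET_BLINK"),
    type = c(rep("grad", m), "eog_h", "eog_v", "eyetrack", "eyetrack",
             "eyetrack"),
    site = c(sensors$channel_site, rep(NA_integer_, 5)),
    pair = c(sensors$channel_ori, rep(NA_integer_, 5)),
    stringsAsFactors = FALSE)

  rec <- meg_recording(data, info, fs, gaze$page_spans, sensors)
  truth <- structure(list(
    artifact_sources = ocular$sources,
    artifact_mixing = art_mixing,
    brain_sources = S_brain,
    brain_mixing = brain_mix,
    brain_positions = brain_pos,
    sensor_noise = noise,
    blink_onsets = ocular$blink_onsets,
    frontal_channels = frontal),
    class = "simulation_truth")
  list(recording = rec, truth = truth)
}

# 1/f ("pink") noise via spectral shaping
pink_noise <- function(n) {
  nf <- floor(n / 2)
  f <- seq_len(nf)
  amp <- 1 / sqrt(f)
  ph <- runif(nf, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = ph)
  full <- c(0, spec, if (n %% 2 == 0) Re(spec[nf]) else NULL,
            Conj(rev(spec[seq_len(nf - if (n %% 2 == 0) 1 else 0)])))
  x <- Re(fft(full[seq_len(n)], inverse = TRUE))
  x / sd(x)
}

#' Simulate a full continuous-reading MEG dataset
#'
#' Convenience wrapper running [generate_gaze()], [ocular_signals()] and
#' [assemble_recording()] with a shared configuration; identical config and
#' seed give byte-identical output.
#'
#' @param config A [sim_config()].
#' @return Object of class `reading_sim`: list with `recording`, `truth`,
#'   `gaze`, `config`.
#' @export
simulate_reading_dataset <- function(config = sim_config()) {
  gaze <- generate_gaze(config)
  sens <- sensor_layout(config$n_sensor_sites)
  oc <- ocular_signals(gaze, config, sens)
  asm <- assemble_recording(oc, gaze, config)
  structure(list(recording = asm$recording, truth = asm$truth, gaze = gaze,
                 config = config),
            class = "reading_sim")
}

#' @export
print.reading_sim <- function(x, ...) {
  print(x$config); print(x$recording)
  invisible(x)
}
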