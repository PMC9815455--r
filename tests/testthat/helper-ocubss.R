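# Shared fixtures and oracles.  Everything is generated in code; the
# heavier objects are memoised so several test files can share one copy.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

# small reading simulation: 20 sensor sites, 3 pages of 15 s
tiny_cfg <- function(seed = 7, page_duration = 15, ...) {
  sim_config(n_sensor_sites = 20, n_pages = 3,
             page_duration = page_duration, rng_seed = seed, ...)
}

tiny_sim <- function() memo("tiny_sim", simulate_reading_dataset(tiny_cfg()))

# coarse localization grid matching the 20-site layout
tiny_grid <- function() memo("tiny_grid", {
  make_forward_grid(sensor_layout(20), spacing = 0.012,
                    eye_spacing = 0.005)
})

# Amari index: permutation/scale-invariant separation error of a gain
# matrix P = W_est %*% A_true; 0 means perfect up to signed permutation.
amari_index <- function(P) {
  P <- abs(P)
  n <- nrow(P)
  r <- (sum(P / apply(P, 1, max)) - n) / (2 * n * (n - 1))
  c <- (sum(t(t(P) / apply(P, 2, max))) - n) / (2 * n * (n - 1))
  r + c
}

# best |correlation| of each true source with any estimated component
best_corrs <- function(sources_est, sources_true) {
  cc <- abs(cor(t(sources_est), t(sources_true)))
  apply(cc, 2, max)
}

# band power via Welch periodogram (oracle-side helper)
band_power <- function(x, sfreq, band) {
  sp <- stats::spec.pgram(stats::ts(x, frequency = sfreq), spans = 9,
                          plot = FALSE, detrend = TRUE)
  sum(sp$spec[sp$freq >= band[1] & sp$freq <= band[2]])
}

# fraction of spectral power inside a band
band_fraction <- function(x, sfreq, band) {
  sp <- stats::spec.pgram(stats::ts(x, frequency = sfreq), spans = 9,
                          plot = FALSE, detrend = TRUE)
  sum(sp$spec[sp$freq >= band[1] & sp$freq <= band[2]]) / sum(sp$spec)
}

# 4-source benchmark mixture: every source carries temporal structure
# (for second-order separation) and a distinctive non-Gaussian marginal
# (for the higher-order methods)
make_benchmark_sources <- function(n_samples, sfreq = 600, seed = 1) {
  set.seed(seed)
  t <- (seq_len(n_samples) - 1) / sfreq
  # One sign-alternating sparse pulse train (symmetric, very
  # super-Gaussian, ~60 ms autocorrelation), one sawtooth (the only
  # strongly sub-Gaussian member -- marginal-likelihood ICA entangles
  # pairs of heavily sub-Gaussian or one-sided sparse sources), and two
  # lightly AR-filtered Laplacians with different correlation lengths.
  pulse_train <- function(width_s, rate_hz) {
    x <- numeric(n_samples)
    w <- round(width_s * sfreq)
    pulse <- sin(pi * seq_len(w) / w)^2
    for (o in which(runif(n_samples - w) < rate_hz / sfreq))
      x[o:(o + w - 1L)] <- x[o:(o + w - 1L)] +
        sample(c(-1, 1), 1) * pulse
    x
  }
  lap_ar <- function(phi) {
    as.numeric(stats::filter(sign(rnorm(n_samples)) * rexp(n_samples),
                             phi, method = "recursive"))
  }
  s1 <- pulse_train(0.06, 3)
  s2 <- 2 * ((3 * t + runif(1)) %% 1) - 1              # uniform marginal
  s3 <- lap_ar(0.4)
  s4 <- lap_ar(0.15)
  S <- rbind(s1, s2, s3, s4)
  S / apply(S, 1, sd)
}
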