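# Component removal and pipeline-level behaviour.

test_that("removal identities hold to machine precision", {
  sim <- tiny_sim()
  rec <- demean_pages(sim$recording)
  g <- rec$info$type == "grad"
  dec <- suppressWarnings(sobi_decompose(rec, lags = 0:30))
  # empty set: exact identity
  expect_identical(remove_components(dec, rec, integer(0))$data, rec$data)
  # removing everything with a square invertible W leaves ~nothing
  all_gone <- remove_components(dec, rec, seq_len(n_components(dec)))
  expect_lt(max(abs(all_gone$data[g, ])) / max(abs(rec$data[g, ])), 1e-8)
  # reconstruction: cleaned + removed contribution = original
  idx <- c(1L, 3L)
  cleaned <- remove_components(dec, rec, idx)
  contrib <- dec$mixing[, idx] %*% (dec$demixing[idx, ] %*% rec$data[g, ])
  expect_equal(cleaned$data[g, ] + contrib, rec$data[g, ],
               tolerance = 1e-12, ignore_attr = TRUE)
  # auxiliary channels and page spans untouched
  expect_identical(cleaned$data[!g, ], rec$data[!g, ])
  expect_identical(cleaned$page_spans, rec$page_spans)
  expect_error(remove_components(dec, rec, 999L), "out of range")
})

test_that("an artifact-free recording passes through with a warning", {
  cfg <- sim_config(n_sensor_sites = 16, n_pages = 2, page_duration = 12,
                    n_brain_sources = 6, snr_artifact = -Inf,
                    rng_seed = 9)
  sim <- simulate_reading_dataset(cfg)
  grid16 <- memo("grid16c", make_forward_grid(sensor_layout(16),
                                              spacing = 0.014,
                                              eye_spacing = 0.006))
  # the decompositions also warn about hitting their iteration caps;
  # capture everything and check for the pipeline-level message
  w <- capture_warnings(
    res <- run_pipeline(sim$recording, "sobi_fastica", grid = grid16,
                        top_k = 80, fastica_components = 12, seed = 2))
  expect_true(any(grepl("no saccade or blink", w)))
  # nothing was removed: output equals the demeaned input
  ref <- demean_pages(sim$recording)
  expect_equal(res$recording$data, ref$data, tolerance = 1e-12)
  expect_length(res$provenance$saccade_components, 0)
  expect_length(res$provenance$blink_components, 0)
  # strict mode errors instead
  expect_error(
    suppressWarnings(
      run_pipeline(sim$recording, "sobi_fastica", grid = grid16,
                   top_k = 80, fastica_components = 12, seed = 2,
                   strict = TRUE)),
    "no saccade or blink")
})

test_that("the two-stage pipeline removes both artifacts deterministically", {
  cfg <- sim_config(n_sensor_sites = 16, n_pages = 2, page_duration = 12,
                    n_brain_sources = 6, rng_seed = 205)
  sim <- simulate_reading_dataset(cfg)
  grid16 <- memo("grid16c", make_forward_grid(sensor_layout(16),
                                              spacing = 0.014,
                                              eye_spacing = 0.006))
  run_once <- function() suppressWarnings(
    run_pipeline(sim$recording, "sobi_fastica", grid = grid16,
                 top_k = 80, fastica_components = 12, seed = 3))
  res1 <- run_once()
  expect_gte(length(res1$provenance$saccade_components), 1)
  expect_gte(length(res1$provenance$blink_components), 1)
  expect_true(all(0:150 %in% res1$provenance$lags))
  # frontal artifact power reduced
  g <- sim$recording$info$type == "grad"
  fr <- sim$truth$frontal_channels
  ref <- demean_pages(sim$recording)
  before <- mean(ref$data[g, ][fr, ]^2)
  after <- mean(res1$recording$data[g, ][fr, ]^2)
  expect_lt(after, before)
  # determinism
  res2 <- run_once()
  expect_identical(res1$recording$data, res2$recording$data)
  expect_identical(res1$provenance, res2$provenance)
})
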