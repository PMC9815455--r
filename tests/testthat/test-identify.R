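# Component identification: localization, EOG correlation, features,
# classification.

test_that("localization ranks the generating point first", {
  grid <- tiny_grid()
  eye_idx <- which(grid$in_eye_region)[3]
  tb <- tangential_basis(grid$points[eye_idx, ])
  topo <- drop(grid$leadfield[, , eye_idx] %*% tb[1, ])
  loc <- localize_component(topo, grid, top_k = 100)
  expect_equal(loc$ranking$point[1], eye_idx)
  expect_equal(loc$ranking$correlation[1], 1, tolerance = 1e-8)
  expect_gte(loc$eye_fraction, 0.5)
  # occipital source: essentially no eye-region points in the top ranks
  occ <- which(grid$points[, 2] < -0.05 & grid$points[, 3] > 0)[1]
  tb2 <- tangential_basis(grid$points[occ, ])
  topo2 <- drop(grid$leadfield[, , occ] %*% tb2[2, ])
  loc2 <- localize_component(topo2, grid, top_k = 100)
  expect_lte(loc2$eye_fraction, 0.05)
  # sign and scale invariance of the ranking
  loc3 <- localize_component(-topo, grid, top_k = 100)
  expect_identical(loc3$ranking$point, loc$ranking$point)
  loc4 <- localize_component(3.7 * topo, grid, top_k = 100)
  expect_identical(loc4$ranking$point, loc$ranking$point)
  expect_error(localize_component(rep(1, 40), grid), "zero-variance")
})

test_that("EOG correlation: identities, independence, segment restriction", {
  set.seed(40)
  n <- 100000
  heog <- rnorm(n)
  veog <- rnorm(n)
  r <- eog_correlation(heog, heog, veog)
  expect_equal(r[["r_h"]], 1)
  expect_lt(abs(eog_correlation(rnorm(n), heog, veog)[["r_h"]]), 0.02)
  # blink-segment restriction strengthens a blink component's r_v
  blink <- rep(0, n); on <- seq(1000, n - 200, by = 5000)
  for (o in on) blink[o:(o + 180)] <- sin(pi * (0:180) / 180)^2
  comp <- blink + 0.3 * rnorm(n)
  veog2 <- 2.5 * blink + rnorm(n, 0, 0.5) + 0.5 * rnorm(n)
  seg <- blink > 0
  r_all <- eog_correlation(comp, heog, veog2)[["r_v"]]
  r_seg <- eog_correlation(comp, heog, veog2, segments = seg)[["r_v"]]
  expect_gt(r_seg, r_all)
  expect_error(eog_correlation(rep(0, n), heog, veog), "zero-variance")
})

test_that("sawtooth score separates reading ramps from oscillations", {
  fs <- 600
  t <- (0:17999) / fs
  saw <- 2 * ((0.8 * t) %% 1) - 1           # slow rise, sharp fall
  sine <- sin(2 * pi * 0.8 * t)
  expect_gte(sawtooth_score(saw + rnorm(length(saw), 0, 0.05), fs), 0.6)
  expect_lt(sawtooth_score(sine, fs), sawtooth_score(saw, fs))
  expect_equal(sawtooth_score(rnorm(18000), fs), 0)
})

test_that("spike rate counts separated robust outliers", {
  fs <- 600
  x <- rnorm(12000, 0, 0.1)
  on <- seq(500, 11500, by = 1200)
  for (o in on) x[o:(o + 150)] <- x[o:(o + 150)] + 3
  sr <- spike_rate(x, fs)
  expect_equal(sr$count, length(on))
  expect_equal(sr$rate, length(on) / 20, tolerance = 0.01)
  expect_equal(spike_rate(rep(0, 1000), fs)$count, 0L)
})

test_that("the classification rule follows its stated logic", {
  th <- identify_thresholds()
  sac_feats <- list(sawtooth = 0.8, r_h = 0.9, r_v = 0.1,
                    eye_fraction = 0.7, kurtosis = 2, spike_count = 0,
                    duration_s = 60)
  expect_equal(classify_component(sac_feats, th)$label, "saccade")
  blink_feats <- list(sawtooth = 0.1, r_h = 0.1, r_v = 0.85,
                      eye_fraction = 0.7, kurtosis = 20, spike_count = 10,
                      duration_s = 60)
  expect_equal(classify_component(blink_feats, th, blink_n = 12)$label,
               "blink")
  # blink-shaped but localized away from the eyes: other + manual review
  posterior <- blink_feats; posterior$eye_fraction <- 0.1
  cl <- classify_component(posterior, th, blink_n = 12)
  expect_equal(cl$label, "other")
  expect_true(cl$review)
  # vertical-gaze staircase: eye-localized, page-period sawtooth, weak
  # EOG correlations -> still a saccade component
  vert <- list(sawtooth = 0.8, r_h = 0.1, r_v = 0.45, eye_fraction = 0.8,
               kurtosis = 2, spike_count = 0, duration_s = 60)
  expect_equal(classify_component(vert, th)$label, "saccade")
  # a brain oscillation matches nothing
  alpha_feats <- list(sawtooth = 0.2, r_h = 0.05, r_v = 0.02,
                      eye_fraction = 0, kurtosis = 2.2, spike_count = 1,
                      duration_s = 60)
  expect_equal(classify_component(alpha_feats, th)$label, "other")
})

test_that("identify_components labels a simulated SOBI decomposition", {
  sim <- tiny_sim()
  rec <- demean_pages(sim$recording)
  dec <- suppressWarnings(sobi_decompose(rec, lags = 0:150))
  rep_ <- identify_components(dec, rec, tiny_grid(), top_k = 100)
  expect_s3_class(rep_, "component_report")
  sac <- labelled_components(rep_, "saccade", primary_only = TRUE)
  expect_length(sac, 1)
  cc <- abs(cor(dec$sources[sac, ], sim$truth$artifact_sources["saccade_h", ]))
  expect_gte(cc, 0.9)
  # manual override wins
  rep2 <- identify_components(dec, rec, tiny_grid(), top_k = 100,
                              override = setNames(list("other"),
                                                  as.character(sac)))
  expect_false(sac %in% labelled_components(rep2, "saccade"))
  # topographies attribute: one site-RMS column per component
  expect_equal(dim(attr(rep_, "topographies")),
               c(20, n_components(dec)))
})
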