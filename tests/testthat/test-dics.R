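# Frequency-domain beamformer evaluation.

sine_rec <- function(n = 12000, fs = 600) {
  t <- (0:(n - 1)) / fs
  sin(2 * pi * 10 * t)
}

test_that("CSD: coherent sines, independent noise, AR oracle", {
  fs <- 600
  s <- sine_rec()
  X <- rbind(a = s, b = 0.8 * s)
  csd <- compute_csd(X, c(8, 13), sfreq = fs)
  C <- csd$matrix
  coh <- abs(C[1, 2]) / sqrt(Re(C[1, 1]) * Re(C[2, 2]))
  expect_gt(coh, 0.999)
  expect_equal(csd$rank, 1)
  expect_lt(max(abs(C - Conj(t(C)))), 1e-10)
  # independent white channels: off-diagonals vanish relative to diagonal
  set.seed(50)
  Xw <- matrix(rnorm(4 * 120000), 4)
  cw <- compute_csd(Xw, c(20, 40), sfreq = fs)$matrix
  expect_lt(max(abs(cw[upper.tri(cw)])) / min(Re(diag(cw))), 0.1)
  # AR(1) diagonal matches the closed-form spectrum within 5% (band mean)
  set.seed(51)
  phi <- 0.8; sd_in <- 1
  xar <- as.numeric(arima.sim(list(ar = phi), 600000, sd = sd_in))
  band <- c(5, 15)
  ca <- compute_csd(rbind(xar, rnorm(600000)), band, sfreq = fs)
  # mean AR(1) spectral density over the band bins (one-sided in Hz)
  nseg <- 600
  freqs <- (1:(nseg / 2)) * fs / nseg
  fb <- freqs[freqs >= band[1] & freqs <= band[2]]
  sar <- sd_in^2 / (fs * abs(1 - phi * exp(-2i * pi * fb / fs))^2)
  expect_equal(Re(ca$matrix[1, 1]), mean(sar), tolerance = 0.05)
  expect_error(compute_csd(Xw, c(250, 320), sfreq = fs), "Nyquist")
})

test_that("common filter: closed form at C = I and rank rule", {
  grid <- tiny_grid()
  m <- 40
  chn <- grid$sensors$channel_names
  mk_csd <- function(C, rank) {
    structure(list(band = c(8, 13), matrix = C, rank = rank,
                   n_segments = 10, channels = chn), class = "csd")
  }
  ci <- mk_csd(diag(m) + 0i, m)
  fl <- common_filter(ci, ci, ci, grid)
  p <- source_power(fl, ci)
  # oracle: power = 1 / (l'l) with l the best tangential leadfield
  i <- 25
  tb <- tangential_basis(grid$points[i, ])
  L <- grid$leadfield[, , i] %*% t(tb)
  lam <- eigen(crossprod(L), symmetric = TRUE)$values[2]
  expect_equal(p$power[i], 1 / lam, tolerance = 1e-8)
  # rank rule: the smaller cleaned rank is used
  c2 <- mk_csd(diag(m) + 0i, 17)
  fl2 <- common_filter(ci, c2, ci, grid)
  expect_equal(fl2$rank_used, 17)
  # weights never depend on the condition CSD fed to source_power
  cs <- mk_csd(2 * diag(m) + 0i, m)
  p2 <- source_power(fl, cs)
  expect_equal(p2$power, 2 * p$power, tolerance = 1e-10)
  expect_equal(source_power(fl, mk_csd(matrix(0i, m, m), 0))$power,
               rep(0, nrow(grid$points)))
})

test_that("a simulated point source peaks at its own grid point", {
  grid <- tiny_grid()
  sens <- grid$sensors
  fs <- 600
  src_i <- which(grid$points[, 2] < 0 & grid$points[, 3] > 0.02)[3]
  tb <- tangential_basis(grid$points[src_i, ])
  l <- drop(grid$leadfield[, , src_i] %*% tb[1, ])
  set.seed(52)
  s <- sine_rec(24000)
  X <- outer(l, s) + matrix(rnorm(40 * 24000, 0, max(abs(l)) * 0.03), 40)
  rownames(X) <- sens$channel_names
  csd <- compute_csd(X, c(8, 13), sfreq = fs)
  fl <- common_filter(csd, csd, csd, grid)
  p <- source_power(fl, csd)
  peak <- which.max(p$power)
  d <- sqrt(sum((grid$points[peak, ] - grid$points[src_i, ])^2))
  expect_lte(d, grid$spacing + 1e-9)
})

test_that("reduction maps implement the stated normalizations", {
  pu <- c(10, 5, 2, 1e-20)
  mk <- function(p) structure(data.frame(point = seq_along(p), power = p),
                              class = c("power_map", "data.frame"))
  # no change -> 0; total removal -> 1; identical pipelines -> diff 0
  rm1 <- reduction_maps(mk(pu), mk(pu), mk(pu * 0.5))
  expect_equal(rm1$reduction_p1[1:3], rep(0, 3))
  rm2 <- reduction_maps(mk(pu), mk(rep(0, 4)), mk(pu * 0.5))
  expect_equal(rm2$reduction_p1[1:3], rep(1, 3))
  rm3 <- reduction_maps(mk(pu), mk(pu * 0.4), mk(pu * 0.4))
  expect_equal(rm3$difference[1:3], rep(0, 3))
  # guarded division flags
  expect_true(rm1$guarded[4])
  expect_true(is.na(rm1$reduction_p1[4]))
  # the pipeline difference is normalized by the power pipeline 2 removed
  rm4 <- reduction_maps(mk(c(10)), mk(c(6)), mk(c(8)))
  expect_equal(rm4$difference[1], (4 - 2) / 2)
  # negative reductions (estimated increases) are preserved
  rm5 <- reduction_maps(mk(c(10)), mk(c(12)), mk(c(9)))
  expect_equal(rm5$reduction_p1[1], -0.2)
})

test_that("parcel tests: constant shift and input validation", {
  set.seed(53)
  grid <- tiny_grid()
  parc <- default_parcellation(grid)
  np <- nrow(grid$points)
  ns <- 12
  delta <- 0.2
  maps <- list(alpha = matrix(rnorm(np * ns, delta, 0.01), np, ns))
  res <- parcel_and_test(maps, parc, alpha = 0.005, diff_threshold = 0.05)
  expect_true(all(res$point_tests$significant))
  expect_equal(res$parcel_table$mean_difference,
               rep(delta, nrow(res$parcel_table)), tolerance = 0.01)
  expect_true(all(levels(parc) %in% c(res$selected$parcel, "eye region")) ||
                nrow(res$selected) > 0)
  expect_error(parcel_and_test(list(a = maps$alpha[, 1:2]), parc),
               "3 subjects")
})
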