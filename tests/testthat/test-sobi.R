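# SOBI: lag selection, whitening, joint diagonalization, decomposition.

test_that("lag selection unions the base interval with high-acf lags", {
  set.seed(10)
  # white noise: nothing beyond the base interval (w.h.p.)
  lags <- select_lags(rnorm(20000), search_max = 1500)
  expect_identical(lags, 0:150)
  # sawtooth with period 900 samples: a neighbourhood of 900 joins in
  saw <- rep(seq(0, 1, length.out = 900), 20)
  lags2 <- select_lags(saw + rnorm(length(saw), 0, 0.05),
                       search_max = 1200)
  expect_true(all(0:150 %in% lags2))
  expect_true(any(abs(lags2 - 900) <= 5))
  # derived oracle: the extra lags are exactly those with acf >= 0.3
  a <- as.numeric(acf(saw + 0, lag.max = 1200, demean = TRUE,
                      plot = FALSE)$acf)
  extra_oracle <- which(a >= 0.3) - 1L
  lags3 <- select_lags(saw, search_max = 1200)
  expect_identical(lags3, sort(unique(c(0:150, extra_oracle))))
  expect_error(select_lags(rep(1, 5000)), "constant")
  expect_error(select_lags(rnorm(100), search_max = 1200), "longer")
})

test_that("whitening yields identity covariance with exact inverses", {
  set.seed(11)
  X <- diag(c(3, 5)) %*% matrix(rnorm(2 * 20000), 2)
  X <- X - rowMeans(X)
  wh <- whiten(X)
  C <- tcrossprod(wh$Z) / ncol(X)
  expect_lt(max(abs(C - diag(nrow(C)))), 1e-8)
  # dewhitener inverts the whitener on the retained subspace
  expect_equal(wh$whitener %*% wh$dewhitener, diag(nrow(wh$whitener)),
               tolerance = 1e-10, ignore_attr = TRUE)
  # scaling is recovered up to rotation: |K| rows relate to 1/sd
  sv <- svd(wh$whitener)$d
  expect_equal(sort(sv), sort(1 / sqrt(eigen(tcrossprod(X) / ncol(X))$values)),
               tolerance = 1e-6)
  expect_error(whiten(X[1, , drop = FALSE]), "2 channels")
  # rank-deficient: duplicated channel is dropped by the tolerance rule
  wh2 <- whiten(rbind(X, X[1, ]))
  expect_equal(nrow(wh2$Z), 2)
})

test_that("joint diagonalization matches the 2x2 eigen oracle", {
  set.seed(12)
  M <- crossprod(matrix(rnorm(4), 2))
  V <- joint_diagonalize(list(M), tol = 1e-12)
  E <- eigen(M, symmetric = TRUE)$vectors
  # same columns up to permutation/sign
  P <- abs(crossprod(V, E))
  expect_lt(abs(max(P[1, ]) - 1), 1e-8)
  expect_lt(abs(max(P[2, ]) - 1), 1e-8)
  expect_true(attr(V, "converged"))
})

test_that("joint diagonalization: identity on diagonal sets, monotone loss", {
  mats <- list(diag(c(1, 2, 3)), diag(c(3, 1, 0.5)))
  V <- joint_diagonalize(mats)
  expect_lt(max(abs(abs(V) - diag(3))), 1e-9)
  set.seed(13)
  R <- qr.Q(qr(matrix(rnorm(25), 5)))
  mats2 <- lapply(1:6, function(k) {
    D <- diag(runif(5))
    S <- R %*% D %*% t(R) + matrix(rnorm(25, 0, 0.02), 5)
    (S + t(S)) / 2
  })
  V2 <- joint_diagonalize(mats2, max_sweeps = 30)
  tr <- attr(V2, "offdiag_trace")
  expect_true(all(diff(tr) <= 1e-12))
  expect_warning(joint_diagonalize(mats2, tol = 0, max_sweeps = 2),
                 "did not converge")
})

test_that("sobi recovers AR sources through a random mixing", {
  set.seed(14)
  n <- 36000  # 60 s at 600 Hz
  s1 <- as.numeric(arima.sim(list(ar = 0.95), n))
  s2 <- as.numeric(arima.sim(list(ar = 0.30), n))
  S <- rbind(s1 / sd(s1), s2 / sd(s2))
  A <- matrix(rnorm(20), 10, 2)
  X <- A %*% S
  X <- X - rowMeans(X)
  dec <- sobi_decompose(X, lags = 0:50)
  cc <- best_corrs(dec$sources, S)
  expect_gte(cc[1], 0.95)
  expect_gte(cc[2], 0.95)
  # demixing applied to data reproduces the sources field
  expect_equal(dec$demixing %*% X, dec$sources, ignore_attr = TRUE)
})

test_that("rank-1 data concentrates in one dominant component", {
  set.seed(15)
  s <- as.numeric(arima.sim(list(ar = 0.9), 8000))
  X <- outer(rep(1, 6), s) + matrix(rnorm(6 * 8000, 0, 1e-3), 6)
  X <- X - rowMeans(X)
  dec <- suppressWarnings(sobi_decompose(X, lags = 0:20))
  v <- apply(dec$sources, 1, var) * colSums(dec$mixing^2)
  expect_gte(v[1] / sum(v), 0.99)
})

test_that("signed-permutation indeterminacy and equivariance", {
  set.seed(16)
  n <- 30000
  phis <- c(0.95, 0.6, 0.2, -0.5)
  S <- do.call(rbind, lapply(phis, function(p) {
    x <- as.numeric(arima.sim(list(ar = p), n)); x / sd(x)
  }))
  A <- matrix(rnorm(40), 10, 4)
  X <- A %*% S + 0.1 * matrix(rnorm(10 * n), 10)   # ~20 dB
  X <- X - rowMeans(X)
  dec <- suppressWarnings(sobi_decompose(X, lags = 0:30))
  G <- dec$demixing %*% A
  # G should be near a signed permutation on the 4 source rows
  rows <- apply(abs(cor(t(dec$sources), t(S))), 2, which.max)
  expect_lt(amari_index(G[rows, ]), 0.1)
  # equivariance: global channel scaling leaves sources unchanged
  dec2 <- suppressWarnings(sobi_decompose(5 * X, lags = 0:30))
  cc <- abs(diag(cor(t(dec2$sources[rows2 <- apply(
    abs(cor(t(dec2$sources), t(S))), 2, which.max), ]),
    t(dec$sources[rows, ]))))
  expect_true(all(cc > 0.999))
})
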