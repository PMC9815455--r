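# Simplified adaptive-mixture ICA: separation, likelihood behaviour,
# Gaussian reductions, cross-model removal.

test_that("a Laplacian pair separates to a signed permutation", {
  set.seed(30)
  n <- 20000
  S <- rbind(sign(rnorm(n)) * rexp(n), sign(rnorm(n)) * rexp(n))
  A <- matrix(c(1, 0.6, -0.4, 1), 2, 2)
  fit <- amica_fit(A %*% S, max_iter = 150, seed = 2)
  W <- fit$models[[1]]$demixing
  expect_lt(amari_index(W %*% A), 0.05)
  # monotone accepted-likelihood trace (EM-style guarantee with slack)
  expect_true(all(diff(fit$loglik) >= -1e-6))
  # mixing is the inverse of demixing
  expect_equal(fit$models[[1]]$mixing %*% W, diag(2), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("Gaussian-only data reduces to whitening / the Gaussian LL", {
  set.seed(31)
  n <- 20000
  A <- matrix(c(1, 0.7, -0.3, 1.2), 2, 2)
  X <- A %*% matrix(rnorm(2 * n), 2)
  X <- X - rowMeans(X)
  # single mixture, shape pinned at 2: updates are Gaussian decorrelation
  fit <- amica_fit(X, n_mix = 1, update_rho = FALSE, rho_init = 2,
                   max_iter = 100, seed = 1)
  W <- fit$models[[1]]$demixing
  SC <- cov(t(W %*% X))
  expect_lt(abs(SC[1, 2]) / sqrt(SC[1, 1] * SC[2, 2]), 0.05)
  expect_equal(diag(SC), c(1, 1), tolerance = 0.05, ignore_attr = TRUE)
  # likelihood matches the analytic Gaussian value within 1% per sample
  ll <- tail(fit$loglik, 1)
  Sig <- tcrossprod(X) / n
  ll_gauss <- -0.5 * (2 * log(2 * pi) + log(det(Sig)) + 2)
  expect_lt(abs(ll - ll_gauss) / abs(ll_gauss), 0.01)
})

test_that("mixtures collapse sensibly and n_mix=3 handles Gaussians", {
  set.seed(32)
  X <- matrix(rnorm(2 * 15000), 2)
  fit <- amica_fit(X, n_mix = 3, max_iter = 120, seed = 5)
  ll <- tail(fit$loglik, 1)
  Sig <- tcrossprod(X - rowMeans(X)) / ncol(X)
  ll_gauss <- -0.5 * (2 * log(2 * pi) + log(det(Sig)) + 2)
  expect_lt(abs(ll - ll_gauss) / abs(ll_gauss), 0.01)
})

test_that("cross-model removal satisfies its algebraic identities", {
  sim <- tiny_sim()
  rec <- demean_pages(sim$recording)
  # two small exactly-invertible surrogate models on the gradiometers
  m <- sum(rec$info$type == "grad")
  set.seed(33)
  W_a <- diag(m) + matrix(rnorm(m * m, 0, 0.05), m)
  W_b <- diag(m) + matrix(rnorm(m * m, 0, 0.05), m)
  mod_a <- list(demixing = W_a, mixing = solve(W_a))
  mod_b <- list(demixing = W_b, mixing = solve(W_b))
  # empty index sets: identity to machine precision
  out <- cross_model_remove(mod_a, mod_b, rec, integer(0), integer(0))
  g <- rec$info$type == "grad"
  rel <- max(abs(out$data[g, ] - rec$data[g, ])) / max(abs(rec$data[g, ]))
  expect_lt(rel, 1e-8)
  # model B = model A equals single-model removal of the union set
  dec_a <- decomposition(mixing = solve(W_a), demixing = W_a,
                         sources = W_a %*% rec$data[g, ],
                         method = "amica",
                         channel_names = rec$info$name[g],
                         scale = method_scale("amica"))
  idx <- c(2L, 5L)
  out2 <- cross_model_remove(mod_a, mod_a, rec, idx, idx)
  out3 <- remove_components(dec_a, rec, idx)
  expect_equal(out2$data[g, ], out3$data[g, ], tolerance = 1e-10)
  expect_error(cross_model_remove(mod_a, mod_b, rec, m + 1L, integer(0)),
               "out of range")
})

test_that("model escalation produces several usable models", {
  set.seed(34)
  n <- 12000
  S <- rbind(sign(rnorm(n)) * rexp(n), runif(n, -1, 1))
  A <- matrix(c(1, 0.4, -0.5, 1), 2, 2)
  fit <- amica_fit(A %*% S, n_models = 3, max_iter = 80, seed = 6)
  expect_length(fit$models, 3)
  expect_equal(sum(vapply(fit$models, `[[`, 1, "alpha")), 1,
               tolerance = 1e-6)
  expect_true(all(diff(fit$loglik) >= -1e-6))
  # every model's demixing separates the pair (same stationary data)
  for (h in 1:3)
    expect_lt(amari_index(fit$models[[h]]$demixing %*% A), 0.2)
})
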