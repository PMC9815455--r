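# Second-Order Blind Identification: whitening followed by orthogonal
# joint approximate diagonalization of lagged covariance matrices, with
# EOG-autocorrelation-driven lag selection.

#' Select SOBI time lags from the horizontal EOG
#'
#' Returns the union of the base lag interval `{0, ..., base_max}` and all
#' lags up to `search_max` at which the biased sample autocorrelation of
#' the demeaned horizontal EOG reaches `acf_threshold` -- the periodic
#' line-return structure of reading shows up as autocorrelation rebounds at
#' high lags, and those lags carry the saccade information.
#'
#' @param heog Horizontal EOG sample sequence.
#' @param base_max Largest lag of the always-included base interval
#'   (samples). Default 150.
#' @param acf_threshold Autocorrelation inclusion threshold. Default 0.3.
#' @param search_max Largest lag searched beyond the base interval
#'   (samples). Default 1200 (2 s at 600 Hz).
#' @return Integer vector of lags (sorted, unique), capped below
#'   `length(heog) / 3`.
#' @export
select_lags <- function(heog, base_max = 150, acf_threshold = 0.3,
                        search_max = 1200) {
  if (length(heog) <= search_max)
    stop("heog must be longer than search_max")
  if (sd(heog) == 0)
    stop("constant horizontal EOG: autocorrelation undefined")
  a <- as.numeric(acf(heog - mean(heog), lag.max = search_max,
                      type = "correlation", demean = FALSE,
                      plot = FALSE)$acf)
  extra <- which(a >= acf_threshold) - 1L      # acf[1] is lag 0
  lags <- sort(unique(c(0:base_max, extra)))
  lags[lags < length(heog) / 3]
}

#' Whiten multichannel data
#'
#' Eigenvalue whitening of the zero-lag covariance with tolerance-based
#' rank truncation: components with relative eigenvalue below `rank_tol`
#' are dropped, the remaining dimensions are scaled to unit variance.
#'
#' @param X Channels x samples matrix (assumed demeaned).
#' @param rank_tol Relative eigenvalue threshold for dimension dropping.
#' @return List with `Z` (whitened data, k x samples), `whitener` (k x m),
#'   `dewhitener` (m x k); `t(whitener)` and `dewhitener` satisfy
#'   `whitener %*% dewhitener = I_k`.
#' @export
whiten <- function(X, rank_tol = 1e-10) {
  if (nrow(X) < 2) stop("whitening requires at least 2 channels")
  C <- tcrossprod(X) / ncol(X)
  e <- eigen(C, symmetric = TRUE)
  keep <- e$values > rank_tol * e$values[1]
  if (sum(keep) < 2)
    stop("covariance is rank deficient beyond repair (rank < 2)")
  d <- e$values[keep]
  U <- e$vectors[, keep, drop = FALSE]
  K <- diag(1 / sqrt(d), length(d)) %*% t(U)
  list(Z = K %*% X, whitener = K,
       dewhitener = U %*% diag(sqrt(d), length(d)))
}

#' Orthogonal joint approximate diagonalization
#'
#' Jacobi-like iterative Givens rotations minimizing the summed squared
#' off-diagonal elements of a set of symmetric matrices; a sweep visits
#' every index pair and the algorithm stops when every rotation angle in a
#' sweep falls below `tol`.
#'
#' @param matrices List of symmetric n x n matrices (symmetrized here as
#'   `(R + t(R)) / 2` for safety).
#' @param tol Rotation-angle (sine) convergence threshold.
#' @param max_sweeps Sweep cap; exceeding it yields a warning-carrying
#'   result, not a failure.
#' @return Orthogonal n x n rotation matrix `V` (columns are the joint
#'   eigenvectors) with attributes `sweeps`, `converged` and
#'   `offdiag_trace` (summed squared off-diagonals before each sweep).
#' @export
joint_diagonalize <- function(matrices, tol = 1e-9, max_sweeps = 100) {
  stopifnot(length(matrices) >= 1)
  n <- nrow(matrices[[1]])
  M <- array(0, dim = c(n, n, length(matrices)))
  for (k in seq_along(matrices))
    M[, , k] <- (matrices[[k]] + t(matrices[[k]])) / 2
  res <- jointdiag_cpp(M, tol = tol, max_sweeps = max_sweeps)
  if (!res$converged)
    warning("joint diagonalization did not converge in ", max_sweeps,
            " sweeps")
  structure(res$rotation, sweeps = res$sweeps, converged = res$converged,
            offdiag_trace = res$offdiag_trace)
}

# symmetrized lagged covariance of whitened data
lagged_cov <- function(Z, tau) {
  Tn <- ncol(Z)
  if (tau == 0) return(tcrossprod(Z) / Tn)
  C <- tcrossprod(Z[, 1:(Tn - tau), drop = FALSE],
                  Z[, (tau + 1):Tn, drop = FALSE]) / (Tn - tau)
  (C + t(C)) / 2
}

#' SOBI decomposition
#'
#' Whitening, symmetrized lagged covariances at the requested lag set,
#' joint diagonalization; then `W = t(V) %*% whitener`,
#' `A = dewhitener %*% V`, `sources = W %*% data`.  Components are ordered
#' by decreasing captured variance.
#'
#' @param rec A `meg_recording` (demeaned, concatenated; only gradiometer
#'   channels are used) or a plain channels x samples matrix.
#' @param lags Integer lag vector, e.g. from [select_lags()]. Default
#'   `0:150`.
#' @param rank_tol Passed to [whiten()].
#' @param tol,max_sweeps Passed to [joint_diagonalize()]; the default tol
#'   `NULL` uses the canonical sample-size-driven rotation threshold
#'   `1 / (100 * sqrt(n_samples))`.
#' @return A [decomposition()] with method `"sobi"`; `extras` records the
#'   lags and diagonalization diagnostics.
#' @export
sobi_decompose <- function(rec, lags = 0:150, rank_tol = 1e-10,
                           tol = NULL, max_sweeps = 100) {
  X <- decomposition_input(rec)
  if (is.null(tol)) tol <- 1 / (100 * sqrt(ncol(X$data)))
  lags <- sort(unique(as.integer(lags)))
  stopifnot(all(lags >= 0), max(lags) < ncol(X$data) / 3)
  wh <- whiten(X$data, rank_tol)
  mats <- lapply(lags, function(tau) lagged_cov(wh$Z, tau))
  V <- joint_diagonalize(mats, tol = tol, max_sweeps = max_sweeps)
  W <- t(V) %*% wh$whitener
  A <- wh$dewhitener %*% V
  S <- W %*% X$data
  ord <- order(colSums(A^2) * apply(S, 1, var), decreasing = TRUE)
  decomposition(mixing = A[, ord, drop = FALSE],
                demixing = W[ord, , drop = FALSE],
                sources = S[ord, , drop = FALSE],
                method = "sobi", channel_names = X$names, scale = X$scale,
                extras = list(lags = lags,
                              sweeps = attr(V, "sweeps"),
                              converged = attr(V, "converged")))
}

# shared input handling: decompositions see gradiometer data only
decomposition_input <- function(rec) {
  if (inherits(rec, "meg_recording")) {
    g <- grads_only(rec)
    list(data = g$data, names = g$info$name, scale = g$scale)
  } else {
    stopifnot(is.matrix(rec))
    list(data = rec,
         names = if (!is.null(rownames(rec))) rownames(rec)
                 else sprintf("ch%03d", seq_len(nrow(rec))),
         scale = 1)
  }
}
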