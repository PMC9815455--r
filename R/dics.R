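# Frequency-domain beamformer evaluation (DICS): band cross-spectral
# densities, a common filter built from the averaged CSD with a
# rank-limited pseudoinverse, condition-specific source power, normalized
# reduction maps, geometric parcellation and group t-tests.

#' Welch cross-spectral density in a frequency band
#'
#' Hann-windowed segments with overlap; the CSD is the cross-periodogram
#' averaged across segments and the band's frequency bins.  Restricted to
#' the reading page spans by default (pass `spans` to override).
#'
#' @param rec A `meg_recording` (gradiometer channels are used) or a
#'   channels x samples matrix (then `sfreq` must be given).
#' @param band Numeric `c(f_lo, f_hi)` in Hz; must lie below Nyquist.
#' @param seg_len Segment length (s). Default 1.
#' @param overlap Fractional segment overlap. Default 0.5.
#' @param spans Optional page-span matrix restricting the data.
#' @param sfreq Sampling rate when `rec` is a bare matrix.
#' @return Object of class `csd`: `band`, `matrix` (complex Hermitian),
#'   `rank` (eigenvalues above `1e-10 * max`), `n_segments`, `channels`.
#' @export
compute_csd <- function(rec, band, seg_len = 1, overlap = 0.5,
                        spans = NULL, sfreq = NULL) {
  if (inherits(rec, "meg_recording")) {
    g <- grads_only(rec)
    X <- g$data
    sfreq <- rec$sfreq
    chn <- g$info$name
    if (!is.null(spans)) {
      idx <- unlist(apply(spans, 1, function(s) s[1]:(s[2] - 1L),
                          simplify = FALSE))
      X <- X[, idx, drop = FALSE]
    }
  } else {
    X <- rec
    if (is.null(sfreq)) stop("sfreq required for matrix input")
    chn <- rownames(X)
  }
  nyq <- sfreq / 2
  if (band[2] > nyq) stop("band extends above the Nyquist frequency")
  nseg <- round(seg_len * sfreq)
  step <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1L, ncol(X) - nseg + 1L, by = step)
  if (!length(starts)) stop("data shorter than one segment")
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))
  freqs <- (seq_len(nseg) - 1) * sfreq / nseg
  bins <- which(freqs >= band[1] & freqs <= band[2] & freqs > 0)
  if (!length(bins)) stop("band contains no frequency bin at this segment length")
  m <- nrow(X)
  C <- matrix(0 + 0i, m, m)
  u <- sum(win^2)
  for (s0 in starts) {
    seg <- X[, s0:(s0 + nseg - 1L), drop = FALSE]
    seg <- seg - rowMeans(seg)
    F <- mvfft(t(seg * rep(win, each = m)))       # freq x channels
    Fb <- F[bins, , drop = FALSE]
    C <- C + crossprod(Conj(Fb), Fb)              # sum_b f_b f_b^H
  }
  C <- C / (length(starts) * length(bins) * u * sfreq)
  C <- (C + Conj(t(C))) / 2
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  structure(list(band = band, matrix = C,
                 rank = sum(ev > 1e-10 * max(ev)),
                 n_segments = length(starts), channels = chn),
            class = "csd")
}

#' @export
print.csd <- function(x, ...) {
  cat(sprintf("<csd> band %g-%g Hz, %d channels, rank %d, %d segments\n",
              x$band[1], x$band[2], nrow(x$matrix), x$rank, x$n_segments))
  invisible(x)
}

# truncated pseudoinverse of a Hermitian PSD matrix (k leading eigenvalues)
hermitian_pinv <- function(C, k) {
  e <- eigen(C, symmetric = TRUE)
  k <- min(k, sum(e$values > 0))
  if (k == 0) stop("rank rule yields k = 0; cannot build the filter")
  V <- e$vectors[, seq_len(k), drop = FALSE]
  V %*% diag(1 / e$values[seq_len(k)], k) %*% Conj(t(V))
}

#' Common DICS beamformer filter
#'
#' Weights are computed from the cross-spectral density averaged across the
#' uncleaned and the two cleaned conditions so that all conditions are
#' mapped through the same spatial filter.  The pseudoinverse is truncated
#' to the smaller of the two cleaned conditions' ranks (removing components
#' lowers the data rank; using more singular values than the lowest-ranked
#' condition supports would inflate its noise).  Per grid point the source
#' orientation is the tangential direction maximizing output power (the
#' minimum-eigenvalue eigenvector of `Re(L' C+ L)`), and the weights are
#' the unit-gain minimum-variance solution
#' `w = (l' C+ l)^(-1) l' C+` for the oriented leadfield `l`.
#'
#' @param csd_uncleaned,csd_p1,csd_p2 [compute_csd()] results on identical
#'   channels and band.
#' @param grid A [make_forward_grid()].
#' @param rank_rule `"min_cleaned"` (default) or an explicit integer rank.
#' @return Object of class `dics_filter`: `weights` (points x channels,
#'   complex), `orientation` (points x 3), `band`, `channels`.
#' @export
common_filter <- function(csd_uncleaned, csd_p1, csd_p2, grid,
                          rank_rule = "min_cleaned") {
  stopifnot(identical(csd_uncleaned$channels, csd_p1$channels),
            identical(csd_p1$channels, csd_p2$channels),
            identical(csd_uncleaned$band, csd_p1$band))
  C_avg <- (csd_uncleaned$matrix + csd_p1$matrix + csd_p2$matrix) / 3
  k <- if (identical(rank_rule, "min_cleaned")) {
    min(csd_p1$rank, csd_p2$rank)
  } else as.integer(rank_rule)
  Cp <- hermitian_pinv(C_avg, k)
  np <- dim(grid$leadfield)[3]
  m <- dim(grid$leadfield)[1]
  W <- matrix(0 + 0i, np, m)
  ori <- matrix(0, np, 3)
  for (i in seq_len(np)) {
    tb <- tangential_basis(grid$points[i, ])
    L <- grid$leadfield[, , i] %*% t(tb)          # m x 2
    M2 <- Re(Conj(t(L)) %*% Cp %*% L)
    e <- eigen((M2 + t(M2)) / 2, symmetric = TRUE)
    u <- e$vectors[, 2]                           # min-eigenvalue direction
    ori[i, ] <- drop(t(tb) %*% u)
    l <- drop(L %*% u)
    lCl <- Re(drop(Conj(l) %*% Cp %*% l))
    W[i, ] <- drop(Conj(l) %*% Cp) / lCl
  }
  structure(list(weights = W, orientation = ori, band = csd_uncleaned$band,
                 channels = csd_uncleaned$channels, rank_used = k),
            class = "dics_filter")
}

#' Source power of a condition through a common filter
#'
#' Applies the common-filter weights to the condition's full-rank CSD:
#' `power(point) = Re(w C w^H)`.
#'
#' @param filter A [common_filter()] result.
#' @param csd_condition A [compute_csd()] on the same channels.
#' @param condition Condition tag stored with the map.
#' @return Object of class `power_map`: data frame `point`, `power`, with
#'   attributes `band` and `condition`.
#' @export
source_power <- function(filter, csd_condition, condition = "unknown") {
  if (!identical(filter$channels, csd_condition$channels))
    stop("channel mismatch between filter and CSD")
  C <- csd_condition$matrix
  WC <- filter$weights %*% C
  p <- Re(rowSums(WC * Conj(filter$weights)))
  structure(data.frame(point = seq_len(nrow(filter$weights)), power = p),
            class = c("power_map", "data.frame"),
            band = filter$band, condition = condition)
}

#' Normalized power-reduction and pipeline-difference maps
#'
#' `red_p = (P_unclean - P_p) / P_unclean` per pipeline, and the pipeline
#' difference `(reduction_1 - reduction_2) / (power reduced by pipeline 2)`
#' i.e. `((P_u - P_1) - (P_u - P_2)) / (P_u - P_2)`.  Negative reductions
#' are preserved (the beamformer may erroneously estimate an increase);
#' divisions with magnitude below `eps` are flagged and set `NA`.
#'
#' @param map_unclean,map_p1,map_p2 [source_power()] maps on the same grid.
#' @param eps Division guard; default `1e-12 * median(P_unclean)`.
#' @return List with `reduction_p1`, `reduction_p2`, `difference` (numeric
#'   vectors over points) and `guarded` (logical).
#' @export
reduction_maps <- function(map_unclean, map_p1, map_p2, eps = NULL) {
  pu <- map_unclean$power; p1 <- map_p1$power; p2 <- map_p2$power
  if (is.null(eps)) eps <- 1e-12 * median(pu)
  g1 <- abs(pu) <= eps
  red1 <- ifelse(g1, NA_real_, (pu - p1) / pu)
  red2 <- ifelse(g1, NA_real_, (pu - p2) / pu)
  den <- pu - p2
  g2 <- abs(den) <= eps
  diff_ <- ifelse(g2, NA_real_, ((pu - p1) - (pu - p2)) / den)
  list(reduction_p1 = red1, reduction_p2 = red2, difference = diff_,
       guarded = g1 | g2)
}

#' Geometric parcellation of a source grid
#'
#' Deterministic partition into labelled sectors (hemisphere x
#' anterior/central/posterior x superior/inferior, plus an eye-region
#' parcel), a stand-in for an anatomical atlas on the spherical grid.
#'
#' @param grid A [make_forward_grid()].
#' @return Factor of parcel labels, one per grid point.
#' @export
default_parcellation <- function(grid) {
  p <- grid$points
  hemi <- ifelse(p[, 1] < 0, "left", "right")
  ap <- cut(p[, 2], breaks = c(-Inf, -0.02, 0.02, Inf),
            labels = c("posterior", "central", "anterior"))
  si <- ifelse(p[, 3] >= 0, "superior", "inferior")
  lab <- paste(hemi, ap, si)
  lab[grid$in_eye_region] <- "eye region"
  factor(lab)
}

#' Parcel aggregation and group t-tests of pipeline differences
#'
#' Per grid point and band, a two-sided one-sample t-test of the
#' between-pipeline normalized reduction difference across subjects against
#' zero at the uncorrected threshold `alpha` (deliberately no
#' multiple-comparison correction -- the aim is consistent large
#' differences, not significance per se).  Parcel means are reported for
#' parcels containing significant points, and parcel-band combinations
#' whose absolute group mean difference exceeds `diff_threshold` are
#' listed.
#'
#' @param diff_maps Named list (one entry per band) of points x subjects
#'   matrices of difference values (e.g. `reduction_maps()$difference`).
#' @param parcellation Factor of parcel labels per point.
#' @param alpha Uncorrected significance level. Default 0.005.
#' @param diff_threshold Group-mean selection threshold. Default 0.05.
#' @return List with `point_tests` (data frame: band, point, t, p,
#'   significant), `parcel_table` (band x parcel group means for parcels
#'   containing significant points), `selected` (parcel-band combinations
#'   exceeding `diff_threshold`).
#' @export
parcel_and_test <- function(diff_maps, parcellation, alpha = 0.005,
                            diff_threshold = 0.05) {
  stopifnot(length(diff_maps) >= 1)
  ns <- ncol(diff_maps[[1]])
  if (ns < 3) stop("at least 3 subjects required")
  pt_rows <- list(); parcel_rows <- list(); sel_rows <- list()
  for (b in names(diff_maps)) {
    Mx <- diff_maps[[b]]
    mu <- rowMeans(Mx)
    sdv <- apply(Mx, 1, sd)
    tstat <- mu / (sdv / sqrt(ns))
    pval <- 2 * pt(abs(tstat), df = ns - 1, lower.tail = FALSE)
    pval[!is.finite(tstat)] <- NA
    sig <- !is.na(pval) & pval < alpha
    pt_rows[[b]] <- data.frame(band = b, point = seq_along(mu), t = tstat,
                               p = pval, significant = sig)
    if (length(parcellation) != nrow(Mx))
      stop("parcellation length does not match map points")
    for (pc in levels(parcellation)) {
      in_pc <- parcellation == pc
      if (!any(in_pc & sig)) next
      gm <- mean(mu[in_pc], na.rm = TRUE)
      parcel_rows[[length(parcel_rows) + 1L]] <-
        data.frame(band = b, parcel = pc, mean_difference = gm,
                   n_significant = sum(in_pc & sig))
      if (is.finite(gm) && abs(gm) > diff_threshold)
        sel_rows[[length(sel_rows) + 1L]] <-
          data.frame(band = b, parcel = pc, mean_difference = gm)
    }
  }
  list(point_tests = do.call(rbind, pt_rows),
       parcel_table = if (length(parcel_rows)) do.call(rbind, parcel_rows)
                      else NULL,
       selected = if (length(sel_rows)) do.call(rbind, sel_rows) else NULL)
}

#' Evaluate both pipelines' power reduction with DICS
#'
#' Convenience wrapper: per band, CSDs of the uncleaned and two cleaned
#' recordings, common filter, condition powers and reduction maps.
#'
#' @param rec_raw,rec_p1,rec_p2 Recordings on the same channels.
#' @param grid A [make_forward_grid()].
#' @param bands Named list of bands; default [ocubss_bands()].
#' @param seg_len,overlap Passed to [compute_csd()].
#' @return Named list per band with `power` (3-column matrix), `maps`
#'   (from [reduction_maps()]) and `filter_rank`.
#' @export
dics_evaluate <- function(rec_raw, rec_p1, rec_p2, grid,
                          bands = ocubss_bands(), seg_len = 1,
                          overlap = 0.5) {
  out <- list()
  for (b in names(bands)) {
    cu <- compute_csd(rec_raw, bands[[b]], seg_len, overlap)
    c1 <- compute_csd(rec_p1, bands[[b]], seg_len, overlap)
    c2 <- compute_csd(rec_p2, bands[[b]], seg_len, overlap)
    fl <- common_filter(cu, c1, c2, grid)
    pu <- source_power(fl, cu, "uncleaned")
    p1 <- source_power(fl, c1, "pipeline1")
    p2 <- source_power(fl, c2, "pipeline2")
    out[[b]] <- list(power = cbind(uncleaned = pu$power,
                                   pipeline1 = p1$power,
                                   pipeline2 = p2$power),
                     maps = reduction_maps(pu, p1, p2),
                     filter_rank = fl$rank_used)
  }
  out
}
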