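# Automated artifact-component identification: time-series features,
# gradiometer-pair RMS topographies, leadfield-correlation localization
# with an eye-region fraction, EOG correlation, and a rule-based
# classifier with a manual-override hook.  The thresholds are
# implementation choices (the original selection was expert visual
# judgement) and are all exposed.

#' Classification thresholds
#'
#' @param r_eog Minimum absolute EOG correlation. Default 0.6.
#' @param eye_fraction Minimum share of top-ranked localization points in
#'   the eye region. Default 0.5.
#' @param kurtosis Minimum excess-free kurtosis for blink components.
#'   Default 5.
#' @param sawtooth Minimum sawtooth template correlation. Default 0.6.
#' @param spike_rate Plausible blink-spike rate range (events/s) used when
#'   no marker count is supplied.
#' @return Named list of thresholds.
#' @export
identify_thresholds <- function(r_eog = 0.6, eye_fraction = 0.5,
                                kurtosis = 5, sawtooth = 0.6,
                                spike_rate = c(0.03, 2)) {
  list(r_eog = r_eog, eye_fraction = eye_fraction, kurtosis = kurtosis,
       sawtooth = sawtooth, spike_rate = spike_rate)
}

#' Gradiometer-pair RMS topography
#'
#' Per-site root mean square of the mixing weights of the two orthogonal
#' gradiometers, the standard display convention for planar-gradiometer
#' component topographies.
#'
#' @param topography Mixing column over gradiometer channels.
#' @param sensors A [sensor_layout()].
#' @return Numeric vector of length `n_sites`.
#' @export
site_rms_topography <- function(topography, sensors) {
  w1 <- topography[sensors$channel_ori == 1L]
  w2 <- topography[sensors$channel_ori == 2L]
  sqrt((w1^2 + w2^2) / 2)
}

#' Leadfield-correlation localization of a component
#'
#' For every grid point the Pearson correlation between the component's
#' sensor weights and the point's leadfield is maximized over tangential
#' dipole orientations (closed form via a 2 x 2 solve; the maximization
#' makes the topography sign irrelevant).  Points are ranked by
#' correlation, the `top_k` best returned, and the eye fraction is the
#' share of those lying within 2 cm of either eye.
#'
#' @param topography Sensor weight vector (gradiometer channels, matching
#'   `grid$sensors`).
#' @param grid A [make_forward_grid()].
#' @param top_k Number of top-ranked points retained. Default 500.
#' @return List with `ranking` (data frame: point index, correlation,
#'   in_eye_region, sorted descending), `eye_fraction`, `correlations`
#'   (full vector).
#' @export
localize_component <- function(topography, grid, top_k = 500) {
  if (sd(topography) == 0) stop("zero-variance topography")
  np <- dim(grid$leadfield)[3]
  tc <- topography - mean(topography)
  nt <- sqrt(sum(tc^2))
  # a = M' tc for every point at once; corr^2 = a' B^-1 a / |tc|^2
  a <- drop(crossprod(grid$tan_leadfield, tc))
  a1 <- a[seq(1, 2 * np, by = 2)]
  a2 <- a[seq(2, 2 * np, by = 2)]
  b11 <- grid$gram_inv[1, 1, ]; b12 <- grid$gram_inv[1, 2, ]
  b22 <- grid$gram_inv[2, 2, ]
  val <- a1 * a1 * b11 + 2 * a1 * a2 * b12 + a2 * a2 * b22
  cors <- sqrt(pmax(val, 0)) / nt
  ord <- order(cors, decreasing = TRUE)
  top <- head(ord, top_k)
  ranking <- data.frame(point = top, correlation = cors[top],
                        in_eye_region = grid$in_eye_region[top])
  list(ranking = ranking, eye_fraction = mean(ranking$in_eye_region),
       correlations = cors)
}

#' Pearson correlation of a component with the EOG channels
#'
#' @param component Component time course.
#' @param heog,veog EOG sample sequences of the same length.
#' @param segments Optional logical mask (or index vector) restricting the
#'   calculation to artifact-containing segments known from the eye
#'   tracker.
#' @return Named vector `c(r_h, r_v)`.
#' @export
eog_correlation <- function(component, heog, veog, segments = NULL) {
  if (!is.null(segments)) {
    component <- component[segments]
    heog <- heog[segments]
    veog <- veog[segments]
  }
  if (sd(component) == 0 || sd(heog) == 0 || sd(veog) == 0)
    stop("zero-variance input to EOG correlation")
  c(r_h = cor(component, heog), r_v = cor(component, veog))
}

#' Sawtooth (reading-ramp) score of a component time course
#'
#' Reading saccade components rise steadily along a line and return with a
#' sharp descent at every line sweep.  The score fits the component with
#' its own asymmetric-ramp template: reset events are detected as
#' dominant-sign outliers of the first difference, a piecewise-linear ramp
#' running between consecutive resets is built, and the score is the
#' absolute correlation of component and template over the covered span.
#'
#' Reset events are full-range jumps within a short window (a line sweep
#' traverses most of the component's range in tens of milliseconds,
#' whereas individual forward saccades move only a fraction of it), with
#' the dominant jump direction chosen by the largest single event.
#'
#' @param component Component time course.
#' @param sfreq Sampling rate (Hz).
#' @param window Jump-detection window (s). Default 0.06, a bit above a
#'   return-sweep duration.
#' @param frac Fraction of the robust amplitude range (5th-95th
#'   percentile) a windowed jump must exceed to count as a reset.
#' @return Score in `[0, 1]` (0 when fewer than 3 resets are found).
#' @export
sawtooth_score <- function(component, sfreq, window = 0.06, frac = 0.5) {
  n <- length(component)
  w <- max(2L, round(window * sfreq))
  if (n <= 3L * w) return(0)
  d <- component[(w + 1L):n] - component[1L:(n - w)]
  rng <- diff(quantile(component, c(0.05, 0.95)))
  if (rng <= 0) return(0)
  thr <- frac * rng
  dn <- which(d < -thr); up <- which(d > thr)
  if (!length(dn) && !length(up)) return(0)
  take_dn <- max(c(-d[dn], 0)) >= max(c(d[up], 0))
  hits <- if (take_dn) dn else up
  if (length(hits) < 3) return(0)
  # one reset per detection run: keep the extremal sample
  grp <- cumsum(c(1L, diff(hits) > 0.15 * sfreq))
  resets <- vapply(split(hits, grp),
                   function(ix) ix[which.max(abs(d[ix]))], numeric(1))
  resets <- sort(as.integer(resets + w %/% 2L))
  if (length(resets) < 3) return(0)
  template <- numeric(n)
  for (j in seq_len(length(resets) - 1L)) {
    a <- resets[j] + 1L; b <- resets[j + 1L]
    template[a:b] <- seq(-0.5, 0.5, length.out = b - a + 1L)
  }
  if (take_dn) template <- template else template <- -template
  span <- (resets[1] + 1L):resets[length(resets)]
  abs(cor(component[span], template[span]))
}

#' Spike rate of a component time course
#'
#' Counts robust-z outlier peaks (|z| > `z_thresh`) separated by at least
#' `min_sep` seconds; blink components show spikes at the blink rate.
#'
#' @param component Component time course.
#' @param sfreq Sampling rate (Hz).
#' @param z_thresh Robust z threshold. Default 4.
#' @param min_sep Minimum peak separation (s). Default 0.25.
#' @return List with `rate` (events/s) and `count`.
#' @export
spike_rate <- function(component, sfreq, z_thresh = 4, min_sep = 0.25) {
  s <- mad(component)
  if (s == 0) return(list(rate = 0, count = 0L))
  z <- abs(component - median(component)) / s
  hits <- which(z > z_thresh)
  if (!length(hits)) return(list(rate = 0, count = 0L))
  starts <- hits[c(TRUE, diff(hits) > min_sep * sfreq)]
  list(rate = length(starts) / (length(component) / sfreq),
       count = length(starts))
}

#' Classify a component from its features
#'
#' Rule: blink when the spike count matches the blink markers, `|r_v|`
#' passes, the kurtosis passes and the eye fraction passes; saccade when
#' the component is not blink-like, its eye fraction passes, and it shows
#' gaze-locked structure (sawtooth score passing, or either EOG
#' correlation passing) -- this catches both the horizontal ramp and the
#' vertical page-staircase components of reading gaze, with the
#' localization eye fraction as the load-bearing ocular criterion;
#' otherwise other.  Blink-shaped components that fail the eye-region
#' test are labelled other and flagged for manual review (they typically
#' originate posterior to the eyes and are mixtures).
#'
#' @param features Named list with `sawtooth`, `r_h`, `r_v`, `eye_fraction`,
#'   `kurtosis`, `spike_count`, `duration_s`.
#' @param thresholds From [identify_thresholds()].
#' @param blink_n Optional true blink-marker count for the spike-match
#'   test; when absent a plausible rate range is used.
#' @return List with `label` (`"saccade"`, `"blink"` or `"other"`) and
#'   `review` (logical manual-review flag).
#' @export
classify_component <- function(features, thresholds = identify_thresholds(),
                               blink_n = NULL) {
  th <- thresholds
  spikes_match <- if (!is.null(blink_n) && blink_n > 0) {
    features$spike_count >= 0.5 * blink_n &&
      features$spike_count <= 2 * blink_n
  } else {
    rate <- features$spike_count / features$duration_s
    rate >= th$spike_rate[1] && rate <= th$spike_rate[2]
  }
  blinkish <- spikes_match && abs(features$r_v) >= th$r_eog &&
    features$kurtosis >= th$kurtosis
  blink <- blinkish && features$eye_fraction >= th$eye_fraction
  gaze_locked <- features$sawtooth >= th$sawtooth ||
    abs(features$r_h) >= th$r_eog || abs(features$r_v) >= th$r_eog
  sac <- !blinkish && features$eye_fraction >= th$eye_fraction &&
    gaze_locked
  label <- if (blink) "blink" else if (sac) "saccade" else "other"
  list(label = label, review = blinkish && !blink)
}

kurtosis_ <- function(x) {
  m <- mean(x); s <- sd(x)
  if (s == 0) return(0)
  mean((x - m)^4) / s^4
}

#' Identify artifact components of a decomposition
#'
#' Computes the feature set of every component (kurtosis, EOG correlations,
#' sawtooth score, spike rate, site-RMS topography, leadfield-correlation
#' localization with eye fraction), classifies each with
#' [classify_component()], and tags the highest-scoring component per
#' artifact type as primary (multiple components per artifact are allowed).
#'
#' @param dec A [decomposition()] whose channels are the gradiometers of
#'   `rec`.
#' @param rec The `meg_recording` carrying the EOG/eye-tracker channels.
#' @param grid A [make_forward_grid()] (or `NULL` to skip localization; the
#'   eye-fraction criterion then always fails and everything is "other").
#' @param thresholds From [identify_thresholds()].
#' @param top_k Localization points retained. Default 500.
#' @param override Optional named list mapping component index (as
#'   character) to a forced label -- the manual-override hook.
#' @return Object of class `component_report`: data frame with one row per
#'   component (index, label, primary, review and all feature scores), plus
#'   attributes `topographies` (site-RMS matrix) and `localizations`.
#' @export
identify_components <- function(dec, rec, grid,
                                thresholds = identify_thresholds(),
                                top_k = 500, override = NULL) {
  heog <- get_channel(rec, "EOG_H")
  veog <- get_channel(rec, "EOG_V")
  markers <- tryCatch(blink_onsets(rec), error = function(e) integer(0))
  blink_n <- if (length(markers)) length(markers) else NULL
  nc <- n_components(dec)
  dur <- ncol(dec$sources) / rec$sfreq
  sensors <- rec$sensors
  topo_rms <- NULL
  locs <- vector("list", nc)

  rows <- lapply(seq_len(nc), function(i) {
    comp <- dec$sources[i, ]
    rr <- eog_correlation(comp, heog, veog)
    feats <- list(
      kurtosis = kurtosis_(comp),
      r_h = rr[["r_h"]], r_v = rr[["r_v"]],
      sawtooth = sawtooth_score(comp, rec$sfreq),
      spike_count = spike_rate(comp, rec$sfreq)$count,
      duration_s = dur, eye_fraction = 0)
    if (!is.null(grid)) {
      loc <- localize_component(dec$mixing[, i], grid, top_k = top_k)
      locs[[i]] <<- loc
      feats$eye_fraction <- loc$eye_fraction
    }
    cl <- classify_component(feats, thresholds, blink_n)
    data.frame(component = i, label = cl$label, review = cl$review,
               kurtosis = feats$kurtosis, r_h = feats$r_h, r_v = feats$r_v,
               sawtooth = feats$sawtooth, spike_count = feats$spike_count,
               eye_fraction = feats$eye_fraction)
  })
  rep_df <- do.call(rbind, rows)

  if (!is.null(override)) {
    for (nm in names(override))
      rep_df$label[rep_df$component == as.integer(nm)] <- override[[nm]]
  }

  # primary component per artifact type: highest combined score
  rep_df$primary <- FALSE
  for (lab in c("saccade", "blink")) {
    idx <- which(rep_df$label == lab)
    if (length(idx)) {
      score <- if (lab == "saccade") {
        abs(rep_df$r_h[idx]) + rep_df$sawtooth[idx]
      } else {
        abs(rep_df$r_v[idx]) + pmin(rep_df$kurtosis[idx] / 20, 1)
      }
      rep_df$primary[idx[which.max(score)]] <- TRUE
    }
  }

  if (!is.null(sensors))
    topo_rms <- apply(dec$mixing, 2, site_rms_topography, sensors = sensors)
  structure(rep_df, class = c("component_report", "data.frame"),
            topographies = topo_rms, localizations = locs)
}

#' Component indices carrying a given artifact label
#' @param report A [identify_components()] result.
#' @param label `"saccade"` or `"blink"`.
#' @param primary_only Return only the primary component.
#' @return Integer vector (possibly empty).
#' @export
labelled_components <- function(report, label, primary_only = FALSE) {
  sel <- report$label == label
  if (primary_only) sel <- sel & report$primary
  report$component[sel]
}
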