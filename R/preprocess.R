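# Data handling ahead of the decompositions: per-page demeaning,
# concatenation, method-specific scaling, blink-page enrichment.

#' Method-specific data scale factors
#'
#' Fixed-point ICA and adaptive-mixture ICA cannot directly process numbers
#' as small as physical gradiometer values, so the data are multiplied by
#' 1e10 (fastica) or 1e8 (amica) before estimation and the results rescaled
#' afterwards; SOBI runs at the native scale (factor 1).
#'
#' @param method One of `"fastica"`, `"amica"`, `"sobi"`.
#' @return Dimensionless multiplier.
#' @export
method_scale <- function(method = c("fastica", "amica", "sobi")) {
  switch(match.arg(method), fastica = 1e10, amica = 1e8, sobi = 1)
}

#' Apply or undo a method scale on a recording
#'
#' The factor is carried as metadata (`rec$scale`) so that rescaling back
#' to the original physical scale is automatic and exact.
#'
#' @param rec A `meg_recording`.
#' @param method Method name passed to [method_scale()], or a numeric
#'   factor.
#' @return The scaled recording (with `scale` updated).
#' @export
scale_recording <- function(rec, method) {
  f <- if (is.numeric(method)) method else method_scale(method)
  rec$data <- rec$data * f
  rec$scale <- rec$scale * f
  rec
}

#' @rdname scale_recording
#' @export
unscale_recording <- function(rec) {
  rec$data <- rec$data / rec$scale
  rec$scale <- 1
  rec
}

#' Per-page channel demeaning
#'
#' Normalizes each channel within each single-page unit to zero mean
#' (demeaning precedes any concatenation).  Idempotent.
#'
#' @param rec A `meg_recording`.
#' @return The demeaned recording.
#' @export
demean_pages <- function(rec) {
  for (p in seq_len(n_pages(rec))) {
    idx <- page_indices(rec, p)
    if (length(idx) == 0) stop("empty page span")
    mu <- rowMeans(rec$data[, idx, drop = FALSE])
    rec$data[, idx] <- rec$data[, idx, drop = FALSE] - mu
  }
  rec
}

#' Concatenate page units into a single continuous recording
#'
#' Appends samples of several recordings (e.g. reading and scanning task
#' units) in the given order and rebuilds the page spans.  All inputs must
#' share the channel set, sampling rate and scale.
#'
#' @param recs A `meg_recording` or list of them.
#' @return A single concatenated `meg_recording`.
#' @export
concatenate_pages <- function(recs) {
  if (inherits(recs, "meg_recording")) return(recs)
  stopifnot(length(recs) >= 1)
  r1 <- recs[[1]]
  for (r in recs[-1]) {
    if (!identical(r$info$name, r1$info$name))
      stop("channel sets differ between recordings")
    if (r$sfreq != r1$sfreq) stop("sampling rates differ")
    if (r$scale != r1$scale) stop("scales differ")
  }
  data <- do.call(cbind, lapply(recs, `[[`, "data"))
  spans <- list(); off <- 0L
  for (r in recs) {
    s <- r$page_spans
    spans[[length(spans) + 1L]] <- cbind(s[, 1] + off, s[, 2] + off)
    off <- off + ncol(r$data)
  }
  meg_recording(data, r1$info, r1$sfreq, do.call(rbind, spans), r1$sensors,
                r1$scale)
}

#' Restrict a recording to a subset of its pages
#'
#' @param rec A `meg_recording`.
#' @param pages Integer page indices (kept in the given order).
#' @return A `meg_recording` containing only those pages.
#' @export
restrict_to_pages <- function(rec, pages) {
  stopifnot(all(pages >= 1), all(pages <= n_pages(rec)))
  idx <- unlist(lapply(pages, function(p) page_indices(rec, p)))
  lens <- vapply(pages, function(p) length(page_indices(rec, p)), 1L)
  stops <- cumsum(lens)
  spans <- cbind(start = c(1L, head(stops, -1) + 1L), stop = stops + 1L)
  meg_recording(rec$data[, idx, drop = FALSE], rec$info, rec$sfreq, spans,
                rec$sensors, rec$scale)
}

#' Select the page units that contain blinks
#'
#' Blink-page enrichment: when a subject blinks rarely, only the one-page
#' units containing at least one blink onset are fed to the blink-extraction
#' ICA; the estimated demixing matrix is then applied to all pages.
#'
#' @param rec A `meg_recording`.
#' @param blink_markers Blink onset sample indices; defaults to onsets from
#'   the `ET_BLINK` eye-tracker channel.
#' @return List with `recording` (concatenation of the selected pages) and
#'   `pages` (their indices in `rec`).
#' @export
select_blink_pages <- function(rec, blink_markers = NULL) {
  if (is.null(blink_markers)) blink_markers <- blink_onsets(rec)
  has <- vapply(seq_len(n_pages(rec)), function(p) {
    s <- rec$page_spans[p, ]
    any(blink_markers >= s[["start"]] & blink_markers < s[["stop"]])
  }, logical(1))
  if (!any(has))
    stop("no page contains a blink onset; enrichment impossible")
  pages <- which(has)
  list(recording = restrict_to_pages(rec, pages), pages = pages)
}
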