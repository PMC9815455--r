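# Core containers: the multichannel recording (x(t) = A s(t) + n(t)) and
# the BSS decomposition (s(t) = W x(t)).

#' Construct a multichannel MEG-like recording
#'
#' @param data Channels x samples numeric matrix (gradiometers in T/m).
#' @param info Data frame with one row per channel: `name`, `type` (one of
#'   `"grad"`, `"eog_h"`, `"eog_v"`, `"eyetrack"`), `site` (integer site id
#'   for gradiometers, NA otherwise), `pair` (1 or 2 within a site).
#' @param sfreq Sampling frequency (Hz).
#' @param page_spans Integer matrix with columns `start`, `stop`: half-open
#'   1-based sample intervals `[start, stop)` that must be disjoint,
#'   ordered, and cover all samples.
#' @param sensors Optional [sensor_layout()] describing the gradiometer
#'   geometry.
#' @param scale Dimensionless multiplier currently applied to `data`
#'   relative to physical units (see [scale_recording()]).
#' @return Object of class `meg_recording`.
#' @export
meg_recording <- function(data, info, sfreq, page_spans, sensors = NULL,
                          scale = 1) {
  stopifnot(is.matrix(data), nrow(data) == nrow(info))
  page_spans <- as.matrix(page_spans)
  colnames(page_spans) <- c("start", "stop")
  validate_page_spans(page_spans, ncol(data))
  grads <- info$type == "grad"
  if (any(grads)) {
    tab <- table(info$site[grads])
    if (any(tab != 2)) stop("exactly two gradiometers required per site id")
  }
  rownames(data) <- info$name
  structure(list(data = data, info = info, sfreq = sfreq,
                 page_spans = page_spans, sensors = sensors, scale = scale),
            class = "meg_recording")
}

validate_page_spans <- function(spans, n_samples) {
  if (nrow(spans) == 0) stop("page_spans must be nonempty")
  if (any(spans[, "stop"] <= spans[, "start"])) stop("empty page span")
  if (spans[1, "start"] != 1L || spans[nrow(spans), "stop"] != n_samples + 1L)
    stop("page_spans must cover all samples")
  if (nrow(spans) > 1 &&
      any(spans[-1, "start"] != spans[-nrow(spans), "stop"]))
    stop("page_spans must be disjoint, ordered and contiguous")
  invisible(TRUE)
}

#' @export
print.meg_recording <- function(x, ...) {
  cat(sprintf(
    "<meg_recording> %d channels (%d grad) x %d samples @ %g Hz, %d pages, scale %g\n",
    nrow(x$data), sum(x$info$type == "grad"), ncol(x$data), x$sfreq,
    nrow(x$page_spans), x$scale))
  invisible(x)
}

#' @export
dim.meg_recording <- function(x) dim(x$data)

#' Number of pages in a recording
#' @param rec A `meg_recording`.
#' @return Integer page count.
#' @export
n_pages <- function(rec) nrow(rec$page_spans)

#' Sample indices of one page
#' @param rec A `meg_recording`.
#' @param p Page number.
#' @return Integer vector of sample indices.
#' @export
page_indices <- function(rec, p) {
  s <- rec$page_spans[p, ]
  seq.int(s[["start"]], s[["stop"]] - 1L)
}

#' Restrict a recording to the gradiometer channels
#'
#' Decompositions operate on the gradiometer data only; EOG and eye-tracker
#' channels are carried as side information.
#'
#' @param rec A `meg_recording`.
#' @return A `meg_recording` containing only `type == "grad"` channels.
#' @export
grads_only <- function(rec) {
  keep <- rec$info$type == "grad"
  meg_recording(rec$data[keep, , drop = FALSE], rec$info[keep, ],
                rec$sfreq, rec$page_spans, rec$sensors, rec$scale)
}

# Convenience channel accessors -------------------------------------------

#' Extract a named auxiliary channel
#' @param rec A `meg_recording`.
#' @param name Channel name (e.g. `"EOG_H"`, `"EOG_V"`, `"ET_BLINK"`).
#' @return Numeric vector.
#' @export
get_channel <- function(rec, name) {
  i <- match(name, rec$info$name)
  if (is.na(i)) stop("no channel named ", name)
  rec$data[i, ]
}

#' Blink onset samples from the eye-tracker blink channel
#' @param rec A `meg_recording` containing an `ET_BLINK` channel.
#' @return Integer vector of onset sample indices.
#' @export
blink_onsets <- function(rec) {
  b <- get_channel(rec, "ET_BLINK")
  which(diff(c(0, b)) > 0.5)
}

#' Construct a BSS decomposition
#'
#' Holds the mixing matrix A, demixing matrix W and component time courses
#' s(t) = W x(t) of a linear decomposition x(t) = A s(t) + n(t).
#'
#' @param mixing m x n mixing matrix A.
#' @param demixing n x m demixing matrix W.
#' @param sources n x samples component matrix.
#' @param method Method tag (`"sobi"`, `"fastica"`, `"amica"`).
#' @param channel_names Names of the m data channels the decomposition was
#'   estimated on.
#' @param scale Scale factor that was applied to the data before
#'   estimation (see [scale_recording()]).
#' @param extras Free-form list of method metadata (lags, seeds,
#'   convergence info, ...).
#' @return Object of class `decomposition`.
#' @export
decomposition <- function(mixing, demixing, sources, method, channel_names,
                          scale = 1, extras = list()) {
  stopifnot(nrow(demixing) == ncol(mixing),
            ncol(demixing) == nrow(mixing),
            nrow(sources) == nrow(demixing),
            nrow(demixing) <= ncol(demixing))
  structure(list(mixing = mixing, demixing = demixing, sources = sources,
                 method = method, channel_names = channel_names,
                 scale = scale, extras = extras),
            class = "decomposition")
}

#' @export
print.decomposition <- function(x, ...) {
  cat(sprintf("<decomposition> method=%s, %d components from %d channels\n",
              x$method, nrow(x$demixing), ncol(x$demixing)))
  invisible(x)
}

#' Number of components
#' @param dec A `decomposition`.
#' @return Integer.
#' @export
n_components <- function(dec) nrow(dec$demixing)
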