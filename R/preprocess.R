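#' Fill short occlusion gaps in a marker series
#'
#' Interior gaps of at most `max_gap` consecutive missing frames are filled
#' by per-coordinate linear interpolation between the bounding samples;
#' longer gaps are left missing and listed in the attached gap report. Gaps
#' touching the start or end of the trial are held at the nearest observed
#' value (no extrapolation).
#'
#' @param series a [marker_series].
#' @param max_gap longest gap (frames) that will be interpolated.
#' @return a `marker_series` with gaps filled; attribute `gap_report` is a
#'   data frame of the gaps found (`marker`, `start`, `end`, `length`,
#'   `filled`), 0-based frame indices.
#' @export
fill_gaps <- function(series, max_gap = 10) {
  stopifnot(inherits(series, "marker_series"))
  pos <- series$positions
  miss <- series$missing
  report <- list()
  nf <- series$n_frames
  for (m in seq_along(series$labels)) {
    mi <- miss[, m]
    if (!any(mi)) next
    if (all(mi))
      stop("marker '", series$labels[m], "' is missing in every frame")
    r <- rle(mi)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      s <- starts[k]; e <- ends[k]; len <- e - s + 1
      edge <- s == 1 || e == nf
      fill <- edge || len <= max_gap
      if (fill) {
        if (s == 1) {                       # leading edge: hold first value
          pos[s:e, , m] <- matrix(pos[e + 1, , m], len, 3, byrow = TRUE)
        } else if (e == nf) {               # trailing edge: hold last value
          pos[s:e, , m] <- matrix(pos[s - 1, , m], len, 3, byrow = TRUE)
        } else {
          w <- seq_len(len) / (len + 1)
          for (c in 1:3)
            pos[s:e, c, m] <- (1 - w) * pos[s - 1, c, m] + w * pos[e + 1, c, m]
        }
        miss[s:e, m] <- FALSE
      }
      report[[length(report) + 1]] <- data.frame(
        marker = series$labels[m], start = s - 1L, end = e - 1L,
        length = len, filled = fill, stringsAsFactors = FALSE)
    }
  }
  out <- marker_series(pos, series$labels, series$frame_rate, miss)
  attr(out, "gap_report") <- if (length(report) > 0) do.call(rbind, report) else
    data.frame(marker = character(0), start = integer(0), end = integer(0),
               length = integer(0), filled = logical(0))
  out
}

#' Five-point 1-3-4-3-1 smoothing filter
#'
#' Symmetric weighted moving average with weights (1, 3, 4, 3, 1)/12, the
#' classic five-point smoothing function for marker trajectories. Interior
#' samples are replaced by the weighted mean of their five-sample
#' neighbourhood; the first and last two samples use the truncated kernel
#' renormalised to unit sum, so output length equals input length and no
#' values are extrapolated.
#'
#' @param signal numeric vector (one coordinate channel); must contain no
#'   missing values (run [fill_gaps()] first).
#' @return smoothed numeric vector of the same length.
#' @examples
#' smooth_five_point(c(0, 0, 1, 0, 0))   # kernel revealed by a unit impulse
#' @export
smooth_five_point <- function(signal) {
  if (length(signal) < 1) stop("signal must contain at least one sample")
  if (any(!is.finite(signal)))
    stop("signal contains missing values; fill gaps before smoothing")
  n <- length(signal)
  if (n == 1) return(signal)
  w <- c(1, 3, 4, 3, 1)
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- (i - 2):(i + 2)
    keep <- j >= 1 & j <= n
    wk <- w[keep]
    out[i] <- sum(wk * signal[j[keep]]) / sum(wk)
  }
  out
}

#' Smooth every marker coordinate of a series
#'
#' Applies [smooth_five_point()] to each coordinate channel of each marker.
#' Markers with missing samples raise an error; fill gaps first.
#'
#' @param series a [marker_series] with no missing samples.
#' @return smoothed `marker_series`.
#' @export
smooth_markers <- function(series) {
  stopifnot(inherits(series, "marker_series"))
  if (any(series$missing))
    stop("series contains missing samples; run fill_gaps() before smoothing")
  pos <- series$positions
  for (m in seq_along(series$labels))
    for (c in 1:3)
      pos[, c, m] <- smooth_five_point(pos[, c, m])
  marker_series(pos, series$labels, series$frame_rate, series$missing)
}
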