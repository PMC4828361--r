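#' Labelled 3D marker trajectories
#'
#' The raw input of the pipeline: positions of named reflective markers over
#' time at a fixed sampling rate. Positions are stored in millimetres in a
#' right-handed frame with Z vertical (up). Missing samples (occlusions,
#' dropouts) carry an explicit flag; a coordinate of zero is a valid position,
#' never a missing-value sentinel.
#'
#' @param positions numeric array `n_frames x 3 x n_markers` (mm), or a list of
#'   `n_frames x 3` matrices, one per marker.
#' @param labels character vector of marker names, one per marker.
#' @param frame_rate sampling rate in Hz (> 0).
#' @param missing logical `n_frames x n_markers` matrix flagging missing
#'   samples; defaults to flagging samples with any non-finite coordinate.
#' @return An object of class `marker_series` with fields `labels`,
#'   `frame_rate`, `n_frames`, `positions` (array `n_frames x 3 x n_markers`)
#'   and `missing` (logical matrix `n_frames x n_markers`).
#' @examples
#' pos <- array(rnorm(5 * 3 * 2), dim = c(5, 3, 2))
#' ms <- marker_series(pos, c("LASI", "RASI"), frame_rate = 200)
#' n_frames(ms)
#' @export
marker_series <- function(positions, labels, frame_rate = 200, missing = NULL) {
  if (is.list(positions)) {
    stopifnot(length(positions) == length(labels))
    nf <- nrow(positions[[1]])
    arr <- array(NA_real_, dim = c(nf, 3, length(positions)))
    for (i in seq_along(positions)) arr[, , i] <- as.matrix(positions[[i]])
    positions <- arr
  }
  positions <- unname(positions)
  if (length(dim(positions)) != 3 || dim(positions)[2] != 3)
    stop("'positions' must be an n_frames x 3 x n_markers array")
  labels <- as.character(labels)
  if (dim(positions)[3] != length(labels))
    stop("number of labels (", length(labels), ") does not match markers (",
         dim(positions)[3], ")")
  if (anyDuplicated(labels))
    stop("duplicate marker labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  if (!is.numeric(frame_rate) || length(frame_rate) != 1 || frame_rate <= 0)
    stop("'frame_rate' must be a single positive number")
  nf <- dim(positions)[1]
  nm <- dim(positions)[3]
  if (nf < 1) stop("series must contain at least one frame")
  if (is.null(missing))
    missing <- matrix(apply(positions, c(1, 3), function(v) any(!is.finite(v))),
                      nrow = nf, ncol = nm)
  missing <- matrix(as.logical(missing), nrow = nf, ncol = nm)
  dimnames(positions) <- list(NULL, c("x", "y", "z"), labels)
  colnames(missing) <- labels
  obj <- structure(
    list(labels = labels, frame_rate = as.numeric(frame_rate),
         n_frames = nf, positions = positions, missing = missing),
    class = "marker_series")
  validate_marker_series(obj)
  obj
}

validate_marker_series <- function(x) {
  stopifnot(inherits(x, "marker_series"))
  if (dim(x$positions)[1] != x$n_frames || nrow(x$missing) != x$n_frames)
    stop("inconsistent frame counts in marker_series")
  ok <- is.finite(x$positions)
  bad <- which(!ok, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    # every non-finite coordinate must be flagged missing
    flagged <- x$missing[cbind(bad[, 1], bad[, 3])]
    if (!all(flagged))
      stop("non-finite positions present in frames not flagged as missing")
  }
  invisible(x)
}

#' @export
print.marker_series <- function(x, ...) {
  n_miss <- sum(x$missing)
  cat(sprintf("marker_series: %d markers x %d frames @ %g Hz (%.2f s)\n",
              length(x$labels), x$n_frames, x$frame_rate,
              x$n_frames / x$frame_rate))
  cat(" markers:", paste(utils::head(x$labels, 8), collapse = ", "),
      if (length(x$labels) > 8) "..." else "", "\n")
  if (n_miss > 0)
    cat(sprintf(" missing samples: %d (%.1f%%)\n", n_miss,
                100 * n_miss / (x$n_frames * length(x$labels))))
  invisible(x)
}

#' Number of frames in a marker series
#' @param x a `marker_series`.
#' @return integer frame count.
#' @export
n_frames <- function(x) x$n_frames

#' Extract one marker's trajectory
#'
#' @param x a `marker_series`.
#' @param label marker name.
#' @return `n_frames x 3` matrix (mm); missing samples are `NA`.
#' @export
marker_xyz <- function(x, label) {
  i <- match(label, x$labels)
  if (is.na(i)) stop("unknown marker: ", label)
  m <- x$positions[, , i, drop = FALSE]
  dim(m) <- dim(m)[1:2]
  colnames(m) <- c("x", "y", "z")
  m[x$missing[, i], ] <- NA_real_
  m
}

#' Convert a marker series to a long data frame
#'
#' One row per marker per frame: `frame` (0-based), `time` (s), `marker`,
#' `x`, `y`, `z` (mm) and `missing`.
#' @param x a `marker_series`.
#' @param ... unused.
#' @export
as.data.frame.marker_series <- function(x, ...) {
  nf <- x$n_frames
  nm <- length(x$labels)
  frame <- rep(seq_len(nf) - 1L, times = nm)
  data.frame(
    frame = frame,
    time = frame / x$frame_rate,
    marker = rep(x$labels, each = nf),
    x = as.vector(x$positions[, 1, ]),
    y = as.vector(x$positions[, 2, ]),
    z = as.vector(x$positions[, 3, ]),
    missing = as.vector(x$missing),
    stringsAsFactors = FALSE)
}

#' Read / write marker trajectories as long-format CSV
#'
#' Columns: `frame, time, marker, x, y, z, missing` with positions in mm.
#' @param path file path.
#' @param x a `marker_series`.
#' @param frame_rate sampling rate used when the file's `time` column is
#'   degenerate (single frame); otherwise inferred from `time`.
#' @return `read_marker_csv` returns a `marker_series`; `write_marker_csv`
#'   returns `path` invisibly.
#' @export
read_marker_csv <- function(path, frame_rate = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "marker", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("marker CSV must contain columns: ", paste(need, collapse = ", "))
  labels <- unique(df$marker)
  frames <- sort(unique(df$frame))
  nf <- length(frames)
  if (is.null(frame_rate)) {
    if ("time" %in% names(df) && nf > 1) {
      tt <- df$time[match(frames, df$frame)]
      frame_rate <- 1 / stats::median(diff(tt))
    } else frame_rate <- 200
  }
  pos <- array(NA_real_, dim = c(nf, 3, length(labels)))
  miss <- matrix(TRUE, nf, length(labels))
  fi <- match(df$frame, frames)
  mi <- match(df$marker, labels)
  pos[cbind(fi, 1L, mi)] <- df$x
  pos[cbind(fi, 2L, mi)] <- df$y
  pos[cbind(fi, 3L, mi)] <- df$z
  if ("missing" %in% names(df)) {
    miss[cbind(fi, mi)] <- as.logical(df$missing)
  } else {
    miss[cbind(fi, mi)] <- !is.finite(df$x) | !is.finite(df$y) | !is.finite(df$z)
  }
  pos[is.na(pos)] <- NA_real_
  marker_series(pos, labels, frame_rate, miss)
}

#' @rdname read_marker_csv
#' @export
write_marker_csv <- function(x, path) {
  df <- as.data.frame(x)
  df$x[df$missing] <- NA_real_
  df$y[df$missing] <- NA_real_
  df$z[df$missing] <- NA_real_
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
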