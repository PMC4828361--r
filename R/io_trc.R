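#' Read a TRC marker-trajectory file
#'
#' TRC is the tab-separated text format used throughout marker-based motion
#' capture: a header carrying `DataRate`, `NumFrames`, `NumMarkers` and
#' `Units`, a marker-label row, and one row per frame of
#' `Frame# Time X1 Y1 Z1 X2 ...`. Positions are converted to millimetres on
#' read (the header may declare `m`, `cm` or `mm`); blank or non-numeric
#' cells become missing samples.
#'
#' @param path path to a TRC file.
#' @return a [marker_series].
#' @seealso [write_trc()]
#' @export
read_trc <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 5)
    stop("malformed TRC header in '", path, "': fewer than 5 header lines")
  split_tab <- function(s) strsplit(s, "\t", fixed = TRUE)[[1]]
  keys <- split_tab(lines[2])
  vals <- split_tab(lines[3])
  if (length(keys) == 0 || !any(keys == "DataRate"))
    stop("malformed TRC header (line 2): missing 'DataRate' field")
  hdr <- stats::setNames(as.list(vals[seq_along(keys)]), keys)
  frame_rate <- suppressWarnings(as.numeric(hdr[["DataRate"]]))
  if (!isTRUE(is.finite(frame_rate)) || frame_rate <= 0)
    stop("malformed TRC header (line 3): DataRate '", hdr[["DataRate"]],
         "' is not a positive number")
  n_markers <- suppressWarnings(as.integer(hdr[["NumMarkers"]]))
  units <- hdr[["Units"]]
  if (is.null(units) || !units %in% c("mm", "cm", "m"))
    stop("malformed TRC header (line 3): Units must be mm, cm or m, got '",
         units, "'")
  scale <- c(mm = 1, cm = 10, m = 1000)[[units]]

  lab_row <- split_tab(lines[4])
  labels <- lab_row[-(1:2)]
  labels <- labels[labels != ""]
  if (!is.na(n_markers) && length(labels) != n_markers)
    stop("malformed TRC header (line 4): ", length(labels),
         " labels but NumMarkers=", n_markers)
  n_markers <- length(labels)

  # line 5 is the X1/Y1/Z1 coordinate-name row; data start at first row whose
  # first field parses as a frame number
  data_lines <- lines[-(1:5)]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  nf <- length(data_lines)
  if (nf < 1) stop("TRC file '", path, "' contains no data frames")
  ncol_expected <- 2 + 3 * n_markers
  pos <- array(NA_real_, dim = c(nf, 3, n_markers))
  for (f in seq_len(nf)) {
    cells <- split_tab(data_lines[f])
    # trailing empty cells are legal; missing markers appear as blanks
    if (length(cells) < ncol_expected)
      cells <- c(cells, rep("", ncol_expected - length(cells)))
    if (length(cells) > ncol_expected && any(nzchar(cells[-seq_len(ncol_expected)])))
      stop("inconsistent column count at frame ", f, " of '", path, "'")
    v <- suppressWarnings(as.numeric(cells[3:ncol_expected]))
    pos[f, , ] <- matrix(v, nrow = 3)
  }
  marker_series(pos * scale, labels, frame_rate)
}

#' Write a marker series as a TRC file
#'
#' Emits a standard TRC header (units mm) and one tab-separated row per
#' frame; missing samples become blank cells. Positions are printed with
#' `digits` significant decimals, so a read-back round trip agrees to text
#' precision.
#'
#' @param x a [marker_series].
#' @param path output path.
#' @param digits decimal places for coordinates.
#' @return `path`, invisibly.
#' @export
write_trc <- function(x, path, digits = 5) {
  stopifnot(inherits(x, "marker_series"))
  nm <- length(x$labels)
  l1 <- paste("PathFileType", "4", "(X/Y/Z)", basename(path), sep = "\t")
  keys <- c("DataRate", "CameraRate", "NumFrames", "NumMarkers", "Units",
            "OrigDataRate", "OrigDataStartFrame", "OrigNumFrames")
  vals <- c(x$frame_rate, x$frame_rate, x$n_frames, nm, "mm",
            x$frame_rate, 1, x$n_frames)
  l4 <- paste(c("Frame#", "Time",
                as.vector(rbind(x$labels, "", ""))), collapse = "\t")
  coord <- paste0(rep(c("X", "Y", "Z"), nm), rep(seq_len(nm), each = 3))
  l5 <- paste(c("", "", coord), collapse = "\t")
  fmt <- function(v) ifelse(is.finite(v), formatC(v, digits = digits,
                                                  format = "f"), "")
  rows <- character(x$n_frames)
  for (f in seq_len(x$n_frames)) {
    vv <- as.vector(x$positions[f, , ])
    vv[rep(x$missing[f, ], each = 3)] <- NA_real_
    rows[f] <- paste(c(f, formatC((f - 1) / x$frame_rate, digits = 6,
                                  format = "f"), fmt(vv)), collapse = "\t")
  }
  writeLines(c(l1, paste(keys, collapse = "\t"),
               paste(vals, collapse = "\t"), l4, l5, rows), path)
  invisible(path)
}
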