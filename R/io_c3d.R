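#' Read a C3D motion-capture file
#'
#' Supports the common modern dialect of the C3D standard: little-endian
#' (Intel) byte order, 3D point data stored as floats or scaled integers, no
#' analog channels required. Marker labels, rate and frame count are taken
#' from the `POINT` parameter group; samples whose residual word is negative
#' (invalid / interpolation failure) are flagged missing. Positions are
#' converted to millimetres using `POINT:UNITS` when present.
#'
#' @param path path to a C3D file.
#' @return a [marker_series].
#' @seealso [write_c3d()]
#' @export
read_c3d <- function(path) {
  raw <- readBin(path, what = "raw", n = file.info(path)$size)
  if (length(raw) < 1024 || raw[2] != as.raw(0x50))
    stop("not a C3D file (bad magic byte): ", path)
  i16 <- function(off, n = 1) readBin(raw[(off + 1):(off + 2 * n)], "integer",
                                      n = n, size = 2, endian = "little")
  f32 <- function(off, n = 1) readBin(raw[(off + 1):(off + 4 * n)], "double",
                                      n = n, size = 4, endian = "little")
  param_block <- as.integer(raw[1])
  n_points <- i16(2)
  n_analog <- i16(4)
  first_frame <- i16(6)
  last_frame <- i16(8)
  hdr_scale <- f32(12)
  data_start <- i16(16)
  frame_rate <- f32(20)

  # ---- parameter section ----
  poff <- (param_block - 1) * 512
  proc <- as.integer(raw[poff + 4])
  if (proc != 84)
    stop("unsupported C3D processor type ", proc, " (only Intel/84 supported)")
  pos <- poff + 4
  groups <- list()   # id -> name
  params <- list()   # "GROUP:PARAM" -> value
  repeat {
    if (pos + 2 > length(raw)) break
    nchar_name <- readBin(raw[pos + 1], "integer", size = 1, signed = TRUE)
    gid <- readBin(raw[pos + 2], "integer", size = 1, signed = TRUE)
    if (nchar_name == 0 || gid == 0) break
    nn <- abs(nchar_name)
    name <- rawToChar(raw[(pos + 3):(pos + 2 + nn)])
    cur <- pos + 2 + nn
    offset <- i16(cur)
    next_pos <- if (offset == 0) NA_integer_ else cur + 2 + offset
    if (gid < 0) {                      # group record
      groups[[as.character(-gid)]] <- name
    } else {                            # parameter record
      dtype <- readBin(raw[cur + 3], "integer", size = 1, signed = TRUE)
      ndim <- as.integer(raw[cur + 4])
      dims <- if (ndim > 0) as.integer(raw[(cur + 5):(cur + 4 + ndim)]) else integer(0)
      dpos <- cur + 4 + ndim
      nel <- if (ndim > 0) prod(dims) else 1L
      val <- switch(as.character(dtype),
        "-1" = rawToChar(raw[(dpos + 1):(dpos + nel)]),
        "1"  = as.integer(raw[(dpos + 1):(dpos + nel)]),
        "2"  = i16(dpos, nel),
        "4"  = f32(dpos, nel),
        NULL)
      if (dtype == -1 && ndim >= 2) {
        # char matrix: first dim is string length
        val <- substring(val, seq(1, nel, by = dims[1]),
                         seq(dims[1], nel, by = dims[1]))
      }
      params[[paste0(groups[[as.character(gid)]], ":", name)]] <-
        list(value = val, dims = dims)
    }
    if (is.na(next_pos) || next_pos <= pos) break
    pos <- next_pos
  }
  getp <- function(key, default = NULL) {
    p <- params[[key]]
    if (is.null(p)) default else p$value
  }
  n_points <- getp("POINT:USED", n_points)[1]
  if (n_points < 1) stop("C3D file declares no 3D points: ", path)
  nf <- getp("POINT:FRAMES", last_frame - first_frame + 1)[1]
  frame_rate <- getp("POINT:RATE", frame_rate)[1]
  scale <- getp("POINT:SCALE", hdr_scale)[1]
  data_start <- getp("POINT:DATA_START", data_start)[1]
  labels <- getp("POINT:LABELS", sprintf("M%03d", seq_len(n_points)))
  labels <- trimws(labels)[seq_len(n_points)]
  labels[!nzchar(labels)] <- sprintf("M%03d", which(!nzchar(labels)))
  units <- trimws(getp("POINT:UNITS", "mm"))
  uscale <- switch(units, mm = 1, cm = 10, m = 1000, 1)

  doff <- (data_start - 1) * 512
  analog_per_frame <- 0L  # analog channels unsupported (none written/needed)
  if (n_analog > 0) stop("C3D files with analog data are not supported")
  pos_arr <- array(NA_real_, dim = c(nf, 3, n_points))
  miss <- matrix(FALSE, nf, n_points)
  if (scale < 0) {                      # float storage
    need <- nf * n_points * 4
    vals <- f32(doff, need)
    dim(vals) <- c(4, n_points, nf)
    for (f in seq_len(nf)) {
      pos_arr[f, , ] <- vals[1:3, , f]
      miss[f, ] <- vals[4, , f] < 0
    }
  } else {                              # int16 storage, scaled
    need <- nf * n_points * 4
    vals <- i16(doff, need)
    dim(vals) <- c(4, n_points, nf)
    for (f in seq_len(nf)) {
      pos_arr[f, , ] <- vals[1:3, , f] * scale
      miss[f, ] <- vals[4, , f] < 0
    }
  }
  pos_arr[is.na(pos_arr)] <- 0
  for (m in seq_len(n_points)) pos_arr[miss[, m], , m] <- NA_real_
  marker_series(pos_arr * uscale, labels, frame_rate, miss)
}

#' Write a marker series as a C3D file
#'
#' Emits the Intel/float dialect: header block, one parameter block holding
#' the `POINT` group (`USED`, `FRAMES`, `RATE`, `SCALE = -1`, `DATA_START`,
#' `UNITS = "mm"`, `LABELS`), and float 3D point data with a residual word
#' per sample (negative residual marks a missing sample).
#'
#' @param x a [marker_series].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_c3d <- function(x, path) {
  stopifnot(inherits(x, "marker_series"))
  np <- length(x$labels)
  nf <- x$n_frames
  w16 <- function(v) writeBin(as.integer(v), con, size = 2, endian = "little")
  w32 <- function(v) writeBin(as.numeric(v), con, size = 4, endian = "little")
  w8 <- function(v) writeBin(as.integer(v), con, size = 1)
  wch <- function(s) writeBin(charToRaw(s), con)

  # ---- build parameter section in memory first to know its block count ----
  lab_len <- max(4L, max(nchar(x$labels)))
  labs <- formatC(x$labels, width = lab_len, flag = "-")
  param_con <- rawConnection(raw(0), "wb")
  con <- param_con
  w8(c(1, 0x50, 0, 84))                # magic, block count patched later, Intel
  grp <- function(name, id) {
    w8(nchar(name)); w8(bitwAnd(256 - id, 255))  # negative id, two's complement
    wch(name)
    w16(1); w8(0)   # offset past the desc-len byte; empty description
  }
  param <- function(name, id, dtype, dims, data) {
    w8(nchar(name)); w8(id); wch(name)
    ndim <- length(dims)
    dsize <- c("-1" = 1, "1" = 1, "2" = 2, "4" = 4)[[as.character(dtype)]]
    nel <- if (ndim > 0) prod(dims) else 1
    off <- 2 + ndim + dsize * nel + 1    # type+ndim + dims + data + desc len
    w16(off)
    w8(dtype); w8(ndim); if (ndim > 0) w8(dims)
    if (dtype == -1) wch(paste(data, collapse = "")) else
      if (dtype == 4) w32(data) else if (dtype == 2) w16(data) else w8(data)
    w8(0)                                # no description
  }
  emit_params <- function(n_blocks, data_start_block) {
    w8(c(1, 0x50, n_blocks, 84))
    grp("POINT", 1)
    param("USED", 1, 2, integer(0), np)
    param("FRAMES", 1, 2, integer(0), nf)
    param("RATE", 1, 4, integer(0), x$frame_rate)
    param("SCALE", 1, 4, integer(0), -1)
    param("DATA_START", 1, 2, integer(0), data_start_block)
    param("UNITS", 1, -1, 2L, "mm")
    param("LABELS", 1, -1, c(lab_len, np), labs)
    w8(c(0, 0))                         # terminator record
  }
  emit_params(0, 0)                     # sizing pass; values patched below
  param_raw <- rawConnectionValue(param_con)
  close(param_con)
  n_param_blocks <- ceiling(length(param_raw) / 512)
  data_start_block <- 2 + n_param_blocks
  param_con <- rawConnection(raw(0), "wb")
  con <- param_con
  emit_params(n_param_blocks, data_start_block)  # same record sizes as pass 1
  param_raw <- rawConnectionValue(param_con)
  close(param_con)
  param_raw <- c(param_raw, raw(n_param_blocks * 512 - length(param_raw)))

  con <- file(path, "wb")
  on.exit(close(con))
  # ---- header block ----
  w8(c(2, 0x50))                        # parameter section at block 2
  w16(np); w16(0)                       # points, analog per frame
  w16(1); w16(nf)                       # first, last frame
  w16(0)                                # max interpolation gap
  w32(-1)                               # scale: negative = float data
  w16(data_start_block)
  w16(0)                                # analog samples per frame
  w32(x$frame_rate)
  writeBin(raw(512 - 24), con)
  # ---- parameter section ----
  writeBin(param_raw, con)
  # ---- data section ----
  dat <- numeric(4 * np * nf)
  k <- 0
  for (f in seq_len(nf)) {
    v <- x$positions[f, , , drop = FALSE]
    dim(v) <- c(3, np)
    res <- rep(0, np)
    mm <- x$missing[f, ]
    v[, mm] <- 0
    res[mm] <- -1
    dat[k + seq_len(4 * np)] <- rbind(v, res)
    k <- k + 4 * np
  }
  w32(dat)
  pad <- (512 - (4 * length(dat)) %% 512) %% 512
  if (pad > 0) writeBin(raw(pad), con)
  invisible(path)
}
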