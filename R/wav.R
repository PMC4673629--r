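#' Write a mono waveform to a RIFF/WAVE file
#'
#' Samples are expected in [-1, 1] full scale; values outside are clipped.
#'
#' @param x numeric vector of samples.
#' @param fs sampling rate in Hz.
#' @param path output file path.
#' @param bits bit depth: 16 (PCM) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, fs, path, bits = 16) {
  stopifnot(is.numeric(x), length(x) > 0, fs > 0, bits %in% c(16L, 32L))
  x <- pmin(1, pmax(-1, x))
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(x)
  bytes_per <- bits / 8
  data_size <- n * bytes_per
  fmt_code <- if (bits == 32) 3L else 1L  # 3 = IEEE float, 1 = PCM
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")                # mono
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * bytes_per), con, size = 4, endian = "little")
  writeBin(as.integer(bytes_per), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (bits == 16) {
    writeBin(as.integer(round(x * 32767)), con, size = 2, endian = "little")
  } else {
    writeBin(as.double(x), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a mono RIFF/WAVE file
#'
#' Supports PCM 16/24/32-bit and IEEE float32, single channel. Samples are
#' returned scaled to [-1, 1].
#'
#' @param path WAV file path.
#' @return list with `samples` (numeric vector), `fs` (Hz) and `bits`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        code = readBin(con, "integer", 1, size = 2, endian = "little"),
        channels = readBin(con, "integer", 1, size = 2, endian = "little"),
        fs = readBin(con, "integer", 1, size = 4, endian = "little")
      )
      invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
      invisible(readBin(con, "integer", 1, size = 2, endian = "little"))
      fmt$bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      extra <- size - 16
      if (extra > 0) invisible(readBin(con, "raw", extra))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
      break
    } else {
      invisible(readBin(con, "raw", size + size %% 2))
    }
  }
  if (is.null(fmt) || is.null(data_raw)) stop("malformed WAV: ", path)
  if (fmt$channels != 1) stop("only mono WAV supported")
  bits <- fmt$bits
  x <- switch(
    as.character(bits),
    "16" = readBin(data_raw, "integer", length(data_raw) / 2, size = 2,
                   signed = TRUE, endian = "little") / 32768,
    "24" = {
      m <- matrix(as.integer(data_raw), nrow = 3)
      v <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
      v <- ifelse(v >= 8388608, v - 16777216, v)
      v / 8388608
    },
    "32" = if (fmt$code == 3) {
      readBin(data_raw, "double", length(data_raw) / 4, size = 4,
              endian = "little")
    } else {
      readBin(data_raw, "integer", length(data_raw) / 4, size = 4,
              endian = "little") / 2147483648
    },
    stop("unsupported bit depth: ", bits)
  )
  list(samples = x, fs = fmt$fs, bits = bits)
}

#' Read an Audacity label track
#'
#' Tab-separated rows `start<TAB>end<TAB>label`, times in seconds, half-open
#' intervals.
#'
#' @param path label file path.
#' @return data.frame with columns `start`, `end`, `label`.
#' @export
read_label_track <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("start", "end", "label"),
                          colClasses = c("numeric", "numeric", "character"),
                          quote = "", comment.char = "")
  df
}

#' Write an Audacity label track
#'
#' @param labels data.frame with columns `start`, `end`, `label`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_label_track <- function(labels, path) {
  stopifnot(all(c("start", "end", "label") %in% names(labels)))
  utils::write.table(
    data.frame(sprintf("%.6f", labels$start), sprintf("%.6f", labels$end),
               labels$label),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
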