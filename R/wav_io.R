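#' Write a mono IEEE-float WAV file
#'
#' Minimal 32-bit float WAV writer (format code 3, with a `fact` chunk).
#' Samples are stored as single-precision floats; a written file read back
#' with [read_wav()] and written again round-trips bit-exactly.
#'
#' @param samples numeric vector of samples.
#' @param path output file path.
#' @param sample_rate sample rate in Hz.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, path, sample_rate) {
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(samples)
  data_bytes <- 4 * n
  # RIFF size: WAVE(4) + fmt(8+16) + fact(8+4) + data(8+n*4)
  riff_size <- 4 + 24 + 12 + 8 + data_bytes
  w_int <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  writeChar("RIFF", con, eos = NULL); w_int(riff_size, 4)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); w_int(16, 4)
  w_int(3, 2)                 # IEEE float
  w_int(1, 2)                 # mono
  w_int(sample_rate, 4)
  w_int(sample_rate * 4, 4)   # byte rate
  w_int(4, 2)                 # block align
  w_int(32, 2)                # bits per sample
  writeChar("fact", con, eos = NULL); w_int(4, 4); w_int(n, 4)
  writeChar("data", con, eos = NULL); w_int(data_bytes, 4)
  writeBin(samples, con, size = 4, endian = "little")
  invisible(path)
}

#' Read a mono IEEE-float WAV file
#'
#' @param path file written by [write_wav()] (or any mono float32 WAV).
#' @return list with `samples` and `sample_rate`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 4)
  if (!identical(magic, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, size = 4, endian = "little")
  if (!identical(readChar(con, 4), "WAVE")) stop("not a WAVE file: ", path)
  sample_rate <- NULL; fmt <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", 1, size = 2, endian = "little")
      ch <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (ch != 1) stop("only mono WAV files are supported")
      sample_rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      seek(con, size - 8, origin = "current")
    } else if (id == "data") {
      if (is.null(fmt)) stop("data chunk before fmt chunk")
      if (fmt != 3) stop("only IEEE float WAV is supported (format code 3)")
      samples <- readBin(con, "numeric", size / 4, size = 4, endian = "little")
      break
    } else {
      seek(con, size + size %% 2, origin = "current")
    }
  }
  if (is.null(samples)) stop("no data chunk found in ", path)
  list(samples = samples, sample_rate = sample_rate)
}

#' Write / read a session event log
#'
#' Tab-separated table with columns `trial_id`, `condition_N`, `onset_s`,
#' `isi_s`, `coherent_indices` (comma-joined, 0-based), `seed`.
#'
#' @param log a `session_log` data.frame.
#' @param path file path.
#' @return `path` invisibly ([write_event_log()]); a `session_log`
#'   ([read_event_log()]).
#' @export
write_event_log <- function(log, path) {
  utils::write.table(log, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  log <- utils::read.delim(path, colClasses = c(coherent_indices = "character"))
  class(log) <- c("session_log", "data.frame")
  log
}
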