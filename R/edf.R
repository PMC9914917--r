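## Minimal single-channel EDF (European Data Format) writer/reader.
## Covers exactly the subset this package emits: one signal, 1-s data
## records, 16-bit samples. Header fields are fixed-width ASCII per the
## EDF specification.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  sprintf(paste0("%-", width, "s"), x)
}

#' Write a single-channel signal to an EDF file
#'
#' Samples are linearly quantized to 16 bits between the physical minimum
#' and maximum of the signal. The signal length must be a whole number of
#' seconds (records are 1 s long).
#'
#' @param path Output file path.
#' @param x Numeric sample vector (micro-volts).
#' @param fs Sampling rate in Hz (integer).
#' @param label Signal label (<= 16 chars).
#' @param recording_id Free-text recording identifier (<= 80 chars).
#' @return `path`, invisibly.
#' @export
write_edf <- function(path, x, fs, label = "EEG Fp1",
                      recording_id = "qeegicp synthetic") {
  fs <- as.integer(fs)
  if (length(x) %% fs != 0)
    stop("signal length must be a whole number of 1-s records")
  n_rec <- length(x) %/% fs
  pmin_ <- min(x); pmax_ <- max(x)
  if (pmax_ <= pmin_) pmax_ <- pmin_ + 1
  dmin <- -32768L; dmax <- 32767L
  dig <- as.integer(round((x - pmin_) / (pmax_ - pmin_) *
                            (dmax - dmin) + dmin))
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),                       # version
    edf_pad("X X X X", 80),                # patient id (anonymous)
    edf_pad(recording_id, 80),             # recording id
    edf_pad("01.01.00", 8),                # start date
    edf_pad("00.00.00", 8),                # start time
    edf_pad(256 + 256, 8),                 # header bytes
    edf_pad("", 44),                       # reserved
    edf_pad(n_rec, 8),                     # number of data records
    edf_pad("1", 8),                       # record duration, s
    edf_pad("1", 4),                       # number of signals
    edf_pad(label, 16),
    edf_pad("AgAgCl electrode", 80),
    edf_pad("uV", 8),
    edf_pad(formatC(pmin_, format = "g", digits = 6), 8),
    edf_pad(formatC(pmax_, format = "g", digits = 6), 8),
    edf_pad(dmin, 8),
    edf_pad(dmax, 8),
    edf_pad("BP 0.5-47 Hz", 80),
    edf_pad(fs, 8),                        # samples per record
    edf_pad("", 32))
  writeBin(charToRaw(hdr), con)
  writeBin(dig, con, size = 2L, endian = "little")
  invisible(path)
}

#' Read a single-channel EDF file
#'
#' Supports the subset written by [write_edf()] (one signal, uniform
#' records); general multi-signal EDF is out of scope.
#'
#' @param path EDF file path.
#' @return A list with `signal` (numeric, physical units), `fs`, `label`,
#'   `n_records`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- rawToChar(readBin(con, "raw", 256))
  fld <- function(s, from, len) trimws(substr(s, from, from + len - 1))
  n_sig <- as.integer(fld(hdr, 253, 4))
  if (n_sig != 1) stop("read_edf supports exactly one signal")
  n_rec <- as.integer(fld(hdr, 237, 8))
  rec_dur <- as.numeric(fld(hdr, 245, 8))
  sh <- rawToChar(readBin(con, "raw", 256))
  ## per-signal header layout for one signal
  label <- substr(sh, 1, 16)
  pmin_ <- as.numeric(substr(sh, 105, 112))
  pmax_ <- as.numeric(substr(sh, 113, 120))
  dmin <- as.numeric(substr(sh, 121, 128))
  dmax <- as.numeric(substr(sh, 129, 136))
  spr <- as.integer(substr(sh, 217, 224))
  dig <- readBin(con, "integer", n = n_rec * spr, size = 2L,
                 endian = "little")
  x <- (dig - dmin) / (dmax - dmin) * (pmax_ - pmin_) + pmin_
  list(signal = x, fs = spr / rec_dur, label = trimws(label),
       n_records = n_rec)
}

#' Write a subject's hemodynamic traces and phases to CSV
#'
#' Companion file to the EDF signal: one row per hemodynamic sample with
#' centred time, ICP, MAP, HR and the phase label at that time.
#'
#' @param path Output CSV path.
#' @param record A `subject_record`.
#' @param header_comment Optional `# ...` comment line written first.
#' @return `path`, invisibly.
#' @export
write_subject_csv <- function(path, record, header_comment = NULL) {
  t <- (seq_along(record$icp) - 0.5) / record$hemo_fs
  phase_idx <- findInterval(t, record$phases$start_s)
  df <- data.frame(time_s = t,
                   icp_mmhg = record$icp,
                   map_mmhg = record$map,
                   hr_bpm = record$hr,
                   phase = record$phases$phase[phase_idx])
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a subject traces CSV written by [write_subject_csv()]
#'
#' @param path CSV path.
#' @return Data frame with columns `time_s`, `icp_mmhg`, `map_mmhg`,
#'   `hr_bpm`, `phase`.
#' @export
read_subject_csv <- function(path) {
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
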