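#' Read a single-channel signal from disk
#'
#' Understands delimited text (one amplitude column, or time + amplitude
#' columns) and WFDB records (`.hea` header + `.dat` signal, formats 16 and
#' 212).  For one-column text the sampling rate comes from `fs`; for
#' two-column text it is inferred from the time spacing; for WFDB it comes
#' from the header.
#'
#' @param path File path.  For WFDB, the `.hea` file or the record name
#'   without extension.
#' @param format `"auto"` (by extension), `"csv"` (any delimited text), or
#'   `"wfdb"`.
#' @param fs Sampling rate assumed for one-column text files (default
#'   360 Hz, the MIT-BIH arrhythmia rate).
#' @param channel Channel to extract from multi-channel input (1-based).
#' @return A [signal_series()].
#' @export
read_signal <- function(path, format = c("auto", "csv", "wfdb"), fs = 360,
                        channel = 1L) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.hea$", path) || file.exists(paste0(path, ".hea")))
      "wfdb" else "csv"
  }
  if (format == "wfdb") return(read_wfdb(path, channel = channel))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else ""
  header <- !grepl("^\\s*[-+0-9.eE]+\\s*(,|\\s|$)", first)
  df <- utils::read.table(path, sep = sep, header = header)
  num <- df[vapply(df, is.numeric, logical(1))]
  if (ncol(num) == 0)
    stop("no numeric columns in ", path, " (unrecognised signal format)",
         call. = FALSE)
  if (ncol(num) == 1L) return(signal_series(num[[1L]], fs))
  t <- num[[1L]]
  dt <- diff(t)
  if (length(dt) < 1 || any(dt <= 0))
    stop("first column of ", path,
         " is not a strictly increasing time axis", call. = FALSE)
  signal_series(num[[min(channel + 1L, ncol(num))]],
                fs = 1 / stats::median(dt))
}

#' Write a signal as delimited text
#'
#' One amplitude per line at full double precision, so that
#' `read_signal(write_signal(x, path))` round-trips exactly.  The sampling
#' rate is recorded as a comment-free sidecar only by the CLI; the text
#' file itself holds amplitudes alone.
#'
#' @param x A `signal_series` or numeric vector.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_signal <- function(x, path) {
  writeLines(sprintf("%.17g", as.numeric(x)), path)
  invisible(path)
}

# --- minimal WFDB support (header + signal formats 16 and 212) ------------

parse_wfdb_header <- function(hea_path) {
  lines <- readLines(hea_path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  rec <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  nsig <- as.integer(rec[2])
  fs <- if (length(rec) >= 3) as.numeric(sub("/.*", "", rec[3])) else 250
  nsamp <- if (length(rec) >= 4) as.integer(rec[4]) else NA_integer_
  sig <- lapply(lines[1 + seq_len(nsig)], function(l) {
    tok <- strsplit(trimws(l), "\\s+")[[1]]
    gain_spec <- if (length(tok) >= 3) tok[3] else "200"
    gain <- as.numeric(sub("\\(.*", "", sub("/.*", "", gain_spec)))
    if (is.na(gain) || gain == 0) gain <- 200
    baseline <- if (grepl("\\(", gain_spec))
      as.numeric(sub(".*\\(([-0-9]+)\\).*", "\\1", gain_spec)) else NA
    adc_zero <- if (length(tok) >= 5) as.numeric(tok[5]) else 0
    list(file = tok[1],
         fmt = as.integer(sub("x.*|:.*|\\+.*", "", tok[2])),
         gain = gain,
         baseline = if (is.na(baseline)) adc_zero else baseline)
  })
  list(record = rec[1], nsig = nsig, fs = fs, nsamp = nsamp, signals = sig)
}

read_dat_16 <- function(path, nsig) {
  raw <- readBin(path, "integer", n = file.size(path) %/% 2L, size = 2L,
                 signed = TRUE, endian = "little")
  matrix(raw, ncol = nsig, byrow = TRUE)
}

read_dat_212 <- function(path, nsig, nsamp) {
  b <- as.integer(readBin(path, "raw", n = file.size(path)))
  ntrip <- length(b) %/% 3L
  i <- 3L * seq_len(ntrip)
  b0 <- b[i - 2L]; b1 <- b[i - 1L]; b2 <- b[i]
  s1 <- bitwAnd(b1, 15L) * 256L + b0        # low nibble of b1 is high bits
  s2 <- bitwAnd(b1, 240L) %/% 16L * 256L + b2
  tosigned <- function(v) ifelse(v > 2047L, v - 4096L, v)
  vals <- as.vector(rbind(tosigned(s1), tosigned(s2)))
  if (!is.na(nsamp)) vals <- vals[seq_len(nsamp * nsig)]
  matrix(vals, ncol = nsig, byrow = TRUE)
}

#' Read one channel of a WFDB record
#'
#' Minimal reader for the WFDB signal file convention: a text `.hea`
#' header naming the signal files, their storage format, gain and
#' baseline, plus binary `.dat` data in format 16 (16-bit little-endian)
#' or 212 (packed 12-bit pairs).  Digital values are converted to physical
#' units as `(adc - baseline) / gain`.
#'
#' @param record Path to the `.hea` file or the record name without
#'   extension.
#' @param channel Channel index (1-based).
#' @return A [signal_series()] in physical units.
#' @export
read_wfdb <- function(record, channel = 1L) {
  hea <- if (grepl("\\.hea$", record)) record else paste0(record, ".hea")
  if (!file.exists(hea)) stop("WFDB header not found: ", hea, call. = FALSE)
  hdr <- parse_wfdb_header(hea)
  if (channel < 1L || channel > hdr$nsig)
    stop("channel out of range for record ", hdr$record, call. = FALSE)
  sig <- hdr$signals[[channel]]
  dat <- file.path(dirname(hea), sig$file)
  if (!file.exists(dat)) stop("WFDB signal file not found: ", dat,
                              call. = FALSE)
  fmt <- hdr$signals[[1L]]$fmt
  adc <- switch(as.character(fmt),
    "16"  = read_dat_16(dat, hdr$nsig),
    "212" = read_dat_212(dat, hdr$nsig, hdr$nsamp),
    stop("unsupported WFDB signal format: ", fmt, call. = FALSE))
  if (!is.na(hdr$nsamp) && nrow(adc) > hdr$nsamp)
    adc <- adc[seq_len(hdr$nsamp), , drop = FALSE]
  signal_series((adc[, channel] - sig$baseline) / sig$gain, hdr$fs)
}

#' Write a single-channel WFDB record (format 16)
#'
#' Companion writer used for fixtures and round-trip tests: quantises the
#' physical signal as `round(x * gain) + baseline` into 16-bit samples.
#'
#' @param x A `signal_series` or numeric vector.
#' @param record Output record path without extension.
#' @param fs Sampling rate (taken from `x` when it carries one).
#' @param gain ADC units per physical unit.
#' @param baseline ADC value corresponding to 0 physical units.
#' @return The header path, invisibly.
#' @export
write_wfdb <- function(x, record, fs = NULL, gain = 200, baseline = 0) {
  v <- as.numeric(x)
  if (is.null(fs)) fs <- sampling_rate(x)
  adc <- as.integer(round(v * gain) + baseline)
  if (any(adc < -32768L | adc > 32767L))
    stop("signal overflows 16-bit storage at this gain", call. = FALSE)
  base <- basename(record)
  writeBin(adc, paste0(record, ".dat"), size = 2L, endian = "little")
  writeLines(c(
    sprintf("%s 1 %g %d", base, fs, length(v)),
    sprintf("%s.dat 16 %g(%d) 16 %d 0 0 0 ch1", base, gain, baseline,
            as.integer(baseline))
  ), paste0(record, ".hea"))
  invisible(paste0(record, ".hea"))
}
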