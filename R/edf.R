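# Minimal European Data Format (EDF, 16-bit) I/O sufficient for round-
# tripping the package's 19-channel recordings: fixed-layout ASCII header,
# one-second data records, little-endian int16 samples with per-signal
# physical scaling. Annotations, EDF+ and discontinuous records are out of
# scope.

pad_field <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = -width, flag = " ")
}

#' Write a recording as EDF
#'
#' @param rec an `eeg_recording`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  n_rec <- floor(ncol(rec$data) / fs)
  if (n_rec < 1) stopf("recording shorter than one 1-s data record")
  ns <- nrow(rec$data)
  phys_max <- pmax(apply(abs(rec$data[, seq_len(n_rec * fs), drop = FALSE]),
                         1, max), 1e-6)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8),
    pad_field(paste("X X X", rec$subject_id), 80),
    pad_field("Startdate X X X X", 80),
    pad_field("01.01.00", 8), pad_field("00.00.00", 8),
    pad_field(256 * (1 + ns), 8),
    pad_field("", 44),
    pad_field(n_rec, 8),
    pad_field(1, 8),
    pad_field(ns, 4),
    paste(vapply(rec$channels, function(l) pad_field(paste("EEG", l), 16), "")
          , collapse = ""),
    paste(rep(pad_field("AgAgCl electrode", 80), ns), collapse = ""),
    paste(rep(pad_field("uV", 8), ns), collapse = ""),
    paste(vapply(-phys_max, function(v) pad_field(sprintf("%.6g", v), 8), ""),
          collapse = ""),
    paste(vapply(phys_max, function(v) pad_field(sprintf("%.6g", v), 8), ""),
          collapse = ""),
    paste(rep(pad_field(-32767, 8), ns), collapse = ""),
    paste(rep(pad_field(32767, 8), ns), collapse = ""),
    paste(rep(pad_field("", 80), ns), collapse = ""),
    paste(rep(pad_field(fs, 8), ns), collapse = ""),
    paste(rep(pad_field("", 32), ns), collapse = ""))
  writeChar(hdr, con, eos = NULL)
  scale <- 32767 / phys_max
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    block <- round(rec$data[, idx, drop = FALSE] * scale)
    block <- pmin(pmax(block, -32767), 32767)
    # per-signal contiguous samples within each record
    writeBin(as.integer(t(block)), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf()]
#'
#' @param path EDF file path.
#' @return An `eeg_recording`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nchars) {
    raw <- readBin(con, "raw", nchars)
    trimws(rawToChar(raw))
  }
  rd(8)                       # version
  patient <- rd(80); rd(80); rd(8); rd(8)
  rd(8)                       # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  labels <- sub("^EEG ", "", labels)
  for (i in seq_len(ns)) rd(80)        # transducer
  for (i in seq_len(ns)) rd(8)         # phys dim
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80)        # prefilter
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1) stopf("mixed sampling rates unsupported")
  fs <- spr[1] / rec_dur
  data <- matrix(0, ns, n_rec * spr[1])
  gain <- (pmax_ - pmin_) / (dmax_ - dmin_)
  for (r in seq_len(n_rec)) {
    block <- readBin(con, "integer", ns * spr[1], size = 2, signed = TRUE,
                     endian = "little")
    block <- matrix(block, nrow = spr[1], ncol = ns)
    idx <- ((r - 1) * spr[1] + 1):(r * spr[1])
    data[, idx] <- t(sweep(sweep(block, 2, dmin_), 2, gain, `*`) +
                       matrix(pmin_, spr[1], ns, byrow = TRUE))
  }
  subject_id <- utils::tail(strsplit(patient, " ")[[1]], 1)
  structure(list(subject_id = subject_id, channels = labels, fs = fs,
                 duration = n_rec * rec_dur, data = data),
            class = "eeg_recording")
}
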