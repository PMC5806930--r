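# Minimal reader/writer for standard continuous 16-bit EDF (European Data
# Format): fixed-layout ASCII header of 256 + 256*ns bytes followed by data
# records of little-endian int16 samples, linearly scaled per channel between
# the digital and physical ranges. Only the subset needed here is supported:
# one uniform sampling rate, continuous recording, no EDF+ annotations signal.

#' @noRd
edf_field <- function(x, width) {
  s <- formatC(as.character(x), width = -width)
  substr(s, 1L, width)
}

#' Read an EDF file
#'
#' @param path Path to a 16-bit EDF file.
#' @return A list with `signal` (T x N matrix in physical units), `fs`, and
#'   channel `labels`. All channels must share one sampling rate.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- rawToChar(readBin(con, "raw", 256L))
  fld <- function(from, len) trimws(substr(hdr, from, from + len - 1L))
  n_rec <- as.integer(fld(237L, 8L))
  rec_dur <- as.numeric(fld(245L, 8L))
  ns <- as.integer(fld(253L, 4L))
  if (is.na(ns) || ns < 1L) stop("not a valid EDF header")
  sig_hdr <- rawToChar(readBin(con, "raw", 256L * ns))
  sfld <- function(block_from, width) {
    # per-signal fields are stored field-major: ns labels, then ns transducers...
    vapply(seq_len(ns), function(i)
      trimws(substr(sig_hdr, block_from + (i - 1L) * width,
                    block_from + i * width - 1L)), "")
  }
  labels <- sfld(1L, 16L)
  # per-signal fields, field-major order:
  # label(16) transducer(80) dim(8) pmin(8) pmax(8) dmin(8) dmax(8)
  # prefilter(80) samples-per-record(8) reserved(32)
  pos <- (16L + 80L + 8L) * ns + 1L
  phys_min <- as.numeric(sfld(pos, 8L));  pos <- pos + 8L * ns
  phys_max <- as.numeric(sfld(pos, 8L));  pos <- pos + 8L * ns
  dig_min <- as.numeric(sfld(pos, 8L));   pos <- pos + 8L * ns
  dig_max <- as.numeric(sfld(pos, 8L));   pos <- pos + 8L * ns + 80L * ns
  spr <- as.integer(sfld(pos, 8L))
  if (length(unique(spr)) != 1L)
    stop("sampling-rate mismatch across channels")
  fs <- spr[1L] / rec_dur
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  total <- n_rec * spr[1L]
  sig <- matrix(0, total, ns)
  for (r in seq_len(n_rec)) {
    d <- readBin(con, "integer", n = spr[1L] * ns, size = 2L,
                 signed = TRUE, endian = "little")
    rows <- (r - 1L) * spr[1L] + seq_len(spr[1L])
    sig[rows, ] <- matrix(d, ncol = ns)
  }
  for (j in seq_len(ns))
    sig[, j] <- phys_min[j] + (sig[, j] - dig_min[j]) * gain[j]
  list(signal = sig, fs = fs, labels = labels)
}

#' Write a session to a 16-bit EDF file
#'
#' Samples are linearly quantized to the int16 range per channel (relative
#' quantization error about 3e-5 of the channel range). The recording is
#' padded with zeros to a whole number of 1-second records.
#'
#' @param session A [recording_session()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(session, path) {
  stopifnot(inherits(session, "recording_session"))
  sig <- session$signal
  fs <- session$fs
  if (fs != round(fs)) stop("EDF export requires an integer sampling rate")
  ns <- ncol(sig)
  spr <- as.integer(fs)
  n_rec <- as.integer(ceiling(nrow(sig) / spr))
  if (n_rec * spr > nrow(sig)) {
    warning("padding final EDF record with zeros")
    sig <- rbind(sig, matrix(0, n_rec * spr - nrow(sig), ns))
  }
  phys_min <- apply(sig, 2L, min) - 1e-6
  phys_max <- apply(sig, 2L, max) + 1e-6
  dig_min <- -32768; dig_max <- 32767
  hdr <- paste0(
    edf_field("0", 8L), edf_field("synthetic", 80L), edf_field("ictalrank", 80L),
    edf_field("01.01.00", 8L), edf_field("00.00.00", 8L),
    edf_field(256L + 256L * ns, 8L), edf_field("", 44L),
    edf_field(n_rec, 8L), edf_field(1, 8L), edf_field(ns, 4L))
  blk <- function(vals, width) paste(vapply(vals, edf_field, "", width), collapse = "")
  sig_hdr <- paste0(
    blk(session$channel_labels, 16L), blk(rep("", ns), 80L),
    blk(rep("uV", ns), 8L),
    blk(sprintf("%.6g", phys_min), 8L), blk(sprintf("%.6g", phys_max), 8L),
    blk(rep(dig_min, ns), 8L), blk(rep(dig_max, ns), 8L),
    blk(rep("LP:100Hz", ns), 80L), blk(rep(spr, ns), 8L), blk(rep("", ns), 32L))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(hdr, sig_hdr)), con)
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  dig <- sig
  for (j in seq_len(ns))
    dig[, j] <- round((sig[, j] - phys_min[j]) / gain[j] + dig_min)
  storage.mode(dig) <- "integer"
  for (r in seq_len(n_rec)) {
    rows <- (r - 1L) * spr + seq_len(spr)
    writeBin(as.vector(dig[rows, ]), con, size = 2L, endian = "little")
  }
  invisible(path)
}
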