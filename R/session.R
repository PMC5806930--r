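#' Multichannel recording session
#'
#' Container for an ECoG recording: a `T x N` signal matrix, sampling rate,
#' channel labels tied to a grid layout, and annotations (seizure intervals,
#' exclusion intervals for artifacts, and the expert electrodes-of-interest).
#'
#' @param signal Numeric `T x N` matrix (microvolts), one column per channel.
#' @param fs Sampling rate in Hz (identical across channels).
#' @param grid A [grid_layout()]; `N` must equal `n_rows * n_cols`.
#' @param channel_labels Labels for the columns of `signal`; defaults to the
#'   grid labels in row-major order. Duplicates are rejected.
#' @param seizure_intervals,exclusion_intervals Lists or 2-column matrices of
#'   `(start, end)` times in seconds, half-open `[start, end)`.
#' @param eoi Character vector of expert electrode-of-interest labels.
#' @param soz_truth Optional ground-truth SOZ labels (synthetic sessions).
#' @return An object of class `recording_session`.
#' @export
recording_session <- function(signal, fs, grid, channel_labels = grid$labels,
                              seizure_intervals = NULL,
                              exclusion_intervals = NULL,
                              eoi = character(), soz_truth = NULL) {
  stopifnot(inherits(grid, "grid_layout"))
  signal <- as.matrix(signal)
  N <- grid$n_rows * grid$n_cols
  if (ncol(signal) != N)
    stop(sprintf("signal has %d channels but grid has %d electrodes",
                 ncol(signal), N))
  if (anyDuplicated(channel_labels)) stop("duplicate channel labels")
  if (length(channel_labels) != N) stop("channel_labels length mismatch")
  if (!all(channel_labels %in% grid$labels))
    stop("channel labels not on the grid: ",
         paste(setdiff(channel_labels, grid$labels), collapse = ", "))
  t_end <- nrow(signal) / fs
  sz <- as_interval_matrix(seizure_intervals, "seizure interval")
  ex <- as_interval_matrix(exclusion_intervals, "exclusion interval")
  if (intervals_overlap(sz)) stop("seizure intervals overlap")
  for (iv in list(sz, ex))
    if (nrow(iv) > 0L && (min(iv) < 0 || max(iv) > t_end + 1e-9))
      stop("annotated intervals outside the recording")
  eoi <- as.character(eoi)
  if (length(eoi) && !all(eoi %in% channel_labels))
    stop("EOI labels not among channels: ",
         paste(setdiff(eoi, channel_labels), collapse = ", "))
  colnames(signal) <- channel_labels
  structure(list(signal = signal, fs = fs, channel_labels = channel_labels,
                 grid = grid, seizure_intervals = sz,
                 exclusion_intervals = ex, eoi = eoi,
                 soz_truth = soz_truth),
            class = "recording_session")
}

#' @export
print.recording_session <- function(x, ...) {
  cat(sprintf(
    "<recording_session: %d channels (%dx%d grid), %.1f s @ %g Hz, %d seizure(s), %d EOI>\n",
    ncol(x$signal), x$grid$n_rows, x$grid$n_cols, nrow(x$signal) / x$fs,
    x$fs, nrow(x$seizure_intervals), length(x$eoi)))
  invisible(x)
}

#' Write a session to disk
#'
#' The native container is a pair of files: `<prefix>.json` (header with the
#' sampling rate, grid, channel labels and annotations) and `<prefix>.dat`
#' (little-endian float64 samples, channel-major). With `format = "edf"` a
#' standard 16-bit EDF file plus a `<prefix>.annotations.json` sidecar is
#' written instead.
#'
#' @param session A [recording_session()].
#' @param prefix Output path prefix (without extension).
#' @param format `"native"` or `"edf"`.
#' @return The header/EDF path, invisibly.
#' @export
write_session <- function(session, prefix, format = c("native", "edf")) {
  stopifnot(inherits(session, "recording_session"))
  format <- match.arg(format)
  if (format == "edf") {
    path <- paste0(prefix, ".edf")
    write_edf(session, path)
    jsonlite::write_json(session_annotations(session),
                         paste0(prefix, ".annotations.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(path))
  }
  header <- c(list(fs = session$fs,
                   n_samples = nrow(session$signal),
                   n_rows = session$grid$n_rows,
                   n_cols = session$grid$n_cols,
                   channel_labels = session$channel_labels,
                   data_file = basename(paste0(prefix, ".dat"))),
              session_annotations(session))
  jsonlite::write_json(header, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA)
  con <- file(paste0(prefix, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.vector(session$signal), con, size = 8L, endian = "little")
  invisible(paste0(prefix, ".json"))
}

#' @noRd
session_annotations <- function(session) {
  iv_list <- function(m) unname(lapply(seq_len(nrow(m)), function(i) m[i, ]))
  list(seizures = iv_list(session$seizure_intervals),
       exclusions = iv_list(session$exclusion_intervals),
       eoi = as.list(session$eoi),
       soz_truth = as.list(session$soz_truth %||% character()))
}

#' Load a session from disk
#'
#' Reads either the native container (pass the `.json` header path) or an EDF
#' file (pass the `.edf` path; a `<prefix>.annotations.json` sidecar carrying
#' the seizure/exclusion/EOI annotations is required). Channels present in the
#' file but absent from the layout are dropped with a warning; a layout
#' channel missing from the file is an error.
#'
#' @param path Path to a `.json` native header or `.edf` file.
#' @param layout_spec Optional [grid_layout()]. For native files the header
#'   already carries the grid; for EDF it is required.
#' @return A [recording_session()].
#' @export
load_session <- function(path, layout_spec = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.edf$", path, ignore.case = TRUE))
    return(load_session_edf(path, layout_spec))
  h <- jsonlite::read_json(path, simplifyVector = TRUE)
  grid <- layout_spec %||% grid_layout(h$n_rows, h$n_cols)
  dat <- file.path(dirname(path), h$data_file)
  if (!file.exists(dat)) stop("missing data file: ", dat)
  con <- file(dat, "rb")
  on.exit(close(con))
  n <- h$n_samples * length(h$channel_labels)
  x <- readBin(con, "double", n = n, size = 8L, endian = "little")
  if (length(x) != n) stop("truncated data file: ", dat)
  sig <- matrix(x, nrow = h$n_samples)
  recording_session(sig, h$fs, grid, channel_labels = h$channel_labels,
                    seizure_intervals = h$seizures,
                    exclusion_intervals = h$exclusions,
                    eoi = unlist(h$eoi) %||% character(),
                    soz_truth = if (length(h$soz_truth)) unlist(h$soz_truth))
}

#' @noRd
load_session_edf <- function(path, layout_spec) {
  if (is.null(layout_spec))
    stop("layout_spec (grid_layout) is required for EDF input")
  ann_path <- sub("\\.edf$", ".annotations.json", path, ignore.case = TRUE)
  if (!file.exists(ann_path))
    stop("missing annotation file: ", ann_path)
  edf <- read_edf(path)
  ann <- jsonlite::read_json(ann_path, simplifyVector = TRUE)
  keep <- edf$labels %in% layout_spec$labels
  if (!all(keep))
    warning("dropping channels not in the layout: ",
            paste(edf$labels[!keep], collapse = ", "))
  missing <- setdiff(layout_spec$labels, edf$labels)
  if (length(missing))
    stop("layout channels absent from the EDF: ",
         paste(missing, collapse = ", "))
  sig <- edf$signal[, keep, drop = FALSE]
  recording_session(sig, edf$fs, layout_spec,
                    channel_labels = edf$labels[keep],
                    seizure_intervals = ann$seizures,
                    exclusion_intervals = ann$exclusions,
                    eoi = unlist(ann$eoi) %||% character(),
                    soz_truth = if (length(ann$soz_truth)) unlist(ann$soz_truth))
}
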