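# Block extraction: the algorithm analyzes 10-second windows of two kinds,
# ictal blocks anchored at each annotated seizure start and rest blocks with
# uniformly random start times in the admissible (non-seizure, non-artifact)
# region. Sample indices are 0-based with half-open [start, end) windows.

#' Recording block
#'
#' A single fixed-length window of a session.
#'
#' @param data `T x N` numeric matrix.
#' @param fs Sampling rate in Hz.
#' @param start_time Window start in seconds from the session start.
#' @param label One of `"ictal"`, `"rest"`, `"pre_ictal"`.
#' @return An object of class `ecog_block`.
#' @export
ecog_block <- function(data, fs, start_time, label = c("rest", "ictal", "pre_ictal")) {
  label <- match.arg(label)
  structure(list(data = as.matrix(data), fs = fs,
                 start_time = start_time, label = label),
            class = "ecog_block")
}

#' @export
print.ecog_block <- function(x, ...) {
  cat(sprintf("<ecog_block %s: %d x %d @ %g Hz, t0 = %.2f s>\n",
              x$label, nrow(x$data), ncol(x$data), x$fs, x$start_time))
  invisible(x)
}

#' @noRd
slice_block <- function(session, start_time, block_length, label) {
  i0 <- round(start_time * session$fs)            # 0-based first sample
  n <- round(block_length * session$fs)
  ecog_block(session$signal[i0 + seq_len(n), , drop = FALSE],
             session$fs, start_time, label)
}

#' Extract the ictal block of each seizure
#'
#' One block per annotated seizure, starting exactly at the seizure start.
#' A seizure shorter than `block_length` still yields a full-length block
#' (the window extends past the seizure end, with a warning); a seizure
#' starting closer than `block_length` to the end of the recording is skipped
#' with a warning.
#'
#' @param session A [recording_session()].
#' @param block_length Window length in seconds (default 10).
#' @return A list of [ecog_block()]s with label `"ictal"`.
#' @export
extract_ictal_blocks <- function(session, block_length = 10) {
  stopifnot(inherits(session, "recording_session"))
  t_end <- nrow(session$signal) / session$fs
  sz <- session$seizure_intervals
  out <- list()
  for (r in seq_len(nrow(sz))) {
    s <- sz[r, 1L]; e <- sz[r, 2L]
    if (s + block_length > t_end + 1e-9) {
      warning(sprintf("seizure at %.1f s starts too close to the recording end; skipped", s))
      next
    }
    if (e - s < block_length)
      warning(sprintf("seizure at %.1f s is shorter than the block length; window extends past its end", s))
    out[[length(out) + 1L]] <- slice_block(session, s, block_length, "ictal")
  }
  out
}

#' Randomly sample rest blocks
#'
#' Start times are drawn uniformly from the admissible rest region: the
#' recording minus every seizure interval extended by `guard` seconds on each
#' side (and by the block length before its start), minus every exclusion
#' interval. Sampled blocks may overlap one another. Reproducible under a
#' fixed RNG state (or the optional `seed`).
#'
#' @param session A [recording_session()].
#' @param count Number of blocks to draw.
#' @param block_length Window length in seconds (default 10).
#' @param guard Peri-seizure guard band in seconds excluded on each side of
#'   every seizure (default 120).
#' @param seed Optional integer seed set before drawing.
#' @return A list of [ecog_block()]s with label `"rest"`.
#' @export
sample_rest_blocks <- function(session, count, block_length = 10,
                               guard = 120, seed = NULL) {
  stopifnot(inherits(session, "recording_session"))
  if (!is.null(seed)) set.seed(seed)
  iv <- admissible_rest_starts(session, block_length, guard)
  w <- iv[, 2L] - iv[, 1L]
  total <- sum(w)
  if (nrow(iv) == 0L || total <= 0)
    stop(sprintf(
      "admissible rest region is empty (need %g-s windows clear of seizures +/- %g s guard and exclusions)",
      block_length, guard))
  u <- runif(count, 0, total)
  edges <- cumsum(c(0, w))
  starts <- numeric(count)
  for (b in seq_len(count)) {
    k <- findInterval(u[b], edges, rightmost.closed = TRUE)
    starts[b] <- iv[k, 1L] + (u[b] - edges[k])
  }
  lapply(starts, function(s) slice_block(session, s, block_length, "rest"))
}

# Intervals of admissible rest-block *start* times.
#' @noRd
admissible_rest_starts <- function(session, block_length, guard) {
  t_end <- nrow(session$signal) / session$fs
  rem <- list()
  sz <- session$seizure_intervals
  for (r in seq_len(nrow(sz)))
    rem[[length(rem) + 1L]] <- c(sz[r, 1L] - guard - block_length,
                                 sz[r, 2L] + guard)
  ex <- session$exclusion_intervals
  for (r in seq_len(nrow(ex)))
    rem[[length(rem) + 1L]] <- c(ex[r, 1L] - block_length, ex[r, 2L])
  removals <- if (length(rem)) do.call(rbind, rem) else matrix(numeric(0), ncol = 2L)
  interval_complement(0, t_end - block_length, removals)
}
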