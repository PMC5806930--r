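# Small shared helpers: interval arithmetic on (start, end) second pairs
# (half-open [start, end) convention, 0-based sample indices) and seed chaining.

#' @noRd
as_interval_matrix <- function(x, what = "interval") {
  if (is.null(x) || length(x) == 0L)
    return(matrix(numeric(0), ncol = 2L))
  if (is.list(x)) x <- do.call(rbind, lapply(x, function(v) as.numeric(v)))
  x <- matrix(as.numeric(x), ncol = 2L)
  if (any(!is.finite(x))) stop(what, "s must be finite", call. = FALSE)
  if (any(x[, 2L] <= x[, 1L]))
    stop(what, "s must have end > start", call. = FALSE)
  x[order(x[, 1L]), , drop = FALSE]
}

#' @noRd
intervals_overlap <- function(iv) {
  if (nrow(iv) < 2L) return(FALSE)
  any(iv[-1L, 1L] < iv[-nrow(iv), 2L])
}

# Subtract a set of closed removal intervals from [lo, hi]; returns a matrix of
# the remaining (possibly empty) sub-intervals.
#' @noRd
interval_complement <- function(lo, hi, removals) {
  keep <- matrix(c(lo, hi), ncol = 2L)
  if (nrow(removals) == 0L) return(keep)
  removals <- removals[order(removals[, 1L]), , drop = FALSE]
  out <- list()
  cur <- lo
  for (r in seq_len(nrow(removals))) {
    a <- removals[r, 1L]; b <- removals[r, 2L]
    if (a > cur) out[[length(out) + 1L]] <- c(cur, min(a, hi))
    cur <- max(cur, b)
    if (cur >= hi) break
  }
  if (cur < hi) out[[length(out) + 1L]] <- c(cur, hi)
  if (length(out) == 0L) return(matrix(numeric(0), ncol = 2L))
  m <- do.call(rbind, out)
  m[m[, 2L] > m[, 1L], , drop = FALSE]
}

# Deterministic child seed for repetition `index` under a master seed; kept
# well inside the 32-bit signed range.
#' @noRd
derive_seed <- function(master, index) {
  (as.integer(master) %% 1000003L) * 2017L + as.integer(index) * 7L + 11L
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
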