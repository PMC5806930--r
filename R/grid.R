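#' Electrode grid layout
#'
#' Describes a rectangular ECoG electrode grid. Electrodes are labelled with the
#' row-digit / column-letter scheme used in clinical grid maps ("1A" is row 1,
#' column A), giving a bijection between (row, column) pairs and labels.
#'
#' @param n_rows,n_cols Grid dimensions (positive integers; at most 26 columns).
#' @return An object of class `grid_layout` with fields `n_rows`, `n_cols` and
#'   the full `labels` vector in row-major order.
#' @examples
#' g <- grid_layout(6, 8)
#' grid_label(g, 3, 2)          # "3B"
#' grid_coords(g, c("1A","6H"))
#' @export
grid_layout <- function(n_rows, n_cols) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (is.na(n_rows) || is.na(n_cols) || n_rows < 1L || n_cols < 1L)
    stop("grid dimensions must be positive integers")
  if (n_cols > 26L) stop("at most 26 columns supported by the letter scheme")
  labels <- as.vector(t(outer(seq_len(n_rows), LETTERS[seq_len(n_cols)], paste0)))
  structure(list(n_rows = n_rows, n_cols = n_cols, labels = labels),
            class = "grid_layout")
}

#' @rdname grid_layout
#' @param grid A `grid_layout`.
#' @param row,col Row and column indices.
#' @export
grid_label <- function(grid, row, col) {
  stopifnot(inherits(grid, "grid_layout"))
  if (any(row < 1L | row > grid$n_rows | col < 1L | col > grid$n_cols))
    stop("grid index out of range")
  paste0(row, LETTERS[col])
}

#' @rdname grid_layout
#' @param labels Character vector of electrode labels.
#' @return `grid_coords()` returns a two-column matrix of (row, col) indices.
#' @export
grid_coords <- function(grid, labels) {
  stopifnot(inherits(grid, "grid_layout"))
  m <- regmatches(labels, regexec("^([0-9]+)([A-Z])$", labels))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) stop("unknown electrode label(s): ",
                     paste(labels[bad], collapse = ", "))
  row <- as.integer(vapply(m, `[`, "", 2L))
  col <- match(vapply(m, `[`, "", 3L), LETTERS)
  if (any(row < 1L | row > grid$n_rows | col > grid$n_cols))
    stop("label(s) outside the grid: ",
         paste(labels[row < 1L | row > grid$n_rows | col > grid$n_cols],
               collapse = ", "))
  cbind(row = row, col = col)
}

#' @export
print.grid_layout <- function(x, ...) {
  cat(sprintf("<grid_layout %d x %d, %d electrodes (%s .. %s)>\n",
              x$n_rows, x$n_cols, x$n_rows * x$n_cols,
              x$labels[1L], x$labels[length(x$labels)]))
  invisible(x)
}
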