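# Visualization: heat maps of estimated causal-influence graphs and grid maps
# contrasting the expert EOI (bold annulus) with the inferred set (solid
# markers).

#' Heat map of a causal-influence graph
#'
#' Entry `(i, j)` shows the estimated influence of node `i` on node `j`; the
#' zeroed diagonal appears as the coolest colour.
#'
#' @param graph A [causal_graph()].
#' @param file Optional PNG path; when `NULL`, draws on the current device.
#' @param main Plot title.
#' @export
plot_graph_heatmap <- function(graph, file = NULL,
                               main = sprintf("%s causal-influence graph",
                                              graph$measure)) {
  stopifnot(inherits(graph, "causal_graph"))
  if (!is.null(file)) {
    grDevices::png(file, width = 720, height = 640)
    on.exit(grDevices::dev.off())
  }
  W <- graph$weights
  N <- nrow(W)
  # orient so row i runs top to bottom, like a matrix
  graphics::image(seq_len(N), seq_len(N), t(W[N:1, , drop = FALSE]),
                  col = grDevices::hcl.colors(64, "viridis"),
                  axes = FALSE, xlab = "influenced node j",
                  ylab = "influencing node i", main = main)
  at <- unique(round(seq(1, N, length.out = min(N, 8L))))
  graphics::axis(1L, at = at, labels = graph$labels[at], las = 2, cex.axis = 0.7)
  graphics::axis(2L, at = at, labels = graph$labels[rev(seq_len(N))][at],
                 las = 2, cex.axis = 0.7)
  graphics::box()
  invisible(graph)
}

#' Grid map of EOI and inferred electrodes
#'
#' Draws the electrode grid with the expert EOI marked by a bold annulus and
#' the inferred nodes by solid markers.
#'
#' @param grid A [grid_layout()].
#' @param eoi,inferred Character vectors of labels (either may be empty).
#' @param file Optional PNG path.
#' @export
plot_grid_map <- function(grid, eoi = character(), inferred = character(),
                          file = NULL) {
  stopifnot(inherits(grid, "grid_layout"))
  if (!is.null(file)) {
    grDevices::png(file, width = 90 * grid$n_cols + 120,
                   height = 90 * grid$n_rows + 120)
    on.exit(grDevices::dev.off())
  }
  co <- grid_coords(grid, grid$labels)
  x <- co[, 2L]; y <- grid$n_rows + 1L - co[, 1L]
  graphics::plot(x, y, type = "n", axes = FALSE, xlab = "", ylab = "",
                 xlim = c(0.5, grid$n_cols + 0.5),
                 ylim = c(0.5, grid$n_rows + 0.5), asp = 1)
  graphics::points(x, y, pch = 21, cex = 3.2, bg = "grey95", col = "grey60")
  if (length(inferred)) {
    i <- match(inferred, grid$labels)
    graphics::points(x[i], y[i], pch = 19, cex = 2.6, col = "#8B4513")
  }
  if (length(eoi)) {
    i <- match(eoi, grid$labels)
    graphics::points(x[i], y[i], pch = 1, cex = 3.8, lwd = 4)
  }
  graphics::text(x, y, grid$labels, cex = 0.7)
  invisible(grid)
}
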