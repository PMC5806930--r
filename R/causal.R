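# Causal-influence graph estimation: for every ordered channel pair, either a
# k-NN estimate of the directed-information rate (conditional mutual
# information of the target's present given both pasts) or pairwise Granger
# causality (log residual-variance ratio). Graphs from multiple seizures are
# combined by element-wise averaging.

#' Estimator parameters
#'
#' @param measure `"DI"` (k-NN directed information) or `"GC"` (pairwise
#'   Granger causality).
#' @param m Memory (Markov) order of the delay embedding for DI (default 2).
#' @param k Neighbour count of the k-NN estimator (default 4).
#' @param gc_order AR order for GC, or `"auto"` to resolve by BIC over orders
#'   1..10 on the reduced (target-only) model. Default 2.
#' @param clip_negative Clip negative pair estimates at 0 (default `TRUE`);
#'   required for the probabilistic normalization of the ranking stage.
#' @param thin Time-thinning factor applied to blocks before DI embedding
#'   (default 2: 200 Hz blocks are embedded at 100 Hz, so `m = 2` spans 20 ms
#'   of history, a typical cortico-cortical interaction latency). Controls the
#'   effective memory span and the estimation cost; ignored by GC.
#' @param n_centers Number of strided evaluation centers over which the DI
#'   conditional-MI average is taken (default 96); neighbours are always
#'   searched over all embedded points.
#' @return An object of class `estimator_params`.
#' @export
estimator_params <- function(measure = c("DI", "GC"), m = 2L, k = 4L,
                             gc_order = 2L, clip_negative = TRUE,
                             thin = 2L, n_centers = 96L) {
  measure <- match.arg(toupper(measure[1L]), c("DI", "GC"))
  m <- as.integer(m); k <- as.integer(k)
  if (m < 1L) stop("m must be >= 1")
  if (k < 1L) stop("k must be >= 1")
  if (!identical(gc_order, "auto")) {
    gc_order <- as.integer(gc_order)
    if (is.na(gc_order) || gc_order < 1L) stop("gc_order must be >= 1 or \"auto\"")
  }
  structure(list(measure = measure, m = m, k = k, gc_order = gc_order,
                 clip_negative = isTRUE(clip_negative),
                 thin = as.integer(thin), n_centers = as.integer(n_centers)),
            class = "estimator_params")
}

#' Causal-influence graph container
#'
#' An `N x N` nonnegative weight matrix with zero diagonal; entry `[i, j]`
#' quantifies the causal influence of channel `i` on channel `j` (nats for DI,
#' log variance ratio for GC).
#'
#' @param weights Nonnegative `N x N` matrix, zero diagonal.
#' @param measure `"DI"` or `"GC"`.
#' @param labels Node labels (defaults to the matrix dimnames).
#' @return An object of class `causal_graph`.
#' @export
causal_graph <- function(weights, measure, labels = NULL) {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights)) stop("weights must be square")
  if (any(!is.finite(weights))) stop("graph weights must be finite")
  if (any(weights < 0)) stop("graph weights must be nonnegative")
  if (any(diag(weights) != 0)) stop("graph diagonal must be zero")
  labels <- labels %||% rownames(weights) %||%
    paste0("n", seq_len(nrow(weights)))
  dimnames(weights) <- list(labels, labels)
  structure(list(weights = weights, measure = measure, labels = labels),
            class = "causal_graph")
}

#' @export
print.causal_graph <- function(x, ...) {
  cat(sprintf("<causal_graph %s: %d nodes, total weight %.4g>\n",
              x$measure, nrow(x$weights), sum(x$weights)))
  invisible(x)
}

#' Pairwise Granger causality
#'
#' Returns `ln(sigma2_reduced / sigma2_full)` where the reduced model regresses
#' `y` on its own `gc_order` lags and the full model adds `gc_order` lags of
#' `x`. Inputs are expected standardized (the statistic is invariant to
#' per-channel affine rescaling).
#'
#' @param x,y Equal-length numeric series (`x` the putative cause).
#' @param params An [estimator_params()]; uses `gc_order` and `clip_negative`.
#' @return A single nonnegative weight (negative estimates clipped at 0 when
#'   `clip_negative`).
#' @export
estimate_gc_pair <- function(x, y, params = estimator_params("GC")) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  x <- x - mean(x)  # no intercept in the lag regressions, so center here;
  y <- y - mean(y)  # together with the variance ratio this gives exact
                    # invariance to per-channel affine rescaling
  p <- resolve_gc_order(matrix(y, ncol = 1L), params$gc_order)
  if (length(y) <= 2L * p)
    stop("series length must exceed 2 * gc_order")
  g <- gc_graph_cpp(cbind(x, y), as.integer(c(p, p)))[1L, 2L]
  if (params$clip_negative) max(g, 0) else g
}

# Per-target-channel AR order: fixed, or BIC over 1..10 on the reduced model.
#' @noRd
resolve_gc_order <- function(X, gc_order, pmax = 10L) {
  N <- ncol(X)
  if (!identical(gc_order, "auto")) return(rep(as.integer(gc_order), N))
  rss <- gc_reduced_rss_cpp(X, pmax)
  Te <- nrow(X) - pmax
  bic <- log(rss / Te) * Te + outer(rep(1, N), seq_len(pmax)) * log(Te)
  as.integer(apply(bic, 1L, which.min))
}

#' k-NN directed information
#'
#' Estimates the per-sample directed-information rate from `x` to `y` as the
#' conditional mutual information `I(Y_t ; X_{t-m..t-1} | Y_{t-m..t-1})`,
#' averaged over `n_centers` strided time points, using max-norm neighbour
#' counts with digamma correction (Frenzel-Pompe / KSG construction). The
#' estimate is invariant in distribution to strictly monotone per-channel
#' transformations.
#'
#' @inheritParams estimate_gc_pair
#' @param params An [estimator_params()]; uses `m`, `k`, `n_centers`,
#'   `clip_negative`. No thinning is applied to directly supplied series.
#' @return A single nonnegative weight in nats.
#' @export
estimate_di_pair <- function(x, y, params = estimator_params("DI")) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) - params$m < params$k + 1L)
    stop("series too short for the requested k and m")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("non-finite values in the embedded series")
  v <- cmi_knn_cpp(as.numeric(x), as.numeric(y), params$m, params$k,
                   params$n_centers)
  if (params$clip_negative) max(v, 0) else v
}

#' Estimate the causal-influence graph of a block
#'
#' All `N (N - 1)` ordered channel pairs are estimated with the selected
#' measure; the diagonal is zero. Deterministic given the block and
#' parameters. For DI the block is first thinned in time by `params$thin`.
#'
#' @param block A preprocessed (band-limited, standardized) [ecog_block()].
#' @param params An [estimator_params()].
#' @return A [causal_graph()].
#' @export
estimate_graph <- function(block, params) {
  stopifnot(inherits(block, "ecog_block"), inherits(params, "estimator_params"))
  X <- block$data
  if (params$measure == "DI") {
    if (params$thin > 1L)
      X <- X[seq(1L, nrow(X), by = params$thin), , drop = FALSE]
    W <- di_graph_cpp(X, params$m, params$k, params$n_centers)
  } else {
    orders <- resolve_gc_order(X, params$gc_order)
    W <- gc_graph_cpp(X, orders)
  }
  W[W < 0] <- 0  # graph assembly always clips: ranking needs nonnegative weights
  diag(W) <- 0
  causal_graph(W, params$measure, colnames(block$data))
}

#' Average causal graphs across seizures
#'
#' Element-wise arithmetic mean; all graphs must share shape and measure.
#'
#' @param graphs Non-empty list of [causal_graph()]s.
#' @return A [causal_graph()].
#' @export
average_graphs <- function(graphs) {
  if (length(graphs) == 0L) stop("need at least one graph")
  if (length(unique(vapply(graphs, function(g) g$measure, ""))) != 1L)
    stop("cannot average graphs with mixed measures")
  dims <- vapply(graphs, function(g) nrow(g$weights), 1L)
  if (length(unique(dims)) != 1L) stop("cannot average graphs of mixed shapes")
  W <- Reduce(`+`, lapply(graphs, function(g) g$weights)) / length(graphs)
  causal_graph(W, graphs[[1L]]$measure, graphs[[1L]]$labels)
}

#' Write / read a graph as labelled TSV
#'
#' @param graph A [causal_graph()].
#' @param path Output path.
#' @export
write_graph_tsv <- function(graph, path) {
  stopifnot(inherits(graph, "causal_graph"))
  df <- data.frame(node = graph$labels, graph$weights, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_graph_tsv
#' @param measure Measure tag to attach on read.
#' @export
read_graph_tsv <- function(path, measure = "DI") {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  W <- as.matrix(df[, -1L, drop = FALSE])
  rownames(W) <- df[[1L]]
  causal_graph(W, measure, df[[1L]])
}
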