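# Node ranking: authority scores from a personalized PageRank on the
# causal-influence graph, hub scores from Reverse PageRank (the same recursion
# on the transposed graph with the outflow teleportation vector), and the
# final per-node score s = h - a. The fixed point is obtained by a direct
# dense linear solve; power iteration serves as an independent oracle in the
# test suite.

#' Column-stochastic transition matrix of a graph
#'
#' `P[j, i] = G[i, j] / rowsum_i(G)`: column `i` of `P` is row `i` of the
#' weight matrix normalized to a probability vector. Any zero column (a node
#' with no outgoing weight) is replaced by the uniform vector `1/N`.
#'
#' @param G A [causal_graph()] or a nonnegative zero-diagonal matrix.
#' @return An `N x N` column-stochastic matrix.
#' @export
transition_matrix <- function(G) {
  W <- graph_weights(G)
  rs <- rowSums(W)
  P <- t(W / ifelse(rs > 0, rs, 1))
  P[, rs == 0] <- 1 / nrow(W)
  P
}

#' @noRd
graph_weights <- function(G) {
  W <- if (inherits(G, "causal_graph")) G$weights else as.matrix(G)
  if (any(W < 0)) stop("graph weights must be nonnegative")
  if (any(diag(W) != 0)) stop("graph diagonal must be zero")
  W
}

#' Teleportation (personalization) vector
#'
#' Soft personalization by total flow: in authority mode node `i` gets weight
#' proportional to its total incoming flow (column sum), in hub mode to its
#' total outgoing flow (row sum); both normalized by the total graph weight.
#'
#' @param G A [causal_graph()] or weight matrix with at least one positive entry.
#' @param mode `"authority"` or `"hub"`.
#' @return A probability vector of length `N`.
#' @export
teleportation_vector <- function(G, mode = c("authority", "hub")) {
  mode <- match.arg(mode)
  W <- graph_weights(G)
  tot <- sum(W)
  if (tot <= 0) stop("teleportation undefined for an all-zero graph")
  if (mode == "authority") colSums(W) / tot else rowSums(W) / tot
}

#' Damped PageRank scores
#'
#' Solves `(I - alpha P) a = (1 - alpha) v` for the unique probability vector
#' `a`, the stationary distribution of the teleporting random walk
#' `alpha P + (1 - alpha) v e^T`. As `alpha` approaches 0 the solution
#' approaches `v` (the normalized flow); larger `alpha` weights the graph
#' structure more.
#'
#' @param P Column-stochastic matrix (see [transition_matrix()]).
#' @param v Teleportation probability vector.
#' @param alpha Damping factor in (0, 1); default 0.85.
#' @return A nonnegative vector summing to 1.
#' @export
pagerank_scores <- function(P, v, alpha = 0.85) {
  P <- as.matrix(P)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (any(abs(colSums(P) - 1) > 1e-8)) stop("P must be column-stochastic")
  if (abs(sum(v) - 1) > 1e-8 || any(v < 0)) stop("v must be a probability vector")
  a <- solve(diag(nrow(P)) - alpha * P, (1 - alpha) * v)
  a / sum(a)  # guard tiny numerical drift; exact to ~1e-15 already
}

#' Hub, authority and final node scores
#'
#' Authority scores come from the PageRank of the graph with the inflow
#' teleportation vector; hub scores from the PageRank of the transposed graph
#' with the outflow vector; the score of node `i` is `s_i = h_i - a_i`, the
#' net flow of causal influence while accounting for the graph structure.
#' Scores are invariant to positive rescaling of the graph, and identically
#' zero for symmetric graphs.
#'
#' @param G A [causal_graph()] or weight matrix, not all-zero.
#' @param alpha Damping factor (default 0.85).
#' @return An object of class `score_vector`: list with authority `a`, hub
#'   `h`, score `s` (sums to 0), teleportation vectors `va`, `vh`, `alpha`,
#'   and node `labels`.
#' @export
node_scores <- function(G, alpha = 0.85) {
  W <- graph_weights(G)
  labels <- rownames(W) %||% paste0("n", seq_len(nrow(W)))
  va <- teleportation_vector(W, "authority")
  vh <- teleportation_vector(W, "hub")
  a <- pagerank_scores(transition_matrix(W), va, alpha)
  h <- pagerank_scores(transition_matrix(t(W)), vh, alpha)
  structure(list(a = setNames(a, labels), h = setNames(h, labels),
                 s = setNames(h - a, labels), va = va, vh = vh,
                 alpha = alpha, labels = labels),
            class = "score_vector")
}

#' @export
print.score_vector <- function(x, ...) {
  top <- order(x$s, decreasing = TRUE)[seq_len(min(5L, length(x$s)))]
  cat(sprintf("<score_vector: %d nodes, alpha = %g; top: %s>\n",
              length(x$s), x$alpha,
              paste(sprintf("%s (%+.4f)", x$labels[top], x$s[top]),
                    collapse = ", ")))
  invisible(x)
}

#' Write node scores to TSV
#'
#' @param scores A [node_scores()] result.
#' @param path Output path.
#' @export
write_scores_tsv <- function(scores, path) {
  stopifnot(inherits(scores, "score_vector"))
  write.table(data.frame(node = scores$labels, authority = scores$a,
                         hub = scores$h, score = scores$s),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
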