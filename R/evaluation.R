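# Evaluation against the expert electrodes-of-interest (EOI): an inference is
# successful when more than half of the inferred nodes fall inside the EOI or
# its strictly adjacent ring; the false-positive detection rate divides the
# inferred nodes outside that protected set by all nodes outside it. Both
# depend only on set membership, never on score magnitudes.

#' Nodes strictly adjacent to the EOI
#'
#' All grid nodes within the chosen neighbourhood of any EOI node, excluding
#' the EOI nodes themselves. Default is the 8-neighbourhood (queen adjacency).
#'
#' @param grid A [grid_layout()].
#' @param eoi Non-empty character vector of EOI labels.
#' @param adjacency `"queen"` (8-neighbourhood, default) or `"rook"`
#'   (4-neighbourhood).
#' @return Character vector of adjacent node labels.
#' @export
adjacent_set <- function(grid, eoi, adjacency = c("queen", "rook")) {
  adjacency <- match.arg(adjacency)
  if (length(eoi) == 0L) stop("eoi must be non-empty")
  co <- grid_coords(grid, eoi)
  all_co <- grid_coords(grid, grid$labels)
  near <- rep(FALSE, length(grid$labels))
  for (i in seq_len(nrow(co))) {
    dr <- abs(all_co[, 1L] - co[i, 1L])
    dc <- abs(all_co[, 2L] - co[i, 2L])
    near <- near | if (adjacency == "queen") (dr <= 1L & dc <= 1L)
                   else (dr + dc <= 1L)
  }
  setdiff(grid$labels[near], eoi)
}

#' @noRd
protected_set <- function(grid, eoi, adjacency = "queen") {
  union(eoi, adjacent_set(grid, eoi, adjacency))
}

#' Is an inference successful?
#'
#' `TRUE` iff strictly more than 50% of the inferred nodes lie in the EOI or
#' its strictly adjacent nodes. An empty inference is not successful. Exactly
#' 50% overlap is not successful.
#'
#' @param inferred Character vector of inferred node labels.
#' @param eoi Character vector of EOI labels.
#' @param grid A [grid_layout()].
#' @param adjacency Passed to [adjacent_set()].
#' @return Logical flag.
#' @export
success <- function(inferred, eoi, grid, adjacency = "queen") {
  if (length(inferred) == 0L) return(FALSE)
  grid_coords(grid, inferred)  # label validation
  prot <- protected_set(grid, eoi, adjacency)
  length(intersect(inferred, prot)) / length(inferred) > 0.5
}

#' False-positive detection rate
#'
#' The number of inferred nodes outside the protected set (EOI plus strictly
#' adjacent nodes) divided by the number of grid nodes outside it.
#'
#' @inheritParams success
#' @return A rate in `[0, 1]`.
#' @export
false_positive_rate <- function(inferred, eoi, grid, adjacency = "queen") {
  if (length(inferred)) grid_coords(grid, inferred)
  prot <- protected_set(grid, eoi, adjacency)
  denom <- length(setdiff(grid$labels, prot))
  if (denom == 0L) stop("protected set covers the whole grid; rate undefined")
  length(setdiff(inferred, prot)) / denom
}

#' Evaluate an inference against the EOI ground truth
#'
#' @param inferred Character vector of inferred labels (or a `soz_inference`).
#' @param eoi EOI labels.
#' @param grid A [grid_layout()].
#' @param adjacency Passed to [adjacent_set()].
#' @return An `evaluation_result`: `success` flag, `Vp` rate, the
#'   `protected_set` and the `inferred` set.
#' @export
evaluate_inference <- function(inferred, eoi, grid, adjacency = "queen") {
  if (inherits(inferred, "soz_inference")) inferred <- inferred$S
  prot <- protected_set(grid, eoi, adjacency)
  structure(list(success = success(inferred, eoi, grid, adjacency),
                 Vp = false_positive_rate(inferred, eoi, grid, adjacency),
                 protected_set = prot, inferred = inferred),
            class = "evaluation_result")
}

#' Net-flow baseline scores
#'
#' Baseline ranker: the score of a node is the sum of its outgoing edge
#' weights minus the sum of its incoming edge weights (one-step flow only,
#' ignoring graph structure). Unlike the PageRank scores it scales linearly
#' with the graph.
#'
#' @param G A [causal_graph()] or weight matrix.
#' @return Named numeric score vector.
#' @export
netflow_scores <- function(G) {
  W <- graph_weights(G)
  setNames(rowSums(W) - colSums(W),
           rownames(W) %||% paste0("n", seq_len(nrow(W))))
}

#' Cohort summary
#'
#' @param results List of [evaluate_inference()] results.
#' @return Named vector: fraction of successful inferences and mean
#'   false-positive detection rate.
#' @export
cohort_summary <- function(results) {
  if (length(results) == 0L) stop("need at least one result")
  c(success_rate = mean(vapply(results, function(r) r$success, TRUE)),
    mean_Vp = mean(vapply(results, function(r) r$Vp, 1.0)))
}
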