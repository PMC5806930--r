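# SOZ inference: candidate nodes in the top p0 percentile of the ictal
# scores, intersected with nodes significant against a per-node empirical
# null built from repeated random draws of rest blocks; the directed-
# information graph is tried first, with a Granger-causality fallback
# (including its own null) when the DI pass selects nothing.

#' Inference parameters
#'
#' @param p0 Top-percentile for the candidate set S0 (default 10).
#' @param p1 Top-percentile of the per-node empirical null for the
#'   significant set S1 (default 5). `p1 = 100` disables the null comparison.
#' @param reps Number of independent null repetitions R (default 200).
#' @param alpha PageRank damping factor (default 0.85).
#' @param block_length Analyzed window length in seconds (default 10).
#' @param guard Peri-seizure guard band for rest sampling, seconds (default 120).
#' @param cutoff,target_fs Preprocessing band edge and output rate
#'   (defaults 100 Hz, 200 Hz).
#' @param di,gc Per-measure [estimator_params()].
#' @param seed Master seed; child seeds are derived deterministically per
#'   null repetition.
#' @return An object of class `inference_params`.
#' @export
inference_params <- function(p0 = 10, p1 = 5, reps = 200L, alpha = 0.85,
                             block_length = 10, guard = 120,
                             cutoff = 100, target_fs = 200,
                             di = estimator_params("DI"),
                             gc = estimator_params("GC"),
                             seed = 1L) {
  if (p0 <= 0 || p0 > 100 || p1 <= 0 || p1 > 100)
    stop("p0 and p1 must be in (0, 100]")
  structure(list(p0 = p0, p1 = p1, reps = as.integer(reps), alpha = alpha,
                 block_length = block_length, guard = guard,
                 cutoff = cutoff, target_fs = target_fs,
                 di = di, gc = gc, seed = as.integer(seed)),
            class = "inference_params")
}

#' @noRd
preprocess_block <- function(block, params) {
  standardize(band_limit(block, cutoff = params$cutoff,
                         target_fs = params$target_fs))
}

#' Top-percentile candidate set
#'
#' Returns the nodes whose score is at or above the `(100 - p0)`-th
#' percentile of the score vector (linear-interpolation percentile; ties at
#' the threshold are all included).
#'
#' @param s Named numeric score vector (or a [node_scores()] result).
#' @param p0 Percentile in (0, 100].
#' @return Character vector of node labels.
#' @export
top_percentile_set <- function(s, p0) {
  if (inherits(s, "score_vector")) s <- s$s
  if (length(s) == 0L) stop("empty score vector")
  if (any(!is.finite(s))) stop("scores must be finite")
  q <- quantile(s, 1 - p0 / 100, type = 7, names = FALSE)
  labs <- names(s) %||% as.character(seq_along(s))
  labs[s >= q]
}

#' Empirical null distribution of node scores
#'
#' For each of `R` repetitions, draws `N_S` (the session's seizure count)
#' random rest blocks, preprocesses them, estimates one causal graph per
#' block with the given measure, averages the graphs and computes node
#' scores; the collected columns form the per-node empirical null. A
#' repetition that fails (e.g. a flat channel in a sampled block) is redrawn,
#' with the event counted.
#'
#' @param session A [recording_session()].
#' @param measure `"DI"` or `"GC"`.
#' @param params An [inference_params()].
#' @param seed Master seed (defaults to `params$seed`).
#' @param score_fun Function mapping a [causal_graph()] to a numeric score
#'   vector; default is the hub-minus-authority score of [node_scores()].
#' @return An object of class `score_null`: `samples` (`N x R` matrix),
#'   per-repetition averaged `graphs`, the `measure`, `seed` and the count of
#'   `resampled` failed repetitions.
#' @export
build_null <- function(session, measure, params, seed = params$seed,
                       score_fun = NULL) {
  stopifnot(inherits(session, "recording_session"),
            inherits(params, "inference_params"))
  score_fun <- score_fun %||% function(g) node_scores(g, params$alpha)$s
  est <- if (toupper(measure) == "DI") params$di else params$gc
  n_s <- nrow(session$seizure_intervals)
  if (n_s < 1L) stop("session has no annotated seizures")
  N <- ncol(session$signal)
  samples <- matrix(NA_real_, N, params$reps,
                    dimnames = list(session$channel_labels, NULL))
  graphs <- vector("list", params$reps)
  resampled <- 0L
  for (r in seq_len(params$reps)) {
    for (attempt in seq_len(10L)) {
      set.seed(derive_seed(seed, r * 101L + attempt))
      ok <- tryCatch({
        blocks <- sample_rest_blocks(session, n_s, params$block_length,
                                     guard = params$guard)
        gs <- lapply(blocks, function(b)
          estimate_graph(preprocess_block(b, params), est))
        graphs[[r]] <- average_graphs(gs)
        samples[, r] <- score_fun(graphs[[r]])
        TRUE
      }, error = function(e) {
        if (grepl("admissible rest region", conditionMessage(e))) stop(e)
        FALSE
      })
      if (ok) break
      resampled <- resampled + 1L
      if (attempt == 10L) stop("null repetition failed 10 consecutive redraws")
    }
  }
  structure(list(samples = samples, graphs = graphs,
                 measure = toupper(measure), seed = seed,
                 resampled = resampled),
            class = "score_null")
}

#' Recompute null scores with a different scorer
#'
#' Reuses the stored per-repetition averaged graphs (same rest-block draws)
#' and applies a new graph-to-scores function, e.g. [netflow_scores()] for
#' the baseline comparison.
#'
#' @param null A [build_null()] result with stored graphs.
#' @param score_fun Function mapping a [causal_graph()] to a score vector.
#' @return A `score_null` with recomputed `samples`.
#' @export
rescore_null <- function(null, score_fun) {
  stopifnot(inherits(null, "score_null"))
  samples <- vapply(null$graphs, score_fun, numeric(nrow(null$samples)))
  dimnames(samples) <- dimnames(null$samples)
  out <- null
  out$samples <- samples
  out
}

#' Nodes significant against their empirical null
#'
#' Returns the nodes whose ictal score is at or above the `(100 - p1)`-th
#' percentile of their own null row.
#'
#' @param s Named score vector (or [node_scores()] result).
#' @param null A [build_null()] result.
#' @param p1 Percentile in (0, 100].
#' @return Character vector of node labels.
#' @export
significant_set <- function(s, null, p1) {
  if (inherits(s, "score_vector")) s <- s$s
  stopifnot(inherits(null, "score_null"))
  if (length(s) != nrow(null$samples))
    stop("score vector and null have different numbers of nodes")
  if (ncol(null$samples) < 20L)
    warning("fewer than 20 null repetitions; tail percentile is coarse")
  q <- apply(null$samples, 1L, quantile, probs = 1 - p1 / 100,
             type = 7, names = FALSE)
  labs <- names(s) %||% rownames(null$samples)
  labs[s >= q]
}

#' @noRd
soz_single_measure <- function(session, measure, params) {
  est <- if (measure == "DI") params$di else params$gc
  ictal <- extract_ictal_blocks(session, params$block_length)
  if (length(ictal) == 0L) stop("no usable ictal blocks")
  gs <- lapply(ictal, function(b)
    estimate_graph(preprocess_block(b, params), est))
  G <- average_graphs(gs)
  scores <- node_scores(G, params$alpha)
  S0 <- top_percentile_set(scores$s, params$p0)
  if (params$p1 >= 100) {
    null <- NULL
    S1 <- scores$labels
  } else {
    null <- build_null(session, measure, params)
    S1 <- significant_set(scores$s, null, params$p1)
  }
  list(graph = G, scores = scores, S0 = S0, S1 = S1,
       S = intersect(S0, S1), null = null)
}

#' Infer the seizure onset zone
#'
#' Full inference pipeline: ictal blocks are preprocessed and turned into
#' per-seizure DI graphs, averaged, and scored; the inferred set is the
#' intersection of the top-`p0`-percentile candidate set S0 with the set S1
#' of nodes significant at level `p1` against the rest-block empirical null.
#' If that intersection is empty the whole procedure is repeated with the GC
#' measure (building a GC null); the result is then returned even if empty.
#'
#' @param session A [recording_session()] with at least one seizure.
#' @param params An [inference_params()].
#' @return An object of class `soz_inference`: sets `S0`, `S1`,
#'   `S = S0 intersect S1`, `measure_used`, `scores`, `null`, the averaged
#'   ictal `graph`, per-measure `details`, and the `params`.
#' @export
infer_soz <- function(session, params = inference_params()) {
  stopifnot(inherits(session, "recording_session"))
  if (nrow(session$seizure_intervals) < 1L)
    stop("session has no annotated seizures; the SOZ is not localizable")
  details <- list()
  res <- soz_single_measure(session, "DI", params)
  details$DI <- res
  measure_used <- "DI"
  if (length(res$S) == 0L) {
    res <- soz_single_measure(session, "GC", params)
    details$GC <- res
    measure_used <- "GC"
  }
  structure(list(S0 = res$S0, S1 = res$S1, S = res$S,
                 measure_used = measure_used, scores = res$scores,
                 null = res$null, graph = res$graph,
                 details = details, params = params),
            class = "soz_inference")
}

#' @export
print.soz_inference <- function(x, ...) {
  cat(sprintf("<soz_inference via %s: S = {%s} (|S0| = %d, |S1| = %d)>\n",
              x$measure_used, paste(x$S, collapse = ", "),
              length(x$S0), length(x$S1)))
  invisible(x)
}
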