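#' Remap connection weights to edge lengths
#'
#' Strong connections should be short for path-based analysis, so edge
#' lengths are the reciprocal of the weights: `l = 1/w` for `w > 0` and
#' `Inf` (no edge) where `w = 0`. This is the standard remap for
#' streamline-weighted connectomes.
#'
#' @param w Connectivity matrix (non-negative, symmetric).
#' @return Matrix of positive lengths with `Inf` for absent edges and a zero
#'   diagonal.
#' @export
weights_to_lengths <- function(w) {
  l <- ifelse(w > 0, 1 / w, Inf)
  diag(l) <- 0
  l
}

graph_from_weights <- function(w) {
  igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' All-pairs shortest path lengths
#'
#' Dijkstra shortest paths on the reciprocal-weight length matrix.
#'
#' @inheritParams weights_to_lengths
#' @return N x N matrix `d` with `d[i,i] = 0`, the minimal sum of edge
#'   lengths elsewhere, and `Inf` for unreachable pairs.
#' @export
shortest_path_lengths <- function(w) {
  n <- nrow(w)
  g <- graph_from_weights(w)
  if (igraph::ecount(g) == 0L) {
    d <- matrix(Inf, n, n)
    diag(d) <- 0
    return(d)
  }
  d <- igraph::distances(g, weights = 1 / igraph::E(g)$weight,
                         algorithm = "dijkstra")
  dimnames(d) <- NULL
  d
}

#' Characteristic path length
#'
#' Mean shortest path length over unordered node pairs. Unreachable pairs are
#' excluded from the mean and their count reported, so that disconnected
#' regions (which tractography can legitimately produce after injury) do not
#' make the metric infinite.
#'
#' @param d Shortest-path matrix from [shortest_path_lengths()].
#' @return List with `value` (mean over reachable pairs) and
#'   `n_unreachable_pairs`.
#' @export
characteristic_path_length <- function(d) {
  ut <- d[upper.tri(d)]
  reachable <- is.finite(ut)
  if (!any(reachable)) {
    stop_metric_undefined("no reachable node pair: path length undefined")
  }
  list(value = mean(ut[reachable]),
       n_unreachable_pairs = sum(!reachable))
}

#' Global efficiency
#'
#' Mean inverse shortest path length over unordered pairs; unreachable pairs
#' contribute zero efficiency.
#'
#' @inheritParams characteristic_path_length
#' @return Scalar efficiency.
#' @export
global_efficiency <- function(d) {
  ut <- d[upper.tri(d)]
  mean(ifelse(is.finite(ut) & ut > 0, 1 / ut, ifelse(ut == 0, Inf, 0)))
}

#' Node strength
#'
#' @inheritParams weights_to_lengths
#' @return Vector of per-node strengths (sum of incident edge weights).
#' @export
node_strength <- function(w) {
  rowSums(w)
}

#' Weighted clustering coefficient
#'
#' Geometric-mean triangle formula on max-normalized weights:
#' `C_i = sum_{j,h} (w_ij w_jh w_hi)^(1/3) / (k_i (k_i - 1))` with
#' `w` rescaled by its maximum, where `k_i` is the binary degree. Nodes with
#' fewer than two neighbors have `C_i = 0`.
#'
#' @inheritParams weights_to_lengths
#' @return Vector of per-node clustering coefficients in `[0, 1]`.
#' @export
clustering_coef <- function(w) {
  n <- nrow(w)
  mx <- max(w)
  if (mx == 0) return(numeric(n))
  w3 <- (w / mx)^(1 / 3)
  num <- diag(w3 %*% w3 %*% w3)
  k <- rowSums(w > 0)
  ifelse(k >= 2, num / (k * (k - 1)), 0)
}

#' Local efficiency
#'
#' For each node, the global efficiency of the subgraph induced by its
#' neighbors (edges and weights restricted to those neighbors); zero when a
#' node has fewer than two neighbors.
#'
#' @inheritParams weights_to_lengths
#' @return Vector of per-node local efficiencies.
#' @export
local_efficiency <- function(w) {
  n <- nrow(w)
  vapply(seq_len(n), function(i) {
    nb <- which(w[i, ] > 0)
    if (length(nb) < 2) return(0)
    sub <- w[nb, nb, drop = FALSE]
    global_efficiency(shortest_path_lengths(sub))
  }, numeric(1))
}

#' Betweenness centrality
#'
#' Weighted betweenness on reciprocal-weight lengths (Brandes accumulation via
#' igraph), unnormalized so values are raw counts of unordered shortest paths
#' through each node; equal-length path multiplicities are split fractionally.
#'
#' @inheritParams weights_to_lengths
#' @return Vector of per-node betweenness values.
#' @export
betweenness_nodes <- function(w) {
  g <- graph_from_weights(w)
  if (igraph::ecount(g) == 0L) return(numeric(nrow(w)))
  bc <- igraph::betweenness(g, weights = 1 / igraph::E(g)$weight,
                            normalized = FALSE)
  unname(bc)
}

#' Greedy geometric navigation efficiency
#'
#' Decentralized routing: from source `s` toward target `t`, repeatedly hop to
#' the connected neighbor whose region centroid is Euclidean-closest to `t`
#' (ties broken by lowest node index). The walk fails when it would revisit a
#' node or reaches a node with no neighbors. The navigation path length is the
#' sum of reciprocal-weight edge lengths along the walk (or the hop count with
#' `measure = "hops"`); pairwise efficiency is its inverse on success and 0 on
#' failure, and the overall efficiency is the mean over all ordered pairs.
#'
#' @inheritParams weights_to_lengths
#' @param coords N x 3 matrix of node centroid coordinates (mm), or a node
#'   table with `x`, `y`, `z` columns.
#' @param measure Length used for the efficiency: `"length"` (reciprocal
#'   weights, default) or `"hops"`.
#' @return List with `value` (mean efficiency over ordered pairs),
#'   `efficiency` (N x N pairwise matrix), and `success` (logical N x N).
#' @export
navigation_efficiency <- function(w, coords, measure = c("length", "hops")) {
  measure <- match.arg(measure)
  if (is.data.frame(coords)) {
    coords <- as.matrix(coords[, c("x", "y", "z")])
  }
  n <- nrow(w)
  if (is.null(coords) || nrow(coords) != n || !all(is.finite(coords))) {
    stop_value("navigation requires finite centroid coordinates for every node")
  }
  geo <- as.matrix(stats::dist(coords))
  lens <- weights_to_lengths(w)
  nbrs <- lapply(seq_len(n), function(i) which(w[i, ] > 0))
  eff <- matrix(0, n, n)
  success <- matrix(FALSE, n, n)
  for (t in seq_len(n)) {
    dt <- geo[, t]
    for (s in seq_len(n)) {
      if (s == t) next
      visited <- logical(n)
      visited[s] <- TRUE
      cur <- s
      plen <- 0
      ok <- FALSE
      repeat {
        nb <- nbrs[[cur]]
        if (length(nb) == 0L) break
        nxt <- nb[which.min(dt[nb])]
        if (visited[nxt]) break
        plen <- plen + if (measure == "length") lens[cur, nxt] else 1
        cur <- nxt
        visited[cur] <- TRUE
        if (cur == t) {
          ok <- TRUE
          break
        }
      }
      if (ok) {
        success[s, t] <- TRUE
        eff[s, t] <- 1 / plen
      }
    }
  }
  list(value = sum(eff) / (n * (n - 1)), efficiency = eff, success = success)
}

#' Degree-preserving weighted rewiring
#'
#' Double-edge swaps `(a-b, c-d) -> (a-d, c-b)` that preserve every node's
#' degree and the multiset of edge weights (weights travel with their original
#' endpoint `a`/`c`). Swaps creating self-loops or duplicate edges are
#' rejected. Uses the R random number stream, so results are reproducible
#' under `set.seed()`.
#'
#' @inheritParams weights_to_lengths
#' @param rewires_per_edge Attempted swaps per edge (default 10).
#' @return Rewired weight matrix with the same degree sequence.
#' @export
rewire_degseq_weighted <- function(w, rewires_per_edge = 10) {
  n_attempts <- as.integer(round(rewires_per_edge * sum(w[upper.tri(w)] > 0)))
  rewire_weighted_cpp(w, n_attempts)
}

#' Clustering normalized to degree-preserving random surrogates
#'
#' Ratio of the network's mean clustering coefficient to the mean clustering
#' of rewired null networks ([rewire_degseq_weighted()]); a value of 1 means
#' clustering equivalent to a random network of the same degrees and weights.
#'
#' @inheritParams weights_to_lengths
#' @param n_nulls Number of null networks (default 100).
#' @param rewires_per_edge Attempted swaps per edge in each null (default 10).
#' @param seed Optional seed for the null ensemble (caller RNG is restored).
#' @return List with `value` (C_norm), `c_obs`, `null_mean`, `null_sd`, and
#'   the per-null means `null_values`.
#' @export
normalized_clustering <- function(w, n_nulls = 100, rewires_per_edge = 10,
                                  seed = NULL) {
  c_obs <- mean(clustering_coef(w))
  null_values <- with_seed(seed, {
    vapply(seq_len(n_nulls), function(k) {
      mean(clustering_coef(rewire_degseq_weighted(w, rewires_per_edge)))
    }, numeric(1))
  })
  null_mean <- mean(null_values)
  if (null_mean == 0) {
    stop_metric_undefined("null networks have zero clustering: C_norm undefined")
  }
  list(value = c_obs / null_mean, c_obs = c_obs, null_mean = null_mean,
       null_sd = sd(null_values), null_values = null_values)
}

#' Compute the eight-metric global graph profile of one connectome
#'
#' Computes mean strength, characteristic path length, global efficiency,
#' navigation efficiency, mean local efficiency, mean clustering coefficient,
#' normalized clustering coefficient, and mean betweenness centrality, keeping
#' the per-node vectors (strength, clustering, local efficiency, betweenness)
#' for regional analysis.
#'
#' @inheritParams weights_to_lengths
#' @param nodes Node table (needed for navigation efficiency); may be `NULL`
#'   when `navigation = FALSE`.
#' @param n_nulls,rewires_per_edge Null-model settings for the normalized
#'   clustering coefficient.
#' @param seed Seed for the null-model ensemble; fixed so the profile is
#'   deterministic given `(matrix, seed)`.
#' @param navigation Compute navigation efficiency (requires `nodes`)?
#' @return An object of class `metric_profile`.
#' @export
connectome_metrics <- function(w, nodes = NULL, n_nulls = 100,
                               rewires_per_edge = 10, seed = 1L,
                               navigation = !is.null(nodes)) {
  w <- as_connectome(w, subject_id = attr(w, "subject_id") %||% "subject",
                     icv = attr(w, "icv"))
  d <- shortest_path_lengths(w)
  cpl <- characteristic_path_length(d)
  s <- node_strength(w)
  cc <- clustering_coef(w)
  le <- local_efficiency(w)
  bc <- betweenness_nodes(w)
  cn <- normalized_clustering(w, n_nulls = n_nulls,
                              rewires_per_edge = rewires_per_edge, seed = seed)
  nav <- if (navigation) {
    navigation_efficiency(w, nodes)
  } else {
    list(value = NA_real_)
  }
  globals <- c(strength = mean(s),
               char_path_length = cpl$value,
               global_efficiency = global_efficiency(d),
               navigation_efficiency = nav$value,
               local_efficiency = mean(le),
               clustering = mean(cc),
               normalized_clustering = cn$value,
               betweenness = mean(bc))
  node_tb <- tibble::tibble(
    index = seq_along(s) - 1L,
    label = if (!is.null(nodes)) nodes$label else paste0("node_", seq_along(s)),
    strength = s, clustering = cc, local_efficiency = le, betweenness = bc)
  structure(list(subject_id = attr(w, "subject_id"),
                 icv = attr(w, "icv"),
                 globals = globals,
                 nodes = node_tb,
                 n_unreachable_pairs = cpl$n_unreachable_pairs,
                 null_model = cn[c("c_obs", "null_mean", "null_sd")],
                 params = list(n_nulls = n_nulls,
                               rewires_per_edge = rewires_per_edge,
                               seed = seed)),
            class = "metric_profile")
}

#' @export
print.metric_profile <- function(x, ...) {
  cat(sprintf("<metric_profile> subject '%s' (%d regions)\n",
              x$subject_id, nrow(x$nodes)))
  print(round(x$globals, 4))
  invisible(x)
}

#' @rdname connectome_metrics
#' @param x A `metric_profile`.
#' @param ... Unused.
#' @method tidy metric_profile
#' @export
tidy.metric_profile <- function(x, ...) {
  tibble::tibble(metric = names(x$globals), value = unname(x$globals))
}

#' @rdname connectome_metrics
#' @method glance metric_profile
#' @export
glance.metric_profile <- function(x, ...) {
  tibble::as_tibble(c(list(subject_id = x$subject_id),
                      as.list(x$globals),
                      list(n_unreachable_pairs = x$n_unreachable_pairs,
                           seed = x$params$seed)))
}
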