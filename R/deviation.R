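#' Per-edge control mean and standard deviation
#'
#' Sample mean and sample standard deviation (denominator n - 1) of every
#' edge weight across the control cohort; the normative reference the z-score
#' deviation map is computed against.
#'
#' @param controls List of control connectivity matrices (common dimension).
#' @return List of class `cohort_edge_stats` with `mu`, `sigma` (N x N
#'   matrices) and `n_controls`.
#' @export
cohort_edge_stats <- function(controls) {
  if (length(controls) < 2) {
    stop_cohort("edge statistics need at least 2 controls")
  }
  dims <- vapply(controls, nrow, integer(1))
  if (length(unique(dims)) != 1L ||
      any(vapply(controls, ncol, integer(1)) != dims[1])) {
    stop_dimension("control matrices do not share a common dimension")
  }
  n <- dims[1]
  k <- length(controls)
  stack <- array(unlist(controls, use.names = FALSE), dim = c(n, n, k))
  mu <- rowMeans(stack, dims = 2)
  # two-pass sample SD (ddof = 1), vectorized over edges
  dev <- stack - as.vector(mu)
  sigma <- sqrt(rowSums(dev * dev, dims = 2) / (k - 1))
  structure(list(mu = mu, sigma = sigma, n_controls = k),
            class = "cohort_edge_stats")
}

#' Edgewise z-score deviation matrix
#'
#' `Z[i,j] = (T[i,j] - mu[i,j]) / sigma[i,j]`: the patient's distance from the
#' control mean in control standard deviations, per edge. Positive z means a
#' stronger edge in the patient than in controls, negative z a weaker edge.
#' Edges with zero control variance get `z = 0` when the patient matches the
#' control value exactly, and are otherwise excluded from parametric testing
#' with reason `"zero-variance"`.
#'
#' @param patient Patient connectivity matrix.
#' @param stats `cohort_edge_stats` for the control cohort.
#' @return List with `z` (N x N, zero diagonal) and `excluded` (tibble of
#'   upper-triangle edges `i`, `j` (1-based), `reason`).
#' @export
edge_z_matrix <- function(patient, stats) {
  if (!all(dim(patient) == dim(stats$mu))) {
    stop_dimension("patient matrix dimension does not match cohort statistics")
  }
  z <- matrix(0, nrow(patient), ncol(patient))
  pos <- stats$sigma > 0
  z[pos] <- (patient[pos] - stats$mu[pos]) / stats$sigma[pos]
  bad <- !pos & (patient != stats$mu)
  diag(bad) <- FALSE
  idx <- which(bad & upper.tri(bad), arr.ind = TRUE)
  excluded <- tibble::tibble(i = as.integer(idx[, "row"]) - 1L,
                             j = as.integer(idx[, "col"]) - 1L,
                             reason = rep("zero-variance", nrow(idx)))
  diag(z) <- 0
  list(z = z, excluded = excluded)
}

#' Two-sided normal p-value for a z-score
#'
#' `p = 2 * Phi(-|z|)`, evaluated through the lower-tail normal CDF directly
#' (no `1 - CDF` subtraction), so far-tail values keep full relative accuracy.
#'
#' @param z Numeric vector of z-scores.
#' @return Two-sided p-values in `(0, 1]`.
#' @export
z_to_p_two_sided <- function(z) {
  2 * pnorm(-abs(z))
}

#' Benjamini-Hochberg false discovery rate step-up
#'
#' Sorts the p-values ascending, rejects all `p_(k)` with
#' `p_(k) <= k * q / m` for the largest such `k`, and returns the adjusted
#' q-values `q_(k) = min_{j >= k} m * p_(j) / j` capped at 1 (so rejection is
#' equivalent to `q_adj <= q`).
#'
#' @param p Vector of p-values in `(0, 1]`.
#' @param q Target false discovery rate (default 0.05).
#' @return List with `q_values` (adjusted, same order as `p`) and `reject`
#'   (logical mask).
#' @export
bh_fdr <- function(p, q = 0.05) {
  if (length(p) == 0L) {
    return(list(q_values = numeric(0), reject = logical(0)))
  }
  qv <- p.adjust(p, method = "BH")
  list(q_values = qv, reject = qv <= q)
}

#' Node-strength z-scores against the control cohort
#'
#' Each node's strength (sum of incident edge weights) is converted to a
#' z-score using the control mean and standard deviation for that node, with
#' two-sided normal p-values; by default the N-node family is corrected with
#' Benjamini-Hochberg FDR. Positive z means stronger node strength in the
#' patient. Zero-variance nodes are excluded and flagged.
#'
#' @inheritParams edge_z_matrix
#' @param controls List of control connectivity matrices.
#' @param q FDR level (default 0.05).
#' @param correct Apply FDR correction over the node family (default `TRUE`;
#'   when `FALSE`, significance is `p <= q` uncorrected).
#' @return Tibble with one row per node: `index` (0-based), `strength`, `z`,
#'   `p`, `q_value`, `significant`, `sign`, `excluded`.
#' @export
node_strength_z <- function(patient, controls, q = 0.05, correct = TRUE) {
  if (length(controls) < 2) stop_cohort("need at least 2 controls")
  s_pat <- node_strength(patient)
  s_ctl <- vapply(controls, node_strength, numeric(length(s_pat)))
  mu <- rowMeans(s_ctl)
  sigma <- apply(s_ctl, 1, sd)
  ok <- sigma > 0
  z <- rep(NA_real_, length(s_pat))
  z[ok] <- (s_pat[ok] - mu[ok]) / sigma[ok]
  z[!ok & s_pat == mu] <- 0
  excluded <- !ok & s_pat != mu
  p <- ifelse(is.na(z) | excluded, NA_real_, z_to_p_two_sided(z))
  tested <- which(!is.na(p))
  q_value <- rep(NA_real_, length(p))
  significant <- rep(FALSE, length(p))
  if (length(tested) > 0) {
    if (correct) {
      fdr <- bh_fdr(p[tested], q = q)
      q_value[tested] <- fdr$q_values
      significant[tested] <- fdr$reject
    } else {
      q_value[tested] <- p[tested]
      significant[tested] <- p[tested] <= q
    }
  }
  tibble::tibble(index = seq_along(s_pat) - 1L,
                 strength = s_pat, z = z, p = p, q_value = q_value,
                 significant = significant,
                 sign = dplyr::case_when(is.na(z) ~ NA_character_,
                                         z < 0 ~ "weaker",
                                         z > 0 ~ "stronger",
                                         TRUE ~ "equal"),
                 excluded = excluded)
}

#' Detect betweenness hubs
#'
#' The top fraction (default 10%) of nodes by betweenness centrality;
#' `k = round-half-up(fraction * N)`, capped at N (on the 84-region atlas the
#' default gives 8 hubs). Ties at the threshold are broken by higher node
#' strength, then by lower node index, so hub sets are deterministic.
#'
#' @param bc Per-node betweenness values.
#' @param strength Per-node strengths used for tie-breaking (optional).
#' @param fraction Fraction of nodes to call hubs (default 0.10).
#' @return Tibble of class `hub_set`: `index` (0-based), `betweenness`,
#'   `strength`, ordered by rank.
#' @export
detect_hubs <- function(bc, strength = NULL, fraction = 0.10) {
  n <- length(bc)
  if (!all(is.finite(bc))) stop_value("betweenness values must be finite")
  if (is.null(strength)) strength <- numeric(n)
  k <- min(n, floor(fraction * n + 0.5))
  ord <- order(-bc, -strength, seq_len(n))
  sel <- ord[seq_len(k)]
  structure(tibble::tibble(index = sel - 1L,
                           betweenness = bc[sel],
                           strength = strength[sel]),
            class = c("hub_set", "tbl_df", "tbl", "data.frame"),
            fraction = fraction, n_nodes = n)
}

#' Hub arrangement alterations
#'
#' Set difference of patient and reference hub memberships: `gained` hubs are
#' present in the patient but not the reference, `lost` hubs the reverse.
#'
#' @param patient_hubs,reference_hubs `hub_set` tibbles (or vectors of
#'   0-based node indices) over the same node universe.
#' @return List with integer vectors `gained` and `lost` (0-based indices).
#' @export
hub_alterations <- function(patient_hubs, reference_hubs) {
  as_idx <- function(h) {
    if (is.data.frame(h)) as.integer(h$index) else as.integer(h)
  }
  p <- as_idx(patient_hubs)
  r <- as_idx(reference_hubs)
  list(gained = sort(setdiff(p, r)), lost = sort(setdiff(r, p)))
}

#' Full regional deviation analysis of one patient
#'
#' Computes the edgewise z-score deviation map with two-sided normal p-values
#' and Benjamini-Hochberg FDR over the upper-triangle edge family (excluding
#' zero-variance edges), node-strength z-scores with FDR over the node family,
#' and the hub comparison between the patient and the control reference
#' (betweenness hubs of the group-average control connectome by default, or
#' the per-control consensus).
#'
#' @param patient Patient connectivity matrix.
#' @param controls List of control connectivity matrices.
#' @param nodes Optional node table for labeling.
#' @param fdr_q FDR level for edges and nodes (default 0.05).
#' @param hub_fraction Fraction of nodes called hubs (default 0.10).
#' @param reference_hubs `"group_average"` (hubs of the mean control
#'   connectome) or `"consensus"` (nodes most frequently hubs across
#'   individual controls).
#' @param correct_nodes FDR-correct the node-strength family (default `TRUE`).
#' @return Object of class `connectome_deviation` with elements `edges`
#'   (tibble of tested upper-triangle edges), `excluded_edges`, `nodes`,
#'   `patient_hubs`, `reference_hubs`, `hub_changes`, `z_edges`, and
#'   `summary`.
#' @export
connectome_deviation <- function(patient, controls, nodes = NULL,
                                 fdr_q = 0.05, hub_fraction = 0.10,
                                 reference_hubs = c("group_average",
                                                    "consensus"),
                                 correct_nodes = TRUE) {
  reference_hubs <- match.arg(reference_hubs)
  stats <- cohort_edge_stats(controls)
  ez <- edge_z_matrix(patient, stats)
  n <- nrow(patient)
  pairs <- upper_tri_pairs(n)
  excl_key <- paste(ez$excluded$i + 1L, ez$excluded$j + 1L)
  tested <- !(paste(pairs$i, pairs$j) %in% excl_key)
  ii <- pairs$i[tested]
  jj <- pairs$j[tested]
  edges <- tibble::tibble(
    i = ii - 1L, j = jj - 1L,
    weight = patient[cbind(ii, jj)],
    control_mean = stats$mu[cbind(ii, jj)],
    z = ez$z[cbind(ii, jj)])
  edges$p <- z_to_p_two_sided(edges$z)
  fdr <- bh_fdr(edges$p, q = fdr_q)
  edges$q_value <- fdr$q_values
  edges$significant <- fdr$reject
  edges$sign <- dplyr::case_when(edges$z < 0 ~ "weaker",
                                 edges$z > 0 ~ "stronger",
                                 TRUE ~ "equal")
  if (!is.null(nodes)) {
    edges$node_i_label <- nodes$label[edges$i + 1L]
    edges$node_j_label <- nodes$label[edges$j + 1L]
  }
  node_z <- node_strength_z(patient, controls, q = fdr_q,
                            correct = correct_nodes)
  pat_bc <- betweenness_nodes(patient)
  pat_hubs <- detect_hubs(pat_bc, node_strength(patient),
                          fraction = hub_fraction)
  ref_hubs <- if (reference_hubs == "group_average") {
    avg <- Reduce(`+`, controls) / length(controls)
    detect_hubs(betweenness_nodes(avg), node_strength(avg),
                fraction = hub_fraction)
  } else {
    consensus_hubs(controls, fraction = hub_fraction)
  }
  changes <- hub_alterations(pat_hubs, ref_hubs)
  node_z$betweenness <- pat_bc
  node_z$is_hub <- (node_z$index %in% pat_hubs$index)
  if (!is.null(nodes)) node_z$label <- nodes$label[node_z$index + 1L]
  summary <- tibble::tibble(
    n_edges_tested = nrow(edges),
    n_edges_excluded = nrow(ez$excluded),
    n_significant_weaker = sum(edges$significant & edges$sign == "weaker"),
    n_significant_stronger = sum(edges$significant & edges$sign == "stronger"),
    n_nodes_significant = sum(node_z$significant),
    n_hubs_gained = length(changes$gained),
    n_hubs_lost = length(changes$lost),
    fdr_q = fdr_q, hub_fraction = hub_fraction,
    reference_hubs = reference_hubs)
  structure(list(edges = edges, excluded_edges = ez$excluded,
                 nodes = node_z, patient_hubs = pat_hubs,
                 reference_hubs = ref_hubs, hub_changes = changes,
                 z_edges = ez$z, summary = summary),
            class = "connectome_deviation")
}

# Consensus reference hubs: nodes ranked by how often they are hubs across
# the individual control connectomes, ties by mean betweenness, then index.
consensus_hubs <- function(controls, fraction = 0.10) {
  n <- nrow(controls[[1]])
  counts <- numeric(n)
  bc_sum <- numeric(n)
  str_sum <- numeric(n)
  for (m in controls) {
    bc <- betweenness_nodes(m)
    hubs <- detect_hubs(bc, node_strength(m), fraction = fraction)
    counts[hubs$index + 1L] <- counts[hubs$index + 1L] + 1
    bc_sum <- bc_sum + bc
    str_sum <- str_sum + node_strength(m)
  }
  k <- min(n, floor(fraction * n + 0.5))
  ord <- order(-counts, -bc_sum, seq_len(n))
  sel <- ord[seq_len(k)]
  structure(tibble::tibble(index = sel - 1L,
                           betweenness = bc_sum[sel] / length(controls),
                           strength = str_sum[sel] / length(controls)),
            class = c("hub_set", "tbl_df", "tbl", "data.frame"),
            fraction = fraction, n_nodes = n)
}

#' @export
print.connectome_deviation <- function(x, ...) {
  cat("<connectome_deviation>\n")
  print(x$summary)
  invisible(x)
}

#' @rdname connectome_deviation
#' @param x A `connectome_deviation`.
#' @param ... Unused.
#' @method tidy connectome_deviation
#' @export
tidy.connectome_deviation <- function(x, ...) {
  x$edges
}

#' @rdname connectome_deviation
#' @method glance connectome_deviation
#' @export
glance.connectome_deviation <- function(x, ...) {
  x$summary
}
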