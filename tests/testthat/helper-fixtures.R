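# In-code fixtures shared across test files.

# Random symmetric weighted graph with edge probability p and uniform weights.
random_weighted_graph <- function(n, p = 0.6, wmin = 0.5, wmax = 3,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- matrix(0, n, n)
  ut <- upper.tri(w)
  on <- runif(sum(ut)) < p
  vals <- ifelse(on, runif(sum(ut), wmin, wmax), 0)
  w[ut] <- vals
  w <- w + t(w)
  w
}

# Complete graph with unit weights.
complete_graph <- function(n) {
  w <- matrix(1, n, n)
  diag(w) <- 0
  w
}

# Path graph 1-2-...-n with unit weights.
path_graph <- function(n) {
  w <- matrix(0, n, n)
  for (i in seq_len(n - 1)) w[i, i + 1] <- w[i + 1, i] <- 1
  w
}

# Ring lattice: each node connected to `k` nearest neighbors per side.
ring_lattice <- function(n, k = 2) {
  w <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (s in seq_len(k)) {
      j <- ((i - 1 + s) %% n) + 1
      w[i, j] <- w[j, i] <- 1
    }
  }
  w
}

tiny_node_table <- function(coords, labels = NULL) {
  n <- nrow(coords)
  tibble::tibble(
    index = seq_len(n) - 1L,
    label = labels %||% sprintf("region_%02d", seq_len(n)),
    hemisphere = rep("midline", n),
    x = coords[, 1], y = coords[, 2], z = coords[, 3])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small synthetic study reused by several files (cached per session).
tiny_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- suppressWarnings(
        simulate_cohort(file.path(tempdir(), "graphme_tiny_fixture"),
                        preset = "tiny10"))
    }
    cache
  }
})
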