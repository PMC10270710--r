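# Brute-force reference implementations, independent of the package's code
# paths: exhaustive simple-path enumeration for shortest paths and
# betweenness, literal triple loops for clustering, and the literal BH
# step-up rule. Only usable at tiny N.

oracle_all_paths <- function(w, s, t) {
  n <- nrow(w)
  acc <- new.env()
  acc$len <- numeric(0)
  acc$paths <- list()
  recurse <- function(cur, visited, len, path) {
    if (cur == t) {
      acc$len <- c(acc$len, len)
      acc$paths[[length(acc$paths) + 1L]] <- path
      return(invisible())
    }
    for (nb in seq_len(n)) {
      if (w[cur, nb] > 0 && !visited[nb]) {
        v2 <- visited
        v2[nb] <- TRUE
        recurse(nb, v2, len + 1 / w[cur, nb], c(path, nb))
      }
    }
  }
  visited <- logical(n)
  visited[s] <- TRUE
  recurse(s, visited, 0, s)
  acc
}

oracle_shortest_paths <- function(w) {
  n <- nrow(w)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      p <- oracle_all_paths(w, s, t)
      if (length(p$len) > 0) d[s, t] <- d[t, s] <- min(p$len)
    }
  }
  d
}

oracle_betweenness <- function(w, tol = 1e-9) {
  n <- nrow(w)
  bc <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      p <- oracle_all_paths(w, s, t)
      if (length(p$len) == 0) next
      mn <- min(p$len)
      sel <- which(p$len <= mn + tol * max(mn, 1))
      for (k in sel) {
        interior <- setdiff(p$paths[[k]], c(s, t))
        bc[interior] <- bc[interior] + 1 / length(sel)
      }
    }
  }
  bc
}

oracle_clustering <- function(w) {
  n <- nrow(w)
  mx <- max(w)
  if (mx == 0) return(numeric(n))
  wn <- w / mx
  out <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(w[i, ] > 0)
    if (k < 2) next
    tot <- 0
    for (j in seq_len(n)) {
      for (h in seq_len(n)) {
        if (j != i && h != i && j != h) {
          tot <- tot + (wn[i, j] * wn[j, h] * wn[h, i])^(1 / 3)
        }
      }
    }
    out[i] <- tot / (k * (k - 1))
  }
  out
}

oracle_global_efficiency <- function(d) {
  ut <- d[upper.tri(d)]
  mean(ifelse(is.finite(ut), 1 / ut, 0))
}

oracle_local_efficiency <- function(w) {
  n <- nrow(w)
  vapply(seq_len(n), function(i) {
    nb <- which(w[i, ] > 0)
    if (length(nb) < 2) return(0)
    oracle_global_efficiency(oracle_shortest_paths(w[nb, nb, drop = FALSE]))
  }, numeric(1))
}

# Literal BH step-up: reject all p_(k) for the largest k with
# p_(k) <= k q / m; adjusted value q_(k) = min_{j >= k} m p_(j) / j.
oracle_bh <- function(p, q = 0.05) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  crit <- which(ps <= seq_len(m) * q / m)
  reject_sorted <- logical(m)
  if (length(crit) > 0) reject_sorted[seq_len(max(crit))] <- TRUE
  q_sorted <- pmin(rev(cummin(rev(m * ps / seq_len(m)))), 1)
  reject <- logical(m)
  qv <- numeric(m)
  reject[ord] <- reject_sorted
  qv[ord] <- q_sorted
  list(q_values = qv, reject = reject)
}
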