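# Independent brute-force oracles used to check the package's graph,
# correlation and F1 computations. Deliberately naive: exhaustive
# enumeration over adjacency matrices and confusion tables, no graph
# library involved.

# All-pairs shortest-path distances by Floyd-Warshall on an adjacency matrix.
bf_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj == 1] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# Enumerate all simple paths from s to t of length exactly len (edge count).
bf_paths <- function(adj, s, t, len) {
  paths <- list()
  walk <- function(path) {
    last <- path[length(path)]
    if (length(path) - 1 == len) {
      if (last == t) paths[[length(paths) + 1]] <<- path
      return(invisible())
    }
    for (nxt in which(adj[last, ] == 1)) {
      if (!nxt %in% path) walk(c(path, nxt))
    }
  }
  walk(s)
  paths
}

# The five structural features of every node, by exhaustive enumeration.
bf_structural_features <- function(adj) {
  n <- nrow(adj)
  deg <- rowSums(adj)
  tri <- numeric(n)
  if (n >= 3) {
    combs <- utils::combn(n, 3)
    for (c_i in seq_len(ncol(combs))) {
      v <- combs[, c_i]
      if (adj[v[1], v[2]] == 1 && adj[v[1], v[3]] == 1 && adj[v[2], v[3]] == 1) {
        tri[v] <- tri[v] + 1
      }
    }
  }
  clust <- ifelse(deg < 2, 0, 2 * tri / (deg * (deg - 1)))

  d <- bf_distances(adj)
  btw <- numeric(n)
  if (n >= 3) {
    for (s in seq_len(n - 1)) {
      for (t in (s + 1):n) {
        if (!is.finite(d[s, t]) || d[s, t] == 0) next
        paths <- bf_paths(adj, s, t, d[s, t])
        sigma <- length(paths)
        if (sigma == 0) next
        for (v in seq_len(n)) {
          if (v == s || v == t) next
          through <- sum(vapply(paths, function(p) v %in% p[-c(1, length(p))], logical(1)))
          btw[v] <- btw[v] + through / sigma
        }
      }
    }
    btw <- btw / ((n - 1) * (n - 2) / 2)
  }

  clo <- numeric(n)
  for (v in seq_len(n)) {
    reach <- which(is.finite(d[v, ]))
    r <- length(reach)                     # includes v itself
    if (r > 1) {
      clo[v] <- ((r - 1) / (n - 1)) * ((r - 1) / sum(d[v, setdiff(reach, v)]))
    }
  }
  data.frame(degree = deg, triangles = tri, clustering = clust,
             betweenness = btw, closeness = clo)
}

# Random undirected graph as an adjacency matrix.
bf_random_adj <- function(n, p = 0.35) {
  adj <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (runif(1) < p) adj[i, j] <- adj[j, i] <- 1
    }
  }
  adj
}

# igraph-free conversion of an adjacency matrix into the package's weekly
# graph form: an event per edge, then the standard builder.
adj_to_graph <- function(adj) {
  n <- nrow(adj)
  ids <- sprintf("n%02d", seq_len(n))
  g <- igraph::make_empty_graph(directed = FALSE) + igraph::vertices(ids)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (adj[i, j] == 1) g <- g + igraph::edge(ids[i], ids[j])
    }
  }
  g$week <- 0L
  g$variant <- "whole"
  g
}

# Per-class F1 from an explicitly built confusion matrix.
bf_f1 <- function(y_true, y_pred, K) {
  cm <- matrix(0, K, K)
  for (i in seq_along(y_true)) cm[y_true[i], y_pred[i]] <- cm[y_true[i], y_pred[i]] + 1
  f1 <- numeric(K)
  for (k in seq_len(K)) {
    tp <- cm[k, k]
    prec <- if (sum(cm[, k]) > 0) tp / sum(cm[, k]) else 0
    rec <- if (sum(cm[k, ]) > 0) tp / sum(cm[k, ]) else 0
    f1[k] <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  }
  f1
}
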