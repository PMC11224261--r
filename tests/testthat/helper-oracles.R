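# Independent brute-force oracles used to check the graph-metric
# implementations. Everything here works directly on a weighted adjacency
# matrix (0 = no edge) with pure matrix code and exhaustive enumeration; no
# call into the package's own metric code paths.

# Weighted shortest-path distances (length of an edge = 1/weight) by
# Floyd-Warshall.
oracle_distances <- function(adj, binarize = FALSE) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  d[adj > 0] <- if (binarize) 1 else 1 / adj[adj > 0]
  diag(d) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# All simple paths between s and t, as vertex index vectors.
enumerate_paths <- function(adj, s, t) {
  n <- nrow(adj)
  paths <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == t) {
      paths[[length(paths) + 1]] <<- path
      return()
    }
    for (u in seq_len(n))
      if (adj[v, u] > 0 && !(u %in% path)) walk(c(path, u))
  }
  walk(s)
  paths
}

# Betweenness by exhaustive shortest-path enumeration: for each unordered
# pair, fractional credit to interior vertices of the shortest path(s).
oracle_betweenness <- function(adj, binarize = FALSE, tol = 1e-9) {
  n <- nrow(adj)
  bet <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in seq((s + 1), n)) {
      paths <- enumerate_paths(adj, s, t)
      if (length(paths) == 0) next
      lens <- vapply(paths, function(p) {
        if (length(p) < 2) return(0)
        sum(vapply(seq_len(length(p) - 1), function(i) {
          w <- adj[p[i], p[i + 1]]
          if (binarize) 1 else 1 / w
        }, numeric(1)))
      }, numeric(1))
      best <- min(lens)
      shortest <- paths[lens <= best + tol]
      for (p in shortest) {
        interior <- setdiff(p, c(s, t))
        bet[interior] <- bet[interior] + 1 / length(shortest)
      }
    }
  }
  bet
}

# Closeness as the inverse of the mean shortest-path length to reachable
# nodes (0 for isolated nodes).
oracle_closeness <- function(adj, binarize = FALSE) {
  d <- oracle_distances(adj, binarize)
  diag(d) <- NA
  apply(d, 1, function(x) {
    x <- x[is.finite(x)]
    if (length(x) == 0 || mean(x) == 0) 0 else 1 / mean(x)
  })
}

# Clustering coefficient by exhaustive triad counting on the topology.
oracle_cc <- function(adj) {
  n <- nrow(adj)
  vapply(seq_len(n), function(v) {
    nb <- which(adj[v, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    links <- 0
    for (a in seq_len(k - 1))
      for (b in seq((a + 1), k))
        if (adj[nb[a], nb[b]] > 0) links <- links + 1
    links / (k * (k - 1) / 2)
  }, numeric(1))
}

oracle_global_efficiency <- function(adj, binarize = FALSE) {
  n <- nrow(adj)
  if (n < 2) return(0)
  d <- oracle_distances(adj, binarize)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

oracle_local_efficiency <- function(adj, binarize = FALSE) {
  n <- nrow(adj)
  effs <- vapply(seq_len(n), function(v) {
    nb <- which(adj[v, ] > 0)
    if (length(nb) < 2) return(0)
    oracle_global_efficiency(adj[nb, nb, drop = FALSE], binarize)
  }, numeric(1))
  mean(effs)
}

# Weighted Newman modularity, direct formula evaluation.
oracle_modularity <- function(adj, membership) {
  W <- sum(adj[upper.tri(adj)])
  if (W == 0) return(0)
  s <- rowSums(adj)
  q <- 0
  for (comm in unique(membership)) {
    members <- which(membership == comm)
    sub <- adj[members, members, drop = FALSE]
    W_c <- sum(sub[upper.tri(sub)])
    S_c <- sum(s[members])
    q <- q + W_c / W - (S_c / (2 * W))^2
  }
  q
}

# All set partitions of n elements, as membership vectors (restricted growth
# strings).
all_partitions <- function(n) {
  out <- list()
  grow <- function(prefix) {
    if (length(prefix) == n) {
      out[[length(out) + 1]] <<- prefix
      return()
    }
    top <- if (length(prefix)) max(prefix) else 0L
    for (v in seq_len(top + 1L)) grow(c(prefix, v))
  }
  grow(integer(0))
  out
}

# Exhaustive modularity maximisation over all partitions.
oracle_best_partition <- function(adj) {
  parts <- all_partitions(nrow(adj))
  qs <- vapply(parts, function(p) oracle_modularity(adj, p), numeric(1))
  list(membership = parts[[which.max(qs)]], Q = max(qs))
}

# Brute-force BH step-up: adjusted p for the i-th test is the minimum over
# tests with rank >= rank_i of p_j * m / rank_j, capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  rank <- integer(m)
  rank[ord] <- seq_len(m)
  vapply(seq_len(m), function(i) {
    min(1, min(p[rank >= rank[i]] * m / rank[rank >= rank[i]]))
  }, numeric(1))
}

# Random connected weighted graph as an adjacency matrix; uses the ambient
# RNG stream (tests wrap calls in withr::with_seed).
random_weighted_adj <- function(n, p_edge = 0.6, w_min = 0.1, w_max = 1) {
  repeat {
    adj <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      for (j in seq((i + 1), n)) {
        if (runif(1) < p_edge) {
          w <- runif(1, w_min, w_max)
          adj[i, j] <- adj[j, i] <- w
        }
      }
    }
    d <- oracle_distances(adj)
    if (all(is.finite(d))) return(adj)
  }
}

# Wrap an adjacency matrix as the package's correlation-matrix object so the
# network constructors can consume it directly.
adj_as_corr <- function(adj, group = "G", metadata = NULL) {
  n <- nrow(adj)
  regions <- if (!is.null(rownames(adj))) rownames(adj)
  else sprintf("R%02d", seq_len(n))
  r <- adj
  r[r == 0] <- NA_real_
  dimnames(r) <- list(regions, regions)
  diag(r) <- NA_real_
  structure(list(group = group, regions = regions, r = r,
                 n_animals = NA_integer_, metadata = metadata),
            class = "coreact_corr")
}
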