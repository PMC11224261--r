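#' Newman modularity of a partition
#'
#' `Q = sum_c [ W_c/W - (S_c / 2W)^2 ]` with `W` the total edge weight,
#' `W_c` the weight within community `c`, and `S_c` the summed node strength
#' of `c`. The one-community partition scores 0. In combined (signed) mode
#' the magnitude weights `|r|` are used, matching [detect_communities()].
#'
#' @param g Network from [build_network()].
#' @param membership Named (or network-ordered) vector assigning every node
#'   a community id.
#' @return Modularity Q (dimensionless).
#' @export
modularity_score <- function(g, membership) {
  n <- igraph::vcount(g)
  membership <- resolve_membership(g, membership)
  if (igraph::ecount(g) == 0L) return(0)
  w <- working_weights(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  W <- sum(w)
  s <- numeric(n)
  for (e in seq_along(w)) {
    s[el[e, 1]] <- s[el[e, 1]] + w[e]
    s[el[e, 2]] <- s[el[e, 2]] + w[e]
  }
  q <- 0
  for (comm in unique(membership)) {
    members <- which(membership == comm)
    in_c <- membership[el[, 1]] == comm & membership[el[, 2]] == comm
    W_c <- sum(w[in_c])
    S_c <- sum(s[members])
    q <- q + W_c / W - (S_c / (2 * W))^2
  }
  q
}

resolve_membership <- function(g, membership) {
  n <- igraph::vcount(g)
  if (length(membership) != n)
    validation_stop("membership must assign every node exactly once")
  if (!is.null(names(membership))) {
    idx <- match(igraph::V(g)$name, names(membership))
    if (any(is.na(idx)))
      validation_stop("membership is missing node(s): ",
                      paste(igraph::V(g)$name[is.na(idx)], collapse = ", "))
    membership <- membership[idx]
  }
  as.integer(as.factor(membership))
}

#' Community detection by modularity optimisation
#'
#' Partitions the network into communities of higher within- than
#' between-community weight by maximising Newman modularity: multi-restart
#' Louvain passes over permuted vertex orders, each followed by a greedy
#' single-node-move refinement, keeping the maximum-Q partition. Ties in Q
#' are broken by the lexicographically smallest canonical membership
#' signature, making the result deterministic given the seed. Negative
#' weights (combined mode) enter as magnitudes `|r|`.
#'
#' @param g Network from [build_network()] (positive-weight or combined).
#' @param seed RNG seed for the restart schedule (default 1).
#' @param restarts Number of restarts (default 100).
#' @return List of class `coreact_communities` with `membership` (named
#'   integer vector), `Q`, `n_communities`, `seed`.
#' @export
detect_communities <- function(g, seed = 1, restarts = 100) {
  n <- igraph::vcount(g)
  vnames <- igraph::V(g)$name
  if (igraph::ecount(g) == 0L) {
    memb <- setNames(seq_len(n), vnames)
    return(structure(list(membership = memb, Q = 0, n_communities = n,
                          seed = seed), class = "coreact_communities"))
  }
  w <- working_weights(g)
  gw <- igraph::set_edge_attr(g, "weight", value = w)
  best <- NULL
  best_q <- -Inf
  best_sig <- NULL
  withr::with_seed(seed, {
    for (r in seq_len(restarts)) {
      perm <- sample.int(n)
      gp <- igraph::permute(gw, perm)
      cl <- igraph::cluster_louvain(gp)
      # vertex i of g is vertex perm[i] of gp, so map memberships back
      memb <- as.integer(igraph::membership(cl))[perm]
      memb <- refine_partition(gw, memb)
      q <- modularity_score(g, memb)
      sig <- paste(as.integer(as.factor(memb)), collapse = ".")
      if (q > best_q + 1e-12 ||
          (abs(q - best_q) <= 1e-12 && !is.null(best_sig) && sig < best_sig)) {
        best_q <- q
        best <- memb
        best_sig <- sig
      }
    }
  })
  memb <- setNames(as.integer(as.factor(best)), vnames)
  structure(list(membership = memb, Q = best_q,
                 n_communities = length(unique(memb)), seed = seed),
            class = "coreact_communities")
}

# Greedy single-node moves until no move increases modularity; escapes the
# coarse local optima Louvain can leave on small graphs.
refine_partition <- function(g, membership) {
  n <- igraph::vcount(g)
  q <- modularity_score(g, membership)
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    for (v in seq_len(n)) {
      targets <- unique(c(membership[igraph::neighbors(g, v)],
                          max(membership) + 1L))
      for (tgt in setdiff(targets, membership[v])) {
        cand <- membership
        cand[v] <- tgt
        q_new <- modularity_score(g, cand)
        if (q_new > q + 1e-12) {
          membership <- cand
          q <- q_new
          improved <- TRUE
        }
      }
    }
  }
  membership
}

#' @export
print.coreact_communities <- function(x, ...) {
  cat("Community partition:", x$n_communities, "communities, Q =",
      format(x$Q, digits = 4), "\n")
  invisible(x)
}
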