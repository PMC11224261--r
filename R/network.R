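#' Build a co-reactivation network from a correlation matrix
#'
#' Converts a group correlation matrix into an undirected weighted graph whose
#' nodes are regions and whose edges carry Pearson coefficients. Sign modes:
#' \describe{
#'   \item{positive}{only pairs with `r > threshold`, edge weight `r`;}
#'   \item{negative}{only pairs with `r < -threshold`, edge weight `|r|`;}
#'   \item{combined}{all pairs with `|r| > threshold`, signed weight `r`.}
#' }
#' No magnitude or significance threshold is applied by default
#' (`threshold = 0`): sign is the only filter, so edge weights retain the
#' full correlation structure. Missing coefficients yield no edge; there are
#' no self-loops.
#'
#' @param m A `coreact_corr` object (see [correlation_matrix()]).
#' @param sign_mode One of `"positive"`, `"negative"`, `"combined"`.
#' @param threshold Optional absolute-magnitude cutoff, default 0 (off).
#' @return An `igraph` object with vertex attributes `name` and
#'   `anatomical_group`, edge attribute `weight` (and `sign` in combined
#'   mode), and graph attributes `sign_mode` and `group`.
#' @export
build_network <- function(m, sign_mode = c("positive", "negative", "combined"),
                          threshold = 0) {
  sign_mode <- match.arg(sign_mode)
  r <- m$r
  adj <- switch(sign_mode,
    positive = ifelse(!is.na(r) & r > threshold, r, 0),
    negative = ifelse(!is.na(r) & r < -threshold, -r, 0),
    combined = ifelse(!is.na(r) & abs(r) > threshold, r, 0))
  diag(adj) <- 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  if (!is.null(m$metadata)) {
    igraph::V(g)$anatomical_group <-
      m$metadata$anatomical_group[match(igraph::V(g)$name, m$metadata$region)]
  }
  if (sign_mode == "combined")
    igraph::E(g)$sign <- ifelse(igraph::E(g)$weight >= 0, "positive", "negative")
  g <- igraph::set_graph_attr(g, "sign_mode", sign_mode)
  g <- igraph::set_graph_attr(g, "group", m$group %||% NA_character_)
  g
}

# Magnitude weights used for path-based measures; in combined mode the
# centralities operate on |r| (sign recorded on the edge), an interpretation
# choice documented in the methods vignette.
working_weights <- function(g) {
  w <- igraph::E(g)$weight
  if (identical(igraph::graph_attr(g, "sign_mode"), "combined")) abs(w) else w
}

#' Node strength: average correlation with the other regions
#'
#' The sum of a node's incident edge weights divided by the number of
#' possible partners (N - 1): the average correlation coefficient of the
#' node with every other region, with absent edges contributing 0 (isolated
#' nodes score 0). In combined (signed) mode the positive and negative
#' contributions are scaled relative to each other before averaging: with
#' `s+` and `s-` the sums of positive and absolute negative incident
#' weights, the signed strength is `s+ - (s-/(s+ + s-)) * s-`, divided by
#' N - 1.
#'
#' @param g Network from [build_network()].
#' @return Named numeric vector of strengths.
#' @export
node_strength <- function(g) {
  n <- igraph::vcount(g)
  out <- setNames(numeric(n), igraph::V(g)$name)
  if (igraph::ecount(g) == 0L) return(out)
  el <- igraph::as_edgelist(g, names = FALSE)
  w <- igraph::E(g)$weight
  combined <- identical(igraph::graph_attr(g, "sign_mode"), "combined")
  deg <- tabulate(c(el[, 1], el[, 2]), nbins = n)
  if (!combined) {
    tot <- numeric(n)
    for (e in seq_along(w)) {
      tot[el[e, 1]] <- tot[el[e, 1]] + w[e]
      tot[el[e, 2]] <- tot[el[e, 2]] + w[e]
    }
    if (n > 1) out[] <- tot / (n - 1)
    return(out)
  }
  s_pos <- s_neg <- numeric(n)
  for (e in seq_along(w)) {
    i <- el[e, 1]; j <- el[e, 2]
    if (w[e] >= 0) { s_pos[i] <- s_pos[i] + w[e]; s_pos[j] <- s_pos[j] + w[e] }
    else { s_neg[i] <- s_neg[i] - w[e]; s_neg[j] <- s_neg[j] - w[e] }
  }
  tot <- s_pos + s_neg
  s_star <- numeric(n)
  pos_tot <- tot > 0
  s_star[pos_tot] <- s_pos[pos_tot] -
    (s_neg[pos_tot] / tot[pos_tot]) * s_neg[pos_tot]
  if (n > 1) out[] <- s_star / (n - 1)
  out
}

# Eigenvector centrality by power iteration on the (magnitude) weighted
# adjacency, normalised so the maximum score is 1. Disconnected graphs:
# computed on the largest connected component, other nodes score 0, with a
# warning. Invariant under uniform scaling of all edge weights.
eigenvector_centrality <- function(g, tol = 1e-10, max_iter = 10000) {
  n <- igraph::vcount(g)
  out <- setNames(numeric(n), igraph::V(g)$name)
  if (igraph::ecount(g) == 0L) return(out)
  comp <- igraph::components(g)
  main <- which.max(comp$csize)
  in_main <- comp$membership == main
  if (!all(in_main | igraph::degree(g) == 0))
    warning("disconnected network: eigenvector centrality computed on the ",
            "largest component; other nodes score 0", call. = FALSE)
  sub <- igraph::induced_subgraph(g, which(in_main))
  A <- as.matrix(igraph::as_adjacency_matrix(sub, attr = "weight",
                                             sparse = FALSE))
  A <- abs(A)
  # positive diagonal shift: leaves eigenvectors (and scale-invariance)
  # untouched but guarantees convergence on bipartite-like graphs, whose
  # +/- eigenvalue pairs make the plain iteration oscillate
  A <- A + diag(max(rowSums(A)), nrow(A))
  x <- rep(1 / sqrt(nrow(A)), nrow(A))
  for (it in seq_len(max_iter)) {
    x_new <- A %*% x
    nrm <- sqrt(sum(x_new^2))
    if (nrm == 0) break
    x_new <- as.numeric(x_new / nrm)
    if (max(abs(x_new - x)) < tol) { x <- x_new; break }
    x <- x_new
  }
  x <- abs(x)
  if (max(x) > 0) x <- x / max(x)
  out[igraph::V(sub)$name] <- x
  out
}

# Weighted shortest-path distance matrix with path length 1/weight: stronger
# correlation = shorter path, the usual convention for correlation networks.
path_distances <- function(g, binarize = FALSE) {
  if (igraph::ecount(g) == 0L) {
    n <- igraph::vcount(g)
    d <- matrix(Inf, n, n, dimnames = list(igraph::V(g)$name, igraph::V(g)$name))
    diag(d) <- 0
    return(d)
  }
  w <- working_weights(g)
  lengths <- if (binarize) rep(1, length(w)) else 1 / w
  igraph::distances(g, weights = lengths, algorithm = "dijkstra")
}

#' Centrality profile of a co-reactivation network
#'
#' Computes the four centrality measures used for hub identification plus the
#' per-node clustering coefficient:
#' \describe{
#'   \item{Str}{strength, the mean incident correlation weight
#'     ([node_strength()]);}
#'   \item{Eig}{eigenvector centrality (power iteration on the weighted
#'     adjacency, maximum normalised to 1);}
#'   \item{Bet}{betweenness: number of weighted shortest paths between node
#'     pairs passing through the node (unnormalised, fractional on ties);}
#'   \item{Clo}{closeness, reported as the inverse of the mean shortest-path
#'     length to the other nodes of the component (higher = more central);
#'     the raw mean path length is exposed as `mean_path`;}
#'   \item{CC}{clustering coefficient: fraction of a node's neighbour pairs
#'     that are themselves connected (unweighted topology).}
#' }
#' Path-based measures use length `1/weight` by default; `binarize = TRUE`
#' uses unit lengths on the same topology. Disconnected networks are handled
#' per component (Clo/Bet within components, Eig on the largest, with a
#' warning).
#'
#' @param g Network from [build_network()].
#' @param binarize Use unit path lengths instead of `1/weight` (default
#'   `FALSE`).
#' @return Data.frame of class `coreact_centrality` with one row per node:
#'   `region, anatomical_group, Str, Eig, Bet, Clo, mean_path, CC` plus rank
#'   columns `rank_Str, rank_Eig, rank_Bet, rank_Clo` (1 = most central).
#' @export
compute_centralities <- function(g, binarize = FALSE) {
  if (igraph::vcount(g) == 0L) validation_stop("empty network")
  w <- working_weights(g)
  str <- node_strength(g)
  eig <- eigenvector_centrality(g)
  bet <- if (igraph::ecount(g) == 0L)
    setNames(numeric(igraph::vcount(g)), igraph::V(g)$name)
  else igraph::betweenness(g, weights = if (binarize) rep(1, length(w)) else 1 / w,
                           normalized = FALSE)
  d <- path_distances(g, binarize = binarize)
  diag(d) <- NA
  mean_path <- apply(d, 1, function(x) {
    x <- x[is.finite(x)]
    if (length(x) == 0) NA_real_ else mean(x)
  })
  clo <- ifelse(is.na(mean_path) | mean_path == 0, 0, 1 / mean_path)
  cc <- local_clustering(g)
  out <- data.frame(
    region = igraph::V(g)$name,
    anatomical_group = if (!is.null(igraph::V(g)$anatomical_group))
      igraph::V(g)$anatomical_group else NA_character_,
    Str = as.numeric(str), Eig = as.numeric(eig), Bet = as.numeric(bet),
    Clo = as.numeric(clo), mean_path = as.numeric(mean_path),
    CC = as.numeric(cc), stringsAsFactors = FALSE)
  for (mname in c("Str", "Eig", "Bet", "Clo"))
    out[[paste0("rank_", mname)]] <- rank(-out[[mname]], ties.method = "min")
  class(out) <- c("coreact_centrality", "data.frame")
  out
}

#' Per-node clustering coefficient
#'
#' Fraction of possible connections among a node's neighbours that exist:
#' `(edges among neighbours) / (k(k-1)/2)` on the unweighted topology of the
#' chosen sign mode; nodes with fewer than two neighbours score 0.
#'
#' @param g Network from [build_network()].
#' @param node Optional node name; default all nodes.
#' @return Named numeric vector in \[0, 1\] (or scalar when `node` given).
#' @export
local_clustering <- function(g, node = NULL) {
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  cc <- setNames(ifelse(is.na(cc), 0, cc), igraph::V(g)$name)
  if (is.null(node)) return(cc)
  if (!node %in% names(cc)) validation_stop("node '", node, "' not in network")
  cc[[node]]
}

#' Identify hub regions
#'
#' A node is a hub when it falls in the top-25% candidate set for at least
#' `min_measures` of the four centralities. Per centrality the candidate set
#' holds the `ceiling(prop * N)` top-ranked nodes; ties at the cutoff score
#' are all included. A degenerate profile in which every node ties into every
#' candidate set yields all-hub output with a warning.
#'
#' @param profile Centrality profile from [compute_centralities()].
#' @param prop Candidate-set proportion (default 0.25).
#' @param min_measures Minimum number of centralities (default 3).
#' @return `profile` with logical columns `cand_Str, cand_Eig, cand_Bet,
#'   cand_Clo`, integer `n_top`, and logical `hub` appended.
#' @export
identify_hubs <- function(profile, prop = 0.25, min_measures = 3) {
  n <- nrow(profile)
  k <- ceiling(prop * n)
  measures <- c("Str", "Eig", "Bet", "Clo")
  for (mname in measures) {
    scores <- profile[[mname]]
    cutoff <- sort(scores, decreasing = TRUE)[k]
    profile[[paste0("cand_", mname)]] <- scores >= cutoff
  }
  cand <- as.matrix(profile[paste0("cand_", measures)])
  profile$n_top <- rowSums(cand)
  profile$hub <- profile$n_top >= min_measures
  if (all(profile$hub) && n > k)
    warning("degenerate centrality profile: every node ties into every ",
            "candidate set; all nodes flagged as hubs", call. = FALSE)
  profile
}

#' Global and local efficiency and degree summaries
#'
#' \describe{
#'   \item{global_efficiency}{mean over ordered node pairs of `1/d(i,j)` with
#'     `d` the weighted shortest-path distance (length `1/weight`);
#'     unreachable pairs contribute 0;}
#'   \item{local_efficiency}{mean over nodes of the global efficiency of the
#'     subgraph induced by the node's neighbours (nodes with fewer than two
#'     neighbours contribute 0);}
#'   \item{mean_cc}{average clustering coefficient;}
#'   \item{mean_degree}{average number of incident edges;}
#'   \item{mean_weighted_degree}{average sum of incident weights (magnitude
#'     weights in combined mode).}
#' }
#'
#' @param g Network from [build_network()].
#' @param binarize Use unit path lengths (default `FALSE`).
#' @return Named list with the five metrics.
#' @export
topology_metrics <- function(g, binarize = FALSE) {
  if (igraph::vcount(g) == 0L) validation_stop("empty network")
  list(global_efficiency = global_efficiency(g, binarize = binarize),
       local_efficiency = local_efficiency(g, binarize = binarize),
       mean_cc = mean(local_clustering(g)),
       mean_degree = mean(igraph::degree(g)),
       mean_weighted_degree = if (igraph::ecount(g) == 0L) 0 else
         mean(igraph::strength(g, weights = abs(igraph::E(g)$weight))))
}

global_efficiency <- function(g, binarize = FALSE) {
  n <- igraph::vcount(g)
  if (n < 2) return(0)
  d <- path_distances(g, binarize = binarize)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

local_efficiency <- function(g, binarize = FALSE) {
  n <- igraph::vcount(g)
  if (n == 0) return(0)
  effs <- vapply(seq_len(n), function(v) {
    nb <- igraph::neighbors(g, v)
    if (length(nb) < 2) return(0)
    global_efficiency(igraph::induced_subgraph(g, nb), binarize = binarize)
  }, numeric(1))
  mean(effs)
}

#' In-silico node deletion: hub vs matched non-hub removal
#'
#' Recomputes the topology metrics after deleting either the hub set or a
#' size-matched set of the least central non-hub nodes (largest composite
#' rank, i.e. the mean of the four per-centrality ranks), and reports the
#' change relative to the intact network. A larger efficiency drop after hub
#' deletion than after matched non-hub deletion indicates that hubs carry the
#' network's integration.
#'
#' @param g Network from [build_network()].
#' @param profile Hub-annotated profile from [identify_hubs()].
#' @param mode `"hubs"` or `"non_hubs"`.
#' @return List with `deleted` (node names), `intact`, `deleted_metrics`, and
#'   `delta` (deleted minus intact, per metric).
#' @export
node_deletion_efficiency <- function(g, profile, mode = c("hubs", "non_hubs")) {
  mode <- match.arg(mode)
  if (!"hub" %in% names(profile))
    schema_stop("profile lacks hub annotation; run identify_hubs() first")
  hubs <- profile$region[profile$hub]
  if (length(hubs) == 0L) validation_stop("no hubs identified")
  if (mode == "hubs") {
    del <- hubs
  } else {
    non <- profile[!profile$hub, , drop = FALSE]
    composite <- rowMeans(non[paste0("rank_", c("Str", "Eig", "Bet", "Clo"))])
    del <- non$region[order(-composite)][seq_len(min(length(hubs), nrow(non)))]
  }
  if (length(del) >= igraph::vcount(g))
    validation_stop("deletion would empty the network")
  g_del <- igraph::delete_vertices(g, del)
  intact <- topology_metrics(g)
  deleted <- topology_metrics(g_del)
  delta <- Map(function(a, b) a - b, deleted, intact)
  list(deleted = del, intact = intact, deleted_metrics = deleted,
       delta = delta)
}

#' Export a network as GraphML and a TSV edge list
#'
#' GraphML carries node attributes (`anatomical_group`, the four
#' centralities, `CC`, `hub`, `community` when supplied) and the edge weight;
#' the TSV edge list has columns `source, target, weight, sign`.
#'
#' @param g Network from [build_network()].
#' @param path_graphml,path_tsv Output paths (either may be `NULL` to skip).
#' @param profile Optional hub-annotated centrality profile.
#' @param communities Optional [detect_communities()] result.
#' @return Invisibly, the paths written.
#' @export
write_network <- function(g, path_graphml = NULL, path_tsv = NULL,
                          profile = NULL, communities = NULL) {
  if (!is.null(profile)) {
    ord <- match(igraph::V(g)$name, profile$region)
    for (col in c("Str", "Eig", "Bet", "Clo", "CC"))
      g <- igraph::set_vertex_attr(g, col, value = profile[[col]][ord])
    if ("hub" %in% names(profile))
      g <- igraph::set_vertex_attr(g, "hub", value = profile$hub[ord])
  }
  if (!is.null(communities))
    g <- igraph::set_vertex_attr(
      g, "community",
      value = as.integer(communities$membership[igraph::V(g)$name]))
  if (!is.null(path_graphml))
    igraph::write_graph(g, path_graphml, format = "graphml")
  if (!is.null(path_tsv)) {
    el <- igraph::as_edgelist(g)
    w <- igraph::E(g)$weight
    df <- data.frame(source = el[, 1], target = el[, 2], weight = w,
                     sign = ifelse(w >= 0, "positive", "negative"))
    utils::write.table(df, path_tsv, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(c(graphml = path_graphml, tsv = path_tsv))
}
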