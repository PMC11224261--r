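test_that("correlation matrix reproduces hand-computed Pearson values", {
  md <- tiny_metadata()
  vals <- cbind(r1 = c(1, 2, 3, 4), r2 = c(1, 3, 2, 4),
                r3 = c(2, 4, 6, 8), r4 = c(4, 3, 2, 1))
  rows <- rows_from_matrix(vals, "G1", md)
  m <- correlation_matrix(rows, "G1")
  expect_equal(m$r["r1", "r2"], 0.8)          # hand-evaluated Pearson
  expect_equal(m$r["r1", "r3"], 1)            # identical up to scaling
  expect_equal(m$r["r1", "r4"], -1)           # exact negation about mean
  expect_true(isTRUE(all.equal(m$r, t(m$r))))
  expect_true(all(is.na(diag(m$r))))
  R <- length(m$regions)
  expect_equal(R^2, 16)
  expect_equal(sum(!is.na(m$r[upper.tri(m$r)])), R * (R - 1) / 2)
})

test_that("too-few animals and zero-variance regions give NA with warning", {
  md <- tiny_metadata()
  vals <- cbind(r1 = c(1, 2, 3, 4), r2 = c(5, 5, 5, 5),
                r3 = c(2, 1, 4, 3), r4 = c(1, 4, 2, 3))
  rows <- rows_from_matrix(vals, "G1", md)
  expect_warning(m <- correlation_matrix(rows, "G1"), "zero across-animal")
  expect_true(all(is.na(m$r["r2", ])))
  expect_false(is.na(m$r["r1", "r3"]))

  vals2 <- cbind(r1 = c(1, 2, 3, 4), r2 = c(2, 6, 4, 3),
                 r3 = c(2, 1, 4, 3), r4 = c(1, 4, 2, 3))
  rows2 <- rows_from_matrix(vals2, "G1", md)
  sparse <- rows2[!(rows2$animal_id %in% c("G1_01", "G1_02") &
                      rows2$region == "r4"), ]
  attr(sparse, "region_metadata") <- md
  expect_warning(m2 <- correlation_matrix(sparse, "G1"), "fewer than 3")
  expect_true(is.na(m2$r["r1", "r4"]))
})

test_that("sign modes partition edges by correlation sign", {
  adj <- matrix(c(0, 0.5, -0.3,
                  0.5, 0, 0.8,
                  -0.3, 0.8, 0), 3, 3,
                dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  m <- adj_as_corr(adj)
  pos <- build_network(m, "positive")
  neg <- build_network(m, "negative")
  comb <- build_network(m, "combined")
  expect_equal(igraph::ecount(pos), 2)
  expect_equal(igraph::ecount(neg), 1)
  expect_equal(igraph::ecount(comb), 3)
  expect_equal(sort(igraph::E(pos)$weight), c(0.5, 0.8))
  expect_equal(igraph::E(neg)$weight, 0.3)   # |r| in negative mode
  expect_setequal(igraph::E(comb)$weight, c(0.5, -0.3, 0.8))

  all_pos <- adj_as_corr(matrix(0.4, 3, 3))
  expect_equal(igraph::ecount(build_network(all_pos, "positive")), 3)
  expect_equal(igraph::ecount(build_network(all_pos, "negative")), 0)
})

test_that("centralities match closed-form values on canonical graphs", {
  # triangle with equal weights: symmetric in everything
  tri <- adj_as_corr(matrix(0.6, 3, 3))
  prof <- compute_centralities(build_network(tri, "positive"))
  expect_equal(prof$Str, rep(0.6, 3))
  expect_equal(prof$Eig, rep(1, 3))
  expect_equal(prof$Bet, rep(0, 3))
  expect_equal(prof$CC, rep(1, 3))

  # path a-b-c with unit weights: Bet(b) = 1 (unnormalised pair count)
  path3 <- matrix(0, 3, 3); path3[1, 2] <- path3[2, 1] <- 1
  path3[2, 3] <- path3[3, 2] <- 1
  profp <- compute_centralities(build_network(adj_as_corr(path3), "positive"))
  expect_equal(profp$Bet, c(0, 1, 0))
  expect_equal(profp$Clo[2], 1)        # mean path 1
  expect_equal(profp$Clo[1], 1 / 1.5)  # mean of {1, 2}

  # 4-node star: centre strictly dominates every centrality
  star <- matrix(0, 4, 4); star[1, 2:4] <- star[2:4, 1] <- 1
  profs <- compute_centralities(build_network(adj_as_corr(star), "positive"))
  for (mname in c("Str", "Eig", "Bet", "Clo"))
    expect_true(all(profs[[mname]][1] > profs[[mname]][2:4]))
  expect_equal(profs$CC[1], 0)  # no neighbour-neighbour edges
})

test_that("clustering coefficient matches exhaustive triad counting", {
  # 4-clique minus one edge (1-2 removed)
  adj <- matrix(1, 4, 4); diag(adj) <- 0
  adj[1, 2] <- adj[2, 1] <- 0
  g <- build_network(adj_as_corr(adj), "positive")
  cc <- local_clustering(g)
  expect_equal(unname(cc), oracle_cc(adj))
  # a node incident to the missing edge has both remaining neighbours
  # connected (CC 1); a node not incident to it has 2 of 3 neighbour pairs
  expect_equal(unname(cc[1]), 1)
  expect_equal(unname(cc[3]), 2 / 3)
})

test_that("path-based metrics agree with brute-force oracles on random graphs", {
  withr::with_seed(51, {
    for (i in 1:60) {
      n <- sample(3:6, 1)
      adj <- random_weighted_adj(n)
      g <- build_network(adj_as_corr(adj), "positive")
      prof <- compute_centralities(g)
      expect_equal(prof$Bet, oracle_betweenness(adj), tolerance = 1e-8)
      expect_equal(prof$Clo, oracle_closeness(adj), tolerance = 1e-8)
      expect_equal(prof$CC, oracle_cc(adj), tolerance = 1e-12)
      tm <- topology_metrics(g)
      expect_equal(tm$global_efficiency, oracle_global_efficiency(adj),
                   tolerance = 1e-8)
      expect_equal(tm$local_efficiency, oracle_local_efficiency(adj),
                   tolerance = 1e-8)
    }
  })
})

test_that("eigenvector centrality is scale-invariant and matches igraph", {
  withr::with_seed(61, {
    for (i in 1:20) {
      adj <- random_weighted_adj(sample(4:7, 1))
      g <- build_network(adj_as_corr(adj), "positive")
      eig <- compute_centralities(g)$Eig
      g2 <- build_network(adj_as_corr(3.7 * adj), "positive")
      expect_equal(eig, compute_centralities(g2)$Eig, tolerance = 1e-6)
      ref <- igraph::eigen_centrality(g, weights = igraph::E(g)$weight)$vector
      expect_equal(eig, unname(ref), tolerance = 1e-6)
    }
  })
})

test_that("hub rule: top-25% candidate sets with ties, >=3 of 4 measures", {
  withr::with_seed(71, {
    adj <- random_weighted_adj(15, p_edge = 0.4)
    # make node 1 dominant everywhere
    adj[1, 2:15] <- adj[2:15, 1] <- 0.95
    g <- build_network(adj_as_corr(adj), "positive")
    prof <- identify_hubs(compute_centralities(g))
    expect_equal(sum(prof$cand_Str), 4)  # ceil(0.25 * 15)
    expect_true(prof$hub[1])
    expect_true(all(prof$n_top[prof$hub] >= 3))
  })
  # all-tie degenerate profile: every node a hub, with warning
  tri <- adj_as_corr(matrix(0.5, 5, 5))
  expect_warning(
    prof_tie <- identify_hubs(compute_centralities(build_network(tri,
                                                                 "positive"))),
    "degenerate")
  expect_true(all(prof_tie$hub))
})

test_that("modularity matches its formula and known partitions", {
  # two disconnected triangles: natural partition scores exactly 0.5
  adj <- matrix(0, 6, 6)
  adj[1:3, 1:3] <- 1; adj[4:6, 4:6] <- 1; diag(adj) <- 0
  g <- build_network(adj_as_corr(adj), "positive")
  expect_equal(modularity_score(g, c(1, 1, 1, 2, 2, 2)), 0.5)
  expect_equal(modularity_score(g, rep(1, 6)), 0)  # one community
  withr::with_seed(81, {
    for (i in 1:40) {
      radj <- random_weighted_adj(sample(4:7, 1))
      gg <- build_network(adj_as_corr(radj), "positive")
      memb <- sample(1:3, igraph::vcount(gg), replace = TRUE)
      expect_equal(modularity_score(gg, memb), oracle_modularity(radj, memb),
                   tolerance = 1e-12)
      ig <- igraph::modularity(gg, memb, weights = igraph::E(gg)$weight)
      expect_equal(modularity_score(gg, memb), ig, tolerance = 1e-10)
    }
  })
})

test_that("community detection recovers exhaustive-optimal partitions", {
  # two disconnected triangles
  adj <- matrix(0, 6, 6)
  adj[1:3, 1:3] <- 1; adj[4:6, 4:6] <- 1; diag(adj) <- 0
  g <- build_network(adj_as_corr(adj), "positive")
  comm <- detect_communities(g, seed = 1, restarts = 20)
  expect_equal(comm$Q, 0.5)
  expect_equal(comm$n_communities, 2)

  # complete graph with equal weights: one community is optimal
  full <- adj_as_corr(matrix(0.7, 5, 5))
  commf <- detect_communities(build_network(full, "positive"),
                              seed = 1, restarts = 20)
  expect_equal(commf$n_communities, 1)
  expect_equal(commf$Q, 0)

  # planted two-block weighted network: blocks recovered exactly
  planted <- matrix(0.05, 8, 8)
  planted[1:4, 1:4] <- 0.8; planted[5:8, 5:8] <- 0.8; diag(planted) <- 0
  gp <- build_network(adj_as_corr(planted), "positive")
  commp <- detect_communities(gp, seed = 3, restarts = 30)
  expect_equal(unname(commp$membership[1:4]),
               rep(commp$membership[[1]], 4))
  expect_equal(unname(commp$membership[5:8]),
               rep(commp$membership[[5]], 4))
  best <- oracle_best_partition(planted)
  expect_equal(commp$Q, best$Q, tolerance = 1e-10)

  # random graphs: Q equals exhaustive maximum
  withr::with_seed(91, {
    for (i in 1:15) {
      radj <- random_weighted_adj(sample(4:7, 1))
      gg <- build_network(adj_as_corr(radj), "positive")
      found <- detect_communities(gg, seed = i, restarts = 40)
      expect_equal(found$Q, oracle_best_partition(radj)$Q, tolerance = 1e-9)
    }
  })

  # determinism given the seed
  c1 <- detect_communities(g, seed = 7, restarts = 10)
  c2 <- detect_communities(g, seed = 7, restarts = 10)
  expect_identical(c1$membership, c2$membership)
})

test_that("topology metrics on canonical graphs", {
  full <- adj_as_corr(matrix(1, 4, 4))
  tm <- topology_metrics(build_network(full, "positive"))
  expect_equal(tm$global_efficiency, 1)
  path3 <- matrix(0, 3, 3); path3[1, 2] <- path3[2, 1] <- 1
  path3[2, 3] <- path3[3, 2] <- 1
  tmp <- topology_metrics(build_network(adj_as_corr(path3), "positive"))
  expect_equal(tmp$global_efficiency, 5 / 6)  # pairs {1,1,1/2} both ways
  empty <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(empty)$name <- c("a", "b", "c")
  tme <- topology_metrics(empty)
  expect_equal(unname(unlist(tme)), rep(0, 5))
})

test_that("hub deletion is compared against matched non-hub deletion", {
  withr::with_seed(101, {
    adj <- random_weighted_adj(10, p_edge = 0.3, w_min = 0.05, w_max = 0.2)
    adj[1, 2:10] <- adj[2:10, 1] <- 0.9   # planted hub
    adj[2, 3:10] <- adj[3:10, 2] <- 0.85  # second planted hub
    g <- build_network(adj_as_corr(adj), "positive")
    prof <- identify_hubs(compute_centralities(g))
    expect_true(all(prof$hub[1:2]))
    del_h <- node_deletion_efficiency(g, prof, "hubs")
    del_n <- node_deletion_efficiency(g, prof, "non_hubs")
    expect_equal(length(del_n$deleted), length(del_h$deleted))
    expect_true(all(!del_n$deleted %in% del_h$deleted))
    expect_lt(del_h$delta$global_efficiency, del_n$delta$global_efficiency)
  })
  # deleting everything is refused
  tri <- build_network(adj_as_corr(matrix(0.5, 3, 3)), "positive")
  prof_tri <- suppressWarnings(identify_hubs(compute_centralities(tri)))
  expect_error(node_deletion_efficiency(tri, prof_tri, "hubs"),
               class = "coreact_validation_error")
})

test_that("mean group connectivity averages exactly the cross-set pairs", {
  md <- tiny_metadata()  # r1, r2 amygdala; r3 PH; r4 mPFC
  r <- matrix(NA_real_, 4, 4, dimnames = list(md$region, md$region))
  r["r1", "r3"] <- r["r3", "r1"] <- 0.5
  r["r2", "r3"] <- r["r3", "r2"] <- 0.5
  r["r1", "r4"] <- r["r4", "r1"] <- 0.2
  r["r2", "r4"] <- r["r4", "r2"] <- 0.4
  r["r3", "r4"] <- r["r4", "r3"] <- 0.9
  r["r1", "r2"] <- r["r2", "r1"] <- 0.99  # within-set, must be excluded
  m <- structure(list(group = "G", regions = md$region, r = r,
                      n_animals = 4, metadata = md), class = "coreact_corr")
  expect_equal(mean_group_connectivity(m, "amygdala", "PH"), 0.5)
  expect_equal(mean_group_connectivity(m, "amygdala", "mPFC"), 0.3)
  # amygdala vs all others: pairs r1/r2 x r3/r4 -> mean of 0.5,0.5,0.2,0.4
  expect_equal(mean_group_connectivity(m, "amygdala"), 0.4)
  expect_error(mean_group_connectivity(m, "amygdala", "amygdala"),
               class = "coreact_validation_error")
  expect_error(mean_group_connectivity(m, "cerebellum", "PH"),
               class = "coreact_validation_error")
  # constant off-diagonal: every selector pair returns the constant
  rc <- matrix(0.33, 4, 4, dimnames = list(md$region, md$region))
  diag(rc) <- NA
  mc <- structure(list(group = "G", regions = md$region, r = rc,
                       n_animals = 4, metadata = md), class = "coreact_corr")
  expect_equal(mean_group_connectivity(mc, "amygdala", "PH"), 0.33)
  expect_equal(mean_group_connectivity(mc, "PH"), 0.33)
})

test_that("combined-mode strength applies the signed decomposition", {
  adj <- matrix(c(0, 0.6, -0.4,
                  0.6, 0, 0.2,
                  -0.4, 0.2, 0), 3, 3,
                dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  g <- build_network(adj_as_corr(adj), "combined")
  s <- node_strength(g)
  # node a: s+ = 0.6, s- = 0.4 -> (0.6 - 0.4/(1.0) * 0.4) / 2 edges
  expect_equal(unname(s["a"]), (0.6 - 0.4 * 0.4 / 1.0) / 2)
  expect_equal(unname(s["b"]), (0.8 - 0) / 2)
})

test_that("networks export to GraphML and TSV with attributes", {
  withr::with_seed(111, {
    adj <- random_weighted_adj(5)
    m <- adj_as_corr(adj, metadata = data.frame(
      region = sprintf("R%02d", 1:5),
      anatomical_group = c("mPFC", "amygdala", "amygdala", "PH",
                           "hippocampus")))
    g <- build_network(m, "positive")
    prof <- suppressWarnings(identify_hubs(compute_centralities(g)))
    comm <- detect_communities(g, seed = 1, restarts = 10)
    gml <- file.path(tempdir(), "net.graphml")
    tsv <- file.path(tempdir(), "net.tsv")
    write_network(g, gml, tsv, profile = prof, communities = comm)
    back <- igraph::read_graph(gml, format = "graphml")
    expect_equal(igraph::ecount(back), igraph::ecount(g))
    expect_true(all(c("anatomical_group", "Str", "hub", "community") %in%
                      igraph::vertex_attr_names(back)))
    edges <- read.delim(tsv)
    expect_equal(nrow(edges), igraph::ecount(g))
    expect_equal(sort(names(edges)), sort(c("source", "target", "weight",
                                            "sign")))
  })
})
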