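## Group-label permutation tests.
##
## All tests share one resampling scheme: the animals of the two groups are
## pooled, group labels are reshuffled without replacement preserving the
## group sizes, and the statistic is recomputed from the jointly relabeled
## data. The p-value follows the literal resampling formula
## p = (# null > empirical) / B (one-sided greater); the bias-corrected
## (k + 1)/(B + 1) value is reported alongside as p_corrected.

new_permutation_result <- function(statistic_name, empirical, null_sample,
                                   B, seed, n_redraws = 0) {
  p <- sum(null_sample > empirical) / B
  structure(list(statistic_name = statistic_name,
                 empirical = empirical,
                 null_sample = null_sample,
                 B = B,
                 p = p,
                 p_corrected = (sum(null_sample > empirical) + 1) / (B + 1),
                 side = "greater",
                 seed = seed,
                 n_redraws = n_redraws),
            class = "coreact_permutation")
}

#' @export
print.coreact_permutation <- function(x, ...) {
  cat("Permutation test:", x$statistic_name, "\n",
      "empirical =", format(x$empirical, digits = 4),
      " B =", x$B, " p =", format(x$p, digits = 4),
      " p_corrected =", format(x$p_corrected, digits = 4), "\n")
  invisible(x)
}

# Wide animal x region matrix of `value` for the pooled animals of two
# groups, plus the observed group labels.
pooled_matrix <- function(rows, groups, regions, value = "double_pct") {
  sub <- rows[rows$group %in% groups, , drop = FALSE]
  if (nrow(sub) == 0L) validation_stop("no rows for groups ",
                                       paste(groups, collapse = ", "))
  animals <- unique(sub$animal_id)
  labels <- sub$group[match(animals, sub$animal_id)]
  wide <- matrix(NA_real_, length(animals), length(regions),
                 dimnames = list(animals, regions))
  idx <- cbind(match(sub$animal_id, animals), match(sub$region, regions))
  keep <- !is.na(idx[, 2])
  wide[idx[keep, , drop = FALSE]] <- sub[[value]][keep]
  if (any(table(labels) < 3))
    validation_stop("fewer than 3 animals in a group; permutation test ",
                    "requires at least 3 per group")
  list(wide = wide, labels = labels, animals = animals)
}

shuffle_labels <- function(labels) sample(labels, length(labels), replace = FALSE)

MAX_REDRAW_FACTOR <- 100L

# Shared resampling engine: `stat_fn(wide, labels)` returns a numeric
# statistic (possibly a vector for family tests) or NULL when undefined for
# the relabeling (e.g. a zero-variance region), in which case the shuffle is
# redrawn, with the redraw count recorded.
permutation_engine <- function(wide, labels, stat_fn, B, seed) {
  if (!is_scalar_number(B) || B < 1 || B != floor(B))
    validation_stop("B must be a positive integer resample count")
  empirical <- stat_fn(wide, labels)
  if (is.null(empirical))
    validation_stop("statistic undefined on the observed labeling")
  null_sample <- matrix(NA_real_, nrow = B, ncol = length(empirical))
  n_redraws <- 0L
  withr::with_seed(seed, {
    b <- 1L
    attempts <- 0L
    while (b <= B) {
      attempts <- attempts + 1L
      if (attempts > MAX_REDRAW_FACTOR * B)
        coreact_stop("too many undefined resamples (", n_redraws,
                     " redraws); statistic cannot be permuted on these data")
      val <- stat_fn(wide, shuffle_labels(labels))
      if (is.null(val)) {
        n_redraws <- n_redraws + 1L
        next
      }
      null_sample[b, ] <- val
      b <- b + 1L
    }
  })
  if (n_redraws > 0)
    message(n_redraws, " resample(s) redrawn (undefined statistic under ",
            "the shuffled labeling)")
  list(empirical = empirical, null_sample = null_sample, n_redraws = n_redraws)
}

safe_pearson <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) return(NULL)
  if (sd(x[ok]) == 0 || sd(y[ok]) == 0) return(NULL)
  cor(x[ok], y[ok])
}

#' Permutation test for one edge (correlation) difference
#'
#' Tests the absolute difference in the across-animal Pearson correlation of
#' reactivation between two groups for one region pair. Each resample
#' shuffles the pooled animal group labels without replacement (group sizes
#' preserved), recomputes both correlations jointly from the single shuffled
#' labeling, and records the absolute difference. Resamples where either
#' shuffled group has a zero-variance region for the pair are redrawn, with
#' the redraw count reported.
#'
#' @param rows Reactivation table ([reactivation_table()]).
#' @param groups Character vector of the two group labels.
#' @param region_pair Character vector of the two region names.
#' @param B Number of resamples (default 1000).
#' @param seed RNG seed.
#' @param value Column correlated (default `"double_pct"`).
#' @return A `coreact_permutation` result with `p = (# null > empirical)/B`.
#' @export
permute_edge_difference <- function(rows, groups, region_pair, B = 1000,
                                    seed = 1, value = "double_pct") {
  stopifnot(length(groups) == 2L, length(region_pair) == 2L)
  pm <- pooled_matrix(rows, groups, regions = region_pair, value = value)
  stat_fn <- function(wide, labels) {
    r1 <- safe_pearson(wide[labels == groups[1], 1],
                       wide[labels == groups[1], 2])
    r2 <- safe_pearson(wide[labels == groups[2], 1],
                       wide[labels == groups[2], 2])
    if (is.null(r1) || is.null(r2)) return(NULL)
    abs(r1 - r2)
  }
  eng <- permutation_engine(pm$wide, pm$labels, stat_fn, B, seed)
  new_permutation_result(
    paste0("edge_absdiff:", region_pair[1], "-", region_pair[2]),
    eng$empirical, as.numeric(eng$null_sample), B, seed, eng$n_redraws)
}

#' Permutation test for one node centrality difference
#'
#' Empirical statistic: the difference (two groups' intact networks) in one
#' centrality measure for one node. Each resample relabels the animals,
#' rebuilds both group correlation matrices and networks under the chosen
#' sign mode, and recomputes the centrality difference.
#'
#' @inheritParams permute_edge_difference
#' @param node Region name.
#' @param centrality One of `"Str"`, `"Eig"`, `"Bet"`, `"Clo"`.
#' @param sign_mode Network sign mode (see [build_network()]).
#' @param metadata Region metadata; defaults to that attached to `rows`.
#' @param absolute Use the absolute difference (default `TRUE`, matching the
#'   edge test); set `FALSE` for the signed group-1 minus group-2 difference.
#' @return A `coreact_permutation` result.
#' @export
permute_centrality_difference <- function(rows, groups, node,
                                          centrality = c("Str", "Eig", "Bet", "Clo"),
                                          sign_mode = "positive",
                                          B = 1000, seed = 1,
                                          metadata = NULL,
                                          value = "double_pct",
                                          absolute = TRUE) {
  stopifnot(length(groups) == 2L)
  centrality <- match.arg(centrality)
  metadata <- metadata %||% attr(rows, "region_metadata") %||%
    default_region_metadata()
  regions <- intersect(metadata$region, unique(rows$region))
  if (!node %in% regions) validation_stop("node '", node, "' not in data")
  pm <- pooled_matrix(rows, groups, regions = regions, value = value)
  stat_fn <- function(wide, labels) {
    vals <- vapply(groups, function(gname) {
      sub <- wide[labels == gname, , drop = FALSE]
      r <- suppressWarnings(cor(sub, use = "pairwise.complete.obs"))
      if (all(is.na(r[node, setdiff(regions, node)]))) return(NA_real_)
      m <- structure(list(group = gname, regions = regions, r = r,
                          n_animals = nrow(sub), metadata = metadata),
                     class = "coreact_corr")
      net <- build_network(m, sign_mode = sign_mode)
      prof <- suppressWarnings(compute_centralities(net))
      prof[[centrality]][prof$region == node]
    }, numeric(1))
    if (any(is.na(vals))) return(NULL)
    d <- unname(vals[1] - vals[2])
    if (absolute) abs(d) else d
  }
  eng <- permutation_engine(pm$wide, pm$labels, stat_fn, B, seed)
  new_permutation_result(
    paste0("centrality_diff:", centrality, ":", node, ":", sign_mode),
    eng$empirical, as.numeric(eng$null_sample), B, seed, eng$n_redraws)
}

#' Permutation test for anatomical-group connectivity difference
#'
#' Empirical statistic: the difference between groups in the mean Pearson
#' coefficient over region pairs crossing two anatomical-group selectors
#' (see [mean_group_connectivity()]). Null by joint group-label shuffling.
#'
#' @inheritParams permute_centrality_difference
#' @param selector_a,selector_b Anatomical-group selectors
#'   (`selector_b = NULL` means all other regions).
#' @return A `coreact_permutation` result.
#' @export
permute_connectivity_difference <- function(rows, groups, selector_a,
                                            selector_b = NULL,
                                            B = 1000, seed = 1,
                                            metadata = NULL,
                                            value = "double_pct",
                                            absolute = TRUE) {
  stopifnot(length(groups) == 2L)
  metadata <- metadata %||% attr(rows, "region_metadata") %||%
    default_region_metadata()
  regions <- intersect(metadata$region, unique(rows$region))
  pm <- pooled_matrix(rows, groups, regions = regions, value = value)
  stat_fn <- function(wide, labels) {
    vals <- vapply(groups, function(gname) {
      sub <- wide[labels == gname, , drop = FALSE]
      r <- suppressWarnings(cor(sub, use = "pairwise.complete.obs"))
      m <- structure(list(group = gname, regions = regions, r = r,
                          n_animals = nrow(sub), metadata = metadata),
                     class = "coreact_corr")
      diag(m$r) <- NA_real_
      tryCatch(mean_group_connectivity(m, selector_a, selector_b),
               coreact_validation_error = function(e) NA_real_)
    }, numeric(1))
    if (any(is.na(vals))) return(NULL)
    d <- unname(vals[1] - vals[2])
    if (absolute) abs(d) else d
  }
  eng <- permutation_engine(pm$wide, pm$labels, stat_fn, B, seed)
  sel_name <- paste0(paste(selector_a, collapse = "+"), "-vs-",
                     if (is.null(selector_b)) "others"
                     else paste(selector_b, collapse = "+"))
  new_permutation_result(paste0("connectivity_diff:", sel_name),
                         eng$empirical, as.numeric(eng$null_sample), B, seed,
                         eng$n_redraws)
}

#' Family-wise edge permutation tests over all region pairs
#'
#' Runs the edge-difference permutation jointly for every region pair: one
#' shuffle per resample recomputes both full correlation matrices, so all
#' pairs share the same relabelings. Raw p-values from the whole family are
#' then adjusted together with [bh_adjust()] ("adjusted globally").
#'
#' @inheritParams permute_centrality_difference
#' @return Data.frame with one row per region pair: `region_a, region_b,
#'   empirical, p, p_corrected, raw_product, adj_p, B, seed`.
#' @export
permute_edge_family <- function(rows, groups, B = 1000, seed = 1,
                                metadata = NULL, value = "double_pct") {
  stopifnot(length(groups) == 2L)
  metadata <- metadata %||% attr(rows, "region_metadata") %||%
    default_region_metadata()
  regions <- intersect(metadata$region, unique(rows$region))
  pm <- pooled_matrix(rows, groups, regions = regions, value = value)
  pair_idx <- which(upper.tri(diag(length(regions))), arr.ind = TRUE)
  stat_fn <- function(wide, labels) {
    r1 <- suppressWarnings(cor(wide[labels == groups[1], , drop = FALSE],
                               use = "pairwise.complete.obs"))
    r2 <- suppressWarnings(cor(wide[labels == groups[2], , drop = FALSE],
                               use = "pairwise.complete.obs"))
    abs(r1[pair_idx] - r2[pair_idx])
  }
  eng <- permutation_engine(pm$wide, pm$labels, stat_fn, B, seed)
  emp <- eng$empirical
  p <- colSums(eng$null_sample > rep(emp, each = B), na.rm = TRUE) / B
  labels_out <- paste(regions[pair_idx[, 1]], regions[pair_idx[, 2]], sep = "-")
  adj <- bh_adjust(p, labels = labels_out)
  out <- data.frame(region_a = regions[pair_idx[, 1]],
                    region_b = regions[pair_idx[, 2]],
                    empirical = emp, p = p,
                    p_corrected = (p * B + 1) / (B + 1),
                    raw_product = adj$raw_product, adj_p = adj$adj_p,
                    B = B, seed = seed, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Family-wise centrality permutation tests over all nodes
#'
#' One shuffle per resample rebuilds both group networks and recomputes all
#' four centralities for every node, so the whole family shares relabelings;
#' p-values are BH-adjusted globally per centrality family.
#'
#' @inheritParams permute_centrality_difference
#' @param centralities Centralities to test (default all four).
#' @return Data.frame with one row per node x centrality.
#' @export
permute_centrality_family <- function(rows, groups,
                                      centralities = c("Str", "Eig", "Bet", "Clo"),
                                      sign_mode = "positive", B = 1000,
                                      seed = 1, metadata = NULL,
                                      value = "double_pct") {
  stopifnot(length(groups) == 2L)
  metadata <- metadata %||% attr(rows, "region_metadata") %||%
    default_region_metadata()
  regions <- intersect(metadata$region, unique(rows$region))
  pm <- pooled_matrix(rows, groups, regions = regions, value = value)
  n_r <- length(regions)
  stat_fn <- function(wide, labels) {
    profs <- lapply(groups, function(gname) {
      sub <- wide[labels == gname, , drop = FALSE]
      r <- suppressWarnings(cor(sub, use = "pairwise.complete.obs"))
      m <- structure(list(group = gname, regions = regions, r = r,
                          n_animals = nrow(sub), metadata = metadata),
                     class = "coreact_corr")
      net <- build_network(m, sign_mode = sign_mode)
      suppressWarnings(compute_centralities(net))
    })
    vals <- unlist(lapply(centralities, function(cn) {
      a <- profs[[1]][[cn]][match(regions, profs[[1]]$region)]
      b <- profs[[2]][[cn]][match(regions, profs[[2]]$region)]
      abs(a - b)
    }))
    if (any(is.na(vals))) return(NULL)
    vals
  }
  eng <- permutation_engine(pm$wide, pm$labels, stat_fn, B, seed)
  emp <- eng$empirical
  p <- colSums(eng$null_sample > rep(emp, each = B), na.rm = TRUE) / B
  out <- data.frame(
    region = rep(regions, times = length(centralities)),
    centrality = rep(centralities, each = n_r),
    empirical = emp, p = p, p_corrected = (p * B + 1) / (B + 1),
    B = B, seed = seed, stringsAsFactors = FALSE)
  adj <- bh_adjust(out$p, labels = paste(out$centrality, out$region, sep = ":"))
  out$raw_product <- adj$raw_product
  out$adj_p <- adj$adj_p
  rownames(out) <- NULL
  out
}

#' Serialise permutation results to JSON
#'
#' Writes a list of `coreact_permutation` results (or a family data.frame) as
#' a JSON array of records with `statistic_name, empirical, p, p_corrected,
#' B, seed, family_id`.
#'
#' @param results List of `coreact_permutation` objects or a family
#'   data.frame.
#' @param path Output path.
#' @param family_id Family identifier stored with every record.
#' @param null_sample_dir Optional directory: the full null sample of each
#'   `coreact_permutation` result is additionally written there as a
#'   single-column text file named after the statistic.
#' @return `path`, invisibly.
#' @export
write_permutation_json <- function(results, path, family_id = "family1",
                                   null_sample_dir = NULL) {
  if (is.data.frame(results)) {
    results$family_id <- family_id
    jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  } else {
    recs <- lapply(results, function(x)
      list(statistic_name = x$statistic_name, empirical = x$empirical,
           p = x$p, p_corrected = x$p_corrected, B = x$B, seed = x$seed,
           family_id = family_id))
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
    if (!is.null(null_sample_dir)) {
      dir.create(null_sample_dir, recursive = TRUE, showWarnings = FALSE)
      for (x in results) {
        fname <- paste0(gsub("[^A-Za-z0-9._-]", "_", x$statistic_name),
                        "_null.txt")
        writeLines(format(x$null_sample, digits = 17),
                   file.path(null_sample_dir, fname))
      }
    }
  }
  invisible(path)
}
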