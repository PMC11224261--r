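#' Simulation configuration for synthetic tagged-cell counts
#'
#' Validates and assembles the full parameterisation of the count generator:
#' group sizes, region panel, expected DAPI+ count, marginal labeling
#' probabilities, target observed/chance reactivation ratios, animal-level
#' rate dispersion, and the per-group target correlation matrix of the
#' latent reactivation rates (Gaussian copula).
#'
#' @param groups Data.frame with columns `name`, `n_animals`.
#' @param regions Region metadata data.frame (`region`, `anatomical_group`);
#'   defaults to the built-in 15-region panel.
#' @param dapi_mean Expected DAPI+ cells per animal x region (Poisson mean,
#'   default 5000).
#' @param p_td,p_cfos Marginal labeling probabilities in (0, 1): a scalar, a
#'   region-named vector, or a region x group matrix.
#' @param ratio Target reactivation ratio (>= 0), same shapes accepted.
#' @param sigma_animal Log-scale animal-level dispersion of labeling rates
#'   (default 0.3).
#' @param corr Region x region target correlation matrix (unit diagonal,
#'   positive semidefinite), or a named list with one matrix per group;
#'   default identity.
#' @return List of class `coreact_sim_config`.
#' @export
simulation_config <- function(groups,
                              regions = default_region_metadata(),
                              dapi_mean = 5000,
                              p_td = 0.06, p_cfos = 0.03, ratio = 1,
                              sigma_animal = 0.3,
                              corr = NULL) {
  if (!is.data.frame(groups) || !all(c("name", "n_animals") %in% names(groups)))
    schema_stop("groups must be a data.frame with columns name, n_animals")
  if (any(groups$n_animals < 1))
    validation_stop("each group needs at least one animal")
  regions <- validate_region_metadata(regions)
  R <- nrow(regions)
  gn <- groups$name

  expand <- function(x, what, lo, hi) {
    if (is.matrix(x)) {
      if (nrow(x) != R || ncol(x) != length(gn))
        schema_stop(what, " matrix must be regions x groups")
      out <- x
    } else if (length(x) == R) {
      out <- matrix(x, R, length(gn))
    } else if (length(x) == 1L) {
      out <- matrix(x, R, length(gn))
    } else schema_stop(what, " must be scalar, per-region, or regions x groups")
    dimnames(out) <- list(regions$region, gn)
    if (any(out < lo) || (is.finite(hi) && any(out >= hi)))
      validation_stop(what, " out of range [", lo, ", ", hi, ")")
    out
  }
  p_td <- expand(p_td, "p_td", 1e-8, 1)
  p_cfos <- expand(p_cfos, "p_cfos", 1e-8, 1)
  ratio <- expand(ratio, "ratio", 0, Inf)

  if (is.null(corr)) corr <- diag(R)
  if (is.matrix(corr)) corr <- setNames(rep(list(corr), length(gn)), gn)
  if (!all(gn %in% names(corr)))
    schema_stop("corr list must name every group")
  for (g in gn) {
    cm <- corr[[g]]
    if (!isTRUE(all.equal(cm, t(cm), tolerance = 1e-8)))
      validation_stop("corr for group '", g, "' is not symmetric")
    if (any(abs(diag(cm) - 1) > 1e-8))
      validation_stop("corr for group '", g, "' must have unit diagonal")
    ev <- eigen(cm, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8)
      validation_stop("corr for group '", g,
                      "' is not positive semidefinite: smallest eigenvalue ",
                      format(min(ev), digits = 6))
    dimnames(corr[[g]]) <- list(regions$region, regions$region)
  }

  structure(list(groups = groups, regions = regions, dapi_mean = dapi_mean,
                 p_td = p_td, p_cfos = p_cfos, ratio = ratio,
                 sigma_animal = sigma_animal, corr = corr),
            class = "coreact_sim_config")
}

# Factor L with L %*% z ~ MVN(0, corr) for standard normal z; built from the
# eigen-decomposition so near-PSD matrices (tiny negative eigenvalues from
# floating point) are handled by truncation at 0.
copula_factor <- function(corr) {
  es <- eigen(corr, symmetric = TRUE)
  es$vectors %*% diag(sqrt(pmax(es$values, 0)), nrow = length(es$values))
}

#' Generate a synthetic tagged-cell count dataset
#'
#' Per animal x region: `n_dapi ~ Poisson(dapi_mean)`; a latent animal-level
#' field `z` drawn from a zero-mean multivariate normal with the group's
#' target correlation matrix (Gaussian copula across regions) modulates both
#' marginal labeling rates on the log scale,
#' `rate = p * exp(sigma_animal * z - sigma_animal^2/2)`;
#' `n_td` and `n_cfos` are binomial draws at the modulated rates; double
#' labeling is drawn conditionally on the realised counts,
#' `n_double ~ Binomial(n_td, ratio * n_cfos / n_dapi)`, so that the expected
#' reactivation ratio given the counts equals the planted `ratio` and
#' `n_double <= n_td` by construction. Infeasible double-label rates (above 1
#' or exceeding `n_cfos`) are clamped and counted; a configuration clamping
#' more than `max_clamp_frac` of cells fails fast, since silent clamping
#' would corrupt the ground truth.
#'
#' Because the correlation is planted on latent log-rates, the realised
#' across-animal Pearson correlation of `double_pct` is attenuated slightly
#' by binomial counting noise and the log-normal transform; convergence to
#' the target is a large-n property.
#'
#' @param cfg A `coreact_sim_config`.
#' @param seed RNG seed (the dataset is fully determined by `cfg` + `seed`).
#' @param max_clamp_frac Maximum tolerated fraction of clamped cells
#'   (default 0.01).
#' @return Validated counts data.frame with attributes `ground_truth` (all
#'   planted parameters, seed, clamp count) and `region_metadata`.
#' @export
generate_dataset <- function(cfg, seed = 1, max_clamp_frac = 0.01) {
  stopifnot(inherits(cfg, "coreact_sim_config"))
  R <- nrow(cfg$regions)
  recs <- vector("list", sum(cfg$groups$n_animals))
  clamped <- 0L
  total_cells <- 0L
  k <- 0L
  withr::with_seed(seed, {
    for (gi in seq_len(nrow(cfg$groups))) {
      gname <- cfg$groups$name[gi]
      L <- copula_factor(cfg$corr[[gname]])
      for (a in seq_len(cfg$groups$n_animals[gi])) {
        aid <- sprintf("%s_%02d", gname, a)
        z <- as.numeric(L %*% rnorm(R))
        mod <- exp(cfg$sigma_animal * z - cfg$sigma_animal^2 / 2)
        rate_td <- pmin(cfg$p_td[, gname] * mod, 0.999)
        rate_cfos <- pmin(cfg$p_cfos[, gname] * mod, 0.999)
        n_dapi <- rpois(R, cfg$dapi_mean)
        n_dapi <- pmax(n_dapi, 1L)
        n_td <- rbinom(R, n_dapi, rate_td)
        n_cfos <- rbinom(R, n_dapi, rate_cfos)
        q <- cfg$ratio[, gname] * n_cfos / n_dapi
        over <- q > 1
        clamped <- clamped + sum(over)
        n_double <- rbinom(R, n_td, pmin(q, 1))
        cap <- n_double > n_cfos
        clamped <- clamped + sum(cap)
        n_double <- pmin(n_double, n_cfos)
        total_cells <- total_cells + R
        k <- k + 1L
        recs[[k]] <- data.frame(
          animal_id = aid, group = gname, region = cfg$regions$region,
          n_dapi = n_dapi, n_td = n_td, n_cfos = n_cfos, n_double = n_double,
          stringsAsFactors = FALSE)
      }
    }
  })
  counts <- do.call(rbind, recs)
  if (clamped / total_cells > max_clamp_frac)
    coreact_stop("infeasible double-label rates clamped in ",
                 clamped, "/", total_cells, " cells (> ",
                 100 * max_clamp_frac, "%); adjust ratio/p_td/p_cfos")
  counts <- validate_counts(counts, cfg$regions)
  attr(counts, "ground_truth") <- list(
    groups = cfg$groups, dapi_mean = cfg$dapi_mean,
    p_td = cfg$p_td, p_cfos = cfg$p_cfos, ratio = cfg$ratio,
    sigma_animal = cfg$sigma_animal, corr = cfg$corr,
    seed = seed, n_clamped = clamped)
  counts
}

#' Block-structured target correlation matrix
#'
#' Convenience constructor of planted-structure correlation matrices for
#' [simulation_config()]: `within` inside each listed anatomical-group block
#' (a character vector of anatomical groups whose member regions are fully
#' coupled), `background` elsewhere, unit diagonal. If the result is not
#' positive semidefinite it is shrunk toward the identity just enough to
#' restore semidefiniteness.
#'
#' @param regions Region metadata data.frame.
#' @param blocks List of character vectors of anatomical groups; each vector
#'   forms one high-correlation block.
#' @param within,background Correlation inside blocks / elsewhere.
#' @return Region x region correlation matrix.
#' @export
block_corr <- function(regions, blocks, within = 0.8, background = 0.1) {
  R <- nrow(regions)
  cm <- matrix(background, R, R,
               dimnames = list(regions$region, regions$region))
  for (bl in blocks) {
    members <- regions$region[regions$anatomical_group %in% bl]
    cm[members, members] <- within
  }
  diag(cm) <- 1
  ev <- eigen(cm, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 0) {
    lambda <- min(ev) / (min(ev) - 1)   # convex shrink toward identity
    cm <- (1 - lambda) * cm + lambda * diag(R)
    dimnames(cm) <- list(regions$region, regions$region)
  }
  cm
}

#' Study-like synthetic dataset preset
#'
#' Emulates the tagging study's design: three groups (CFC n = 7, CFC-5s
#' n = 6, HC n = 6) over the default 15-region panel, with marginal Td+ and
#' c-Fos+ rates set to the published group-mean labeling percentages,
#' above-chance reactivation ratios in the conditioned groups and
#' chance-level (ratio = 1) reactivation in the homecage group, a planted
#' high-correlation amygdala-PH block in the CFC-5s-like group and a
#' hippocampus-PH block in the CFC-like group.
#'
#' @param seed RNG seed.
#' @param n_cfc,n_cfc5s,n_hc Group sizes (defaults 7, 6, 6).
#' @param within,background Planted within-block and background correlations
#'   (defaults 0.8 and 0.1).
#' @return Counts data.frame with `ground_truth` attribute, as from
#'   [generate_dataset()].
#' @export
preset_study_like <- function(seed = 1, n_cfc = 7, n_cfc5s = 6, n_hc = 6,
                              within = 0.8, background = 0.1) {
  regions <- default_region_metadata()
  rates <- study_marginal_rates()
  groups <- data.frame(name = c("CFC", "CFC-5s", "HC"),
                       n_animals = c(n_cfc, n_cfc5s, n_hc))
  ratio <- cbind(CFC = rep(2.5, 15), `CFC-5s` = rep(2.5, 15),
                 HC = rep(1, 15))
  rownames(ratio) <- regions$region
  corr <- list(
    CFC = block_corr(regions, list(c("hippocampus", "PH")),
                     within = within, background = background),
    `CFC-5s` = block_corr(regions, list(c("amygdala", "PH")),
                          within = within, background = background),
    HC = block_corr(regions, list(), within = within,
                    background = background))
  cfg <- simulation_config(
    groups = groups, regions = regions, dapi_mean = 5000,
    p_td = rates$td_pct / 100, p_cfos = rates$cfos_pct / 100,
    ratio = ratio, sigma_animal = 0.3, corr = corr)
  generate_dataset(cfg, seed = seed)
}

#' Write the ground truth of a synthetic dataset as JSON
#'
#' @param counts Counts from [generate_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(counts, path) {
  gt <- attr(counts, "ground_truth")
  if (is.null(gt)) schema_stop("counts carry no ground_truth attribute")
  gt$corr <- lapply(gt$corr, function(m) as.data.frame(m))
  gt$p_td <- as.data.frame(gt$p_td)
  gt$p_cfos <- as.data.frame(gt$p_cfos)
  gt$ratio <- as.data.frame(gt$ratio)
  jsonlite::write_json(gt, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
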