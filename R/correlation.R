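#' Region-by-region Pearson correlation matrix for one group
#'
#' Builds the symmetric matrix of Pearson correlation coefficients of the
#' double-labeled percentage (reactivation) across animals, between every
#' pair of regions, for one experimental group. With R regions the matrix has
#' R^2 cells and R(R-1)/2 unique unordered pairs. Pairs with fewer than
#' `min_n` animals contributing both values, and pairs involving a region
#' with zero across-animal variance, are set to `NA` with a warning
#' (a fabricated 0 would distort strength averages downstream).
#'
#' @param rows Reactivation table (see [reactivation_table()]).
#' @param group Group label to subset on.
#' @param regions Ordered region labels; defaults to the regions present in
#'   the attached metadata, else those present in `rows`.
#' @param value Column correlated across animals (default `"double_pct"`).
#' @param min_n Minimum number of complete animal pairs per region pair
#'   (default 3).
#' @return An object of class `coreact_corr`: list with `group`, `regions`,
#'   `r` (R x R matrix, diagonal `NA`), `n_animals`, and the region metadata.
#' @export
correlation_matrix <- function(rows, group, regions = NULL,
                               value = "double_pct", min_n = 3) {
  metadata <- attr(rows, "region_metadata")
  regions <- regions %||% (if (!is.null(metadata)) metadata$region else
    sort(unique(rows$region)))
  sub <- rows[rows$group == group, , drop = FALSE]
  if (nrow(sub) == 0L) validation_stop("no rows for group '", group, "'")
  animals <- unique(sub$animal_id)
  wide <- matrix(NA_real_, nrow = length(animals), ncol = length(regions),
                 dimnames = list(animals, regions))
  idx <- cbind(match(sub$animal_id, animals), match(sub$region, regions))
  keep <- !is.na(idx[, 2])
  wide[idx[keep, , drop = FALSE]] <- sub[[value]][keep]

  r <- suppressWarnings(stats::cor(wide, use = "pairwise.complete.obs",
                                   method = "pearson"))
  # enforce preconditions pairwise
  obs <- !is.na(wide)
  pair_n <- crossprod(obs)          # animals contributing to each pair
  low_n <- pair_n < min_n
  zero_var <- apply(wide, 2, function(x) {
    x <- x[!is.na(x)]
    length(x) < 2 || isTRUE(sd(x) == 0)
  })
  if (any(zero_var))
    warning("region(s) with zero across-animal variance in group '", group,
            "': ", paste(regions[zero_var], collapse = ", "),
            "; their correlations set to NA", call. = FALSE)
  if (any(low_n[upper.tri(low_n)]))
    warning(sum(low_n[upper.tri(low_n)]), " region pair(s) with fewer than ",
            min_n, " complete animals in group '", group,
            "' set to NA", call. = FALSE)
  r[low_n] <- NA_real_
  r[zero_var, ] <- NA_real_
  r[, zero_var] <- NA_real_
  diag(r) <- NA_real_

  structure(list(group = group, regions = regions, r = r,
                 n_animals = length(animals), metadata = metadata),
            class = "coreact_corr")
}

#' @export
print.coreact_corr <- function(x, ...) {
  cat("Co-reactivation correlation matrix - group '", x$group, "'\n", sep = "")
  cat(length(x$regions), "regions,", length(x$regions)^2, "matrix cells,",
      choose(length(x$regions), 2), "unique pairs,",
      x$n_animals, "animals\n")
  invisible(x)
}

#' Mean inter-anatomical-group connectivity
#'
#' Mean Pearson coefficient over all region pairs crossing from one
#' anatomical-group selector to another (or, with `groups_b = NULL`, from one
#' selector to all other regions). Within-set pairs and missing coefficients
#' are excluded.
#'
#' @param m A `coreact_corr` object.
#' @param groups_a Character vector of anatomical groups (or region names)
#'   selecting the first region set.
#' @param groups_b Second selector, or `NULL` for all regions outside
#'   `groups_a`.
#' @param metadata Region metadata; defaults to the metadata stored in `m`.
#' @return Mean correlation coefficient (scalar).
#' @export
mean_group_connectivity <- function(m, groups_a, groups_b = NULL,
                                    metadata = NULL) {
  metadata <- metadata %||% m$metadata
  if (is.null(metadata))
    schema_stop("no region metadata available for anatomical selectors")
  resolve <- function(sel) {
    hit <- metadata$region[metadata$anatomical_group %in% sel]
    hit <- union(hit, intersect(sel, metadata$region))
    intersect(m$regions, hit)
  }
  set_a <- resolve(groups_a)
  if (length(set_a) == 0L) validation_stop("selector 'groups_a' matches no region")
  set_b <- if (is.null(groups_b)) setdiff(m$regions, set_a) else resolve(groups_b)
  if (length(set_b) == 0L) validation_stop("selector 'groups_b' matches no region")
  if (length(intersect(set_a, set_b)))
    validation_stop("selectors overlap: ",
                    paste(intersect(set_a, set_b), collapse = ", "))
  vals <- m$r[set_a, set_b, drop = FALSE]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) validation_stop("no non-missing cross-set pairs")
  mean(vals)
}

#' Write a correlation matrix as CSV
#'
#' Region x region comma-separated matrix with a header row and a leading
#' region column.
#'
#' @param m A `coreact_corr` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corr_csv <- function(m, path) {
  out <- data.frame(region = m$regions, m$r, check.names = FALSE)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
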