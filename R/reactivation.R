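#' Labeling fractions as percentages of DAPI+ cells
#'
#' Standardises raw counts by the total cell count: `td_pct = 100*n_td/n_dapi`,
#' `cfos_pct = 100*n_cfos/n_dapi`, `double_pct = 100*n_double/n_dapi`.
#'
#' @param counts Validated counts data.frame (see [read_counts()]).
#' @return `counts` with columns `td_pct`, `cfos_pct`, `double_pct` appended.
#' @export
label_fractions <- function(counts) {
  if (any(counts$n_dapi == 0)) {
    i <- which(counts$n_dapi == 0)[1]
    validation_stop("row ", i, " (animal '", counts$animal_id[i],
                    "', region '", counts$region[i],
                    "'): n_dapi is zero, fractions undefined")
  }
  counts$td_pct <- 100 * counts$n_td / counts$n_dapi
  counts$cfos_pct <- 100 * counts$n_cfos / counts$n_dapi
  counts$double_pct <- 100 * counts$n_double / counts$n_dapi
  counts
}

#' Chance-level double labeling under independence
#'
#' The expected percentage of double-labeled cells if learning-tag and
#' retrieval-marker labeling were independent:
#' `(td_pct/100) * (cfos_pct/100) * 100`.
#'
#' @param td_pct,cfos_pct Labeling percentages in \[0, 100\].
#' @return Chance-level double-labeling percentage.
#' @examples
#' chance_overlap_pct(5, 10) # 0.5
#' @export
chance_overlap_pct <- function(td_pct, cfos_pct) {
  if (any(td_pct < 0 | td_pct > 100) || any(cfos_pct < 0 | cfos_pct > 100))
    validation_stop("labeling percentages must lie in [0, 100]")
  (td_pct / 100) * (cfos_pct / 100) * 100
}

#' Observed-over-chance reactivation ratio
#'
#' `double_pct / chance_pct`. A ratio of 1 means reactivation at chance level;
#' above 1, preferential reactivation of the learning-tagged ensemble.
#' `chance_pct == 0` with `double_pct == 0` is undefined and returned as `NA`
#' with a warning (0/0); `chance_pct == 0` with `double_pct > 0` is impossible
#' for consistent counts and raises an error.
#'
#' @param double_pct Observed double-labeled percentage.
#' @param chance_pct Chance-level percentage from [chance_overlap_pct()].
#' @return Dimensionless ratio (vectorised), `NA` where undefined.
#' @export
reactivation_ratio <- function(double_pct, chance_pct) {
  if (any(chance_pct < 0)) validation_stop("chance_pct must be >= 0")
  impossible <- chance_pct == 0 & double_pct > 0
  if (any(impossible))
    validation_stop("double_pct > 0 with chance_pct = 0: inconsistent input")
  undefined <- chance_pct == 0 & double_pct == 0
  out <- ifelse(undefined, NA_real_, double_pct / chance_pct)
  if (any(undefined))
    warning(sum(undefined), " ratio(s) undefined (chance level 0); ",
            "returned as NA and excluded from summaries", call. = FALSE)
  out
}

#' Full reactivation table from raw counts
#'
#' Convenience wrapper chaining [label_fractions()], [chance_overlap_pct()]
#' and [reactivation_ratio()] to produce one row per animal x region with
#' fractions, chance level, and observed/chance reactivation ratio.
#'
#' @param counts Validated counts data.frame.
#' @return Data.frame with columns `animal_id, group, region, td_pct,
#'   cfos_pct, double_pct, chance_pct, ratio`.
#' @export
reactivation_table <- function(counts) {
  rows <- label_fractions(counts)
  rows$chance_pct <- chance_overlap_pct(rows$td_pct, rows$cfos_pct)
  rows$ratio <- reactivation_ratio(rows$double_pct, rows$chance_pct)
  attr(rows, "region_metadata") <- attr(counts, "region_metadata")
  rows
}

#' Group x region summary of reactivation values
#'
#' Mean, standard error and n of a reactivation column per group x region.
#' Missing values (undefined ratios) are excluded, with a message reporting
#' how many were dropped.
#'
#' @param rows Reactivation table from [reactivation_table()].
#' @param value Column to summarise (default `"ratio"`).
#' @return Data.frame with `group, region, mean, se, n`.
#' @export
reactivation_summary <- function(rows, value = "ratio") {
  if (!value %in% names(rows)) schema_stop("no column '", value, "' in rows")
  x <- rows[[value]]
  n_missing <- sum(is.na(x))
  if (n_missing > 0)
    message(n_missing, " missing ", value, " value(s) excluded from summary")
  keep <- !is.na(x)
  sub <- rows[keep, ]
  key <- interaction(sub$group, sub$region, drop = TRUE)
  out <- do.call(rbind, lapply(split(seq_len(nrow(sub)), key), function(idx) {
    v <- sub[[value]][idx]
    data.frame(group = sub$group[idx[1]], region = sub$region[idx[1]],
               mean = mean(v), se = sd(v) / sqrt(length(v)), n = length(v),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg step-up adjustment of a p-value family
#'
#' Each raw p-value is multiplied by the total number of tests in the family
#' and divided by its ascending rank; the step-up monotonicity correction
#' (running minimum from the largest rank down) is then applied and values are
#' capped at 1. Both the raw product and the monotone adjusted value are
#' returned, since the raw product alone can be non-monotone in the raw
#' p-values. One family should pool all tests of an analysis run so that the
#' false-discovery rate is controlled globally.
#'
#' @param raw_p Numeric vector of p-values in \[0, 1\].
#' @param labels Optional labels for the tests (default positional).
#' @return Data.frame with columns `label, raw_p, rank, m, raw_product,
#'   adj_p`, in the input order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.04))$adj_p # 0.03 0.03 0.04
#' @export
bh_adjust <- function(raw_p, labels = NULL) {
  if (length(raw_p) == 0L) validation_stop("empty p-value family")
  if (any(!is.finite(raw_p) | raw_p < 0 | raw_p > 1))
    validation_stop("p-value outside [0, 1] at position ",
                    which(!is.finite(raw_p) | raw_p < 0 | raw_p > 1)[1])
  m <- length(raw_p)
  labels <- labels %||% as.character(seq_len(m))
  ord <- order(raw_p)
  rank_asc <- integer(m)
  rank_asc[ord] <- seq_len(m)
  raw_product <- raw_p * m / rank_asc
  sorted_prod <- raw_product[ord]
  adj_sorted <- pmin(1, rev(cummin(rev(sorted_prod))))
  adj_p <- numeric(m)
  adj_p[ord] <- adj_sorted
  data.frame(label = labels, raw_p = raw_p, rank = rank_asc, m = m,
             raw_product = pmin(1, raw_product), adj_p = adj_p,
             stringsAsFactors = FALSE)
}
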