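#' Read a region metadata table
#'
#' Region metadata assigns every region of the counting panel to one
#' anatomical group. The file is comma-separated text with a header
#' `region,anatomical_group`.
#'
#' @param path Path to the CSV file.
#' @return Data.frame with columns `region`, `anatomical_group`.
#' @seealso [default_region_metadata()] for the built-in 15-region panel.
#' @export
read_region_metadata <- function(path) {
  if (!file.exists(path)) schema_stop("region metadata file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_region_metadata(df)
}

#' @rdname read_region_metadata
#' @param metadata A data.frame to validate in place of a file.
#' @export
validate_region_metadata <- function(metadata) {
  required <- c("region", "anatomical_group")
  missing <- setdiff(required, names(metadata))
  if (length(missing))
    schema_stop("region metadata is missing column(s): ",
                paste(missing, collapse = ", "))
  if (anyDuplicated(metadata$region))
    validation_stop("duplicated region(s) in metadata: ",
                    paste(unique(metadata$region[duplicated(metadata$region)]),
                          collapse = ", "))
  if (nrow(metadata) == 0L) validation_stop("region metadata is empty")
  metadata[, required]
}

COUNT_COLUMNS <- c("animal_id", "group", "region",
                   "n_dapi", "n_td", "n_cfos", "n_double")

#' Read and validate a tagged-cell count table
#'
#' Reads per-animal, per-region counts of DAPI+ cells, learning-tagged (Td+)
#' cells, retrieval-active (c-Fos+) cells, and double-labeled cells from a CSV
#' file with header `animal_id,group,region,n_dapi,n_td,n_cfos,n_double`.
#' An optional `sex` column is accepted and carried along but ignored by all
#' analyses. Rows are expected per animal x region (counts already summed over
#' bilateral images); if several rows share an animal x region key they are
#' treated as per-image counts and summed, with a warning, since the
#' across-animal correlation analyses operate on one value per animal.
#'
#' Validated invariants, each reported with the offending row and field:
#' all counts non-negative integers; `n_td <= n_dapi`; `n_cfos <= n_dapi`;
#' `n_double <= min(n_td, n_cfos)`; every region present in the metadata.
#'
#' @param path Path to the counts CSV.
#' @param metadata Region metadata data.frame (see [read_region_metadata()]);
#'   defaults to the built-in 15-region panel.
#' @return A data.frame of validated counts with the metadata attached as
#'   attribute `"region_metadata"`.
#' @export
read_counts <- function(path, metadata = default_region_metadata()) {
  if (!file.exists(path)) schema_stop("counts file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_counts(df, metadata)
}

#' @rdname read_counts
#' @param counts A data.frame of counts to validate directly.
#' @export
validate_counts <- function(counts, metadata = default_region_metadata()) {
  metadata <- validate_region_metadata(metadata)
  missing <- setdiff(COUNT_COLUMNS, names(counts))
  if (length(missing))
    schema_stop("counts table is missing column(s): ",
                paste(missing, collapse = ", "))
  counts <- counts[, c(COUNT_COLUMNS, intersect("sex", names(counts)))]

  bad_region <- !(counts$region %in% metadata$region)
  if (any(bad_region))
    validation_stop("row ", which(bad_region)[1], ": region '",
                    counts$region[which(bad_region)[1]],
                    "' absent from region metadata")

  for (col in c("n_dapi", "n_td", "n_cfos", "n_double")) {
    x <- counts[[col]]
    if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x != floor(x))) {
      i <- which(!is.finite(x) | x < 0 | x != floor(x))[1]
      validation_stop("row ", i, ", field '", col,
                      "': counts must be non-negative integers")
    }
  }

  key <- paste(counts$animal_id, counts$region, sep = "\r")
  if (anyDuplicated(key)) {
    warning("per-image rows detected (duplicate animal x region keys); ",
            "summing counts to one row per animal x region", call. = FALSE)
    grp <- counts$group[!duplicated(key)]
    sx <- if ("sex" %in% names(counts)) counts$sex[!duplicated(key)] else NULL
    agg <- stats::aggregate(
      counts[c("n_dapi", "n_td", "n_cfos", "n_double")],
      by = list(key = key), FUN = sum)
    ord <- match(unique(key), agg$key)
    first <- !duplicated(key)
    counts <- data.frame(
      animal_id = counts$animal_id[first],
      group = grp,
      region = counts$region[first],
      agg[ord, c("n_dapi", "n_td", "n_cfos", "n_double")],
      stringsAsFactors = FALSE)
    if (!is.null(sx)) counts$sex <- sx
    rownames(counts) <- NULL
  }

  check <- function(cond, col) {
    if (any(cond)) {
      i <- which(cond)[1]
      validation_stop("row ", i, " (animal '", counts$animal_id[i],
                      "', region '", counts$region[i], "'), field '", col,
                      "': ", col, " exceeds its bounding count")
    }
  }
  check(counts$n_td > counts$n_dapi, "n_td")
  check(counts$n_cfos > counts$n_dapi, "n_cfos")
  check(counts$n_double > pmin(counts$n_td, counts$n_cfos), "n_double")

  attr(counts, "region_metadata") <- metadata
  counts
}

#' Write a validated count table back to CSV
#'
#' Inverse of [read_counts()]; writing then re-reading a valid table
#' round-trips identically.
#'
#' @param counts Validated counts data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  write.csv(counts[, intersect(c(COUNT_COLUMNS, "sex"), names(counts))],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a behavioral freezing table
#'
#' Comma-separated text with header
#' `animal_id,freezing_threat_s,freezing_neutral_s[,freezing_on_s,freezing_off_s]`.
#' All freezing values are seconds and must be non-negative; when
#' `session_length_s` is given, no value may exceed it.
#'
#' @param path Path to the behavior CSV.
#' @param session_length_s Optional session length bound in seconds.
#' @return Data.frame of behavior records.
#' @export
read_behavior <- function(path, session_length_s = NULL) {
  if (!file.exists(path)) schema_stop("behavior file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("animal_id", "freezing_threat_s", "freezing_neutral_s")
  missing <- setdiff(required, names(df))
  if (length(missing))
    schema_stop("behavior table is missing column(s): ",
                paste(missing, collapse = ", "))
  num_cols <- intersect(c("freezing_threat_s", "freezing_neutral_s",
                          "freezing_on_s", "freezing_off_s"), names(df))
  for (col in num_cols) {
    if (any(!is.finite(df[[col]]) | df[[col]] < 0))
      validation_stop("row ", which(!is.finite(df[[col]]) | df[[col]] < 0)[1],
                      ", field '", col, "': freezing seconds must be >= 0")
    if (!is.null(session_length_s) && any(df[[col]] > session_length_s))
      validation_stop("row ", which(df[[col]] > session_length_s)[1],
                      ", field '", col, "': freezing exceeds session length")
  }
  df
}

#' Contextual discrimination index
#'
#' The difference between freezing time in the threatening and the neutral
#' context divided by their sum: `(threat - neutral) / (threat + neutral)`.
#' Ranges over \[-1, 1\]; 0 means no discrimination, 1 exclusive freezing in
#' the threatening context. Vectorised; antisymmetric under swapping its
#' arguments.
#'
#' @param freezing_threat_s Freezing seconds in the threatening context (>= 0).
#' @param freezing_neutral_s Freezing seconds in the neutral context (>= 0).
#' @return Numeric vector of indices in \[-1, 1\].
#' @examples
#' discrimination_index(60, 20) # 0.5
#' @export
discrimination_index <- function(freezing_threat_s, freezing_neutral_s) {
  if (any(freezing_threat_s < 0) || any(freezing_neutral_s < 0))
    validation_stop("freezing times must be non-negative")
  total <- freezing_threat_s + freezing_neutral_s
  if (any(total == 0))
    validation_stop("discrimination index undefined: both freezing times are ",
                    "zero (division by zero, not silently 0)")
  (freezing_threat_s - freezing_neutral_s) / total
}

#' Light ON minus OFF freezing difference
#'
#' Signed difference in seconds between freezing during the optogenetic light
#' ON period and the light OFF baseline.
#'
#' @param freezing_on_s Freezing seconds during light ON (>= 0).
#' @param freezing_off_s Freezing seconds during light OFF (>= 0).
#' @return `freezing_on_s - freezing_off_s`, in seconds.
#' @export
freezing_on_off_difference <- function(freezing_on_s, freezing_off_s) {
  if (any(freezing_on_s < 0) || any(freezing_off_s < 0))
    validation_stop("freezing times must be non-negative")
  freezing_on_s - freezing_off_s
}
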