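# Programmatic fixtures: everything is built in code at test time.

tiny_metadata <- function() {
  data.frame(region = c("r1", "r2", "r3", "r4"),
             anatomical_group = c("amygdala", "amygdala", "PH", "mPFC"),
             stringsAsFactors = FALSE)
}

tiny_counts <- function() {
  data.frame(
    animal_id = rep(c("a1", "a2", "a3"), each = 4),
    group = rep("G1", 12),
    region = rep(c("r1", "r2", "r3", "r4"), 3),
    n_dapi = rep(200L, 12),
    n_td = c(10L, 20L, 30L, 12L, 14L, 22L, 28L, 10L, 12L, 18L, 26L, 16L),
    n_cfos = c(20L, 25L, 15L, 8L, 18L, 27L, 13L, 12L, 22L, 23L, 17L, 10L),
    n_double = c(2L, 4L, 3L, 1L, 3L, 5L, 2L, 2L, 2L, 3L, 4L, 1L),
    stringsAsFactors = FALSE)
}

# Reactivation-row table directly from an animals x regions value matrix,
# bypassing count generation, for correlation/permutation tests that only
# need double_pct.
rows_from_matrix <- function(values, group, metadata = NULL,
                             animal_prefix = group) {
  regions <- colnames(values)
  df <- data.frame(
    animal_id = rep(sprintf("%s_%02d", animal_prefix, seq_len(nrow(values))),
                    times = ncol(values)),
    group = group,
    region = rep(regions, each = nrow(values)),
    double_pct = as.vector(values),
    stringsAsFactors = FALSE)
  attr(df, "region_metadata") <- metadata
  df
}

stack_rows <- function(...) {
  parts <- list(...)
  out <- do.call(rbind, parts)
  attr(out, "region_metadata") <- attr(parts[[1]], "region_metadata")
  out
}

# Bivariate normal sample with correlation rho (via Cholesky), for
# permutation-calibration fixtures.
bivariate_sample <- function(n, rho) {
  z1 <- rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  cbind(z1, z2)
}

write_temp_csv <- function(df, dir = tempdir(), name = "tmp.csv") {
  path <- file.path(dir, name)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
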