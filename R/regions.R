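#' Default 15-region panel with anatomical grouping
#'
#' The default region metadata used throughout the package: three medial
#' prefrontal regions (AC, PL, IL), five amygdala nuclei (BLA, BMA, CEA, LA,
#' MEA), four hippocampal subfields (dCA1, dDG, vCA1, vDG), and three
#' parahippocampal-area regions (vSUB, PER_35, PER_36). Any other panel can be
#' supplied as a `region,anatomical_group` table via [read_region_metadata()];
#' nothing downstream assumes 15 regions.
#'
#' @return A data.frame with columns `region` and `anatomical_group`.
#' @examples
#' default_region_metadata()
#' @export
default_region_metadata <- function() {
  data.frame(
    region = c("AC", "PL", "IL",
               "BLA", "BMA", "CEA", "LA", "MEA",
               "dCA1", "dDG", "vCA1", "vDG",
               "vSUB", "PER_35", "PER_36"),
    anatomical_group = c(rep("mPFC", 3), rep("amygdala", 5),
                         rep("hippocampus", 4), rep("PH", 3)),
    stringsAsFactors = FALSE
  )
}

ANATOMICAL_GROUPS <- c("mPFC", "amygdala", "hippocampus", "PH")

# Published group-mean labeling percentages (% of DAPI+ cells) used by the
# study-like simulation preset to place marginal rates on a realistic scale:
# learning-tag (Td+) fractions after training and retrieval-marker (c-Fos+)
# fractions after test, per region, for the CFC, CFC-5s and homecage groups.
study_marginal_rates <- function() {
  regions <- default_region_metadata()$region
  td <- cbind(
    CFC       = c(7.168, 7.414, 4.814, 10.057, 9.116, 15.869, 5.061, 12.523,
                  1.237, 5.850, 2.408, 1.902, 3.825, 8.329, 7.774),
    `CFC-5s`  = c(7.026, 5.899, 4.977, 7.711, 9.127, 11.372, 3.665, 10.806,
                  1.162, 5.204, 1.935, 2.376, 4.566, 7.661, 5.576),
    HC        = c(4.147, 3.022, 2.581, 1.475, 2.850, 2.540, 1.272, 2.803,
                  0.572, 2.975, 0.498, 0.532, 0.200, 1.598, 2.947)
  )
  cfos <- cbind(
    CFC       = c(2.000, 3.738, 2.570, 3.769, 4.077, 2.356, 2.460, 4.743,
                  0.431, 2.743, 1.553, 1.338, 3.467, 4.756, 5.192),
    `CFC-5s`  = c(1.725, 2.689, 2.329, 2.385, 3.330, 2.201, 1.510, 4.611,
                  0.672, 3.005, 1.323, 1.318, 3.548, 3.215, 3.075),
    HC        = c(0.723, 1.015, 1.206, 0.793, 1.457, 0.558, 0.582, 0.697,
                  0.205, 1.582, 0.187, 0.022, 0.073, 0.910, 1.438)
  )
  rownames(td) <- rownames(cfos) <- regions
  list(td_pct = td, cfos_pct = cfos)
}
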