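#' Parameters for the synthetic neuropathology-cognition cohort
#'
#' Bundles every knob of the cohort generator.  Defaults emulate the study
#' conditions the pipeline is designed for: 128 older adults (age
#' 90.53 +/- 6.06 years), 8-12 reconstructed neurons per case with one
#' dendritic segment of at least 20 um each, roughly 5 spines per 10 um of
#' dendrite across the four morphological classes, a male deficit in
#' amyloid/tangle pathology, an episodic-memory composite generated linearly
#' from pathology, sex and (region-specifically) mean spine head diameter,
#' and 3 cases with missing pathology and/or memory scores.
#'
#' @param n_cases number of cases in the cohort.
#' @param neurons_per_case integer range (min, max); neuron counts are drawn
#'   uniformly on this range.
#' @param segment_length segment length range in um (min, max), uniform.
#' @param class_mix named probability 4-vector over thin, stubby, mushroom,
#'   filopodia; must sum to 1.
#' @param spines_per_10um expected spine density (per 10 um of dendrite).
#' @param regions character vector of region labels to simulate.
#' @param beta_hd named vector, one entry per region: episodic-memory units
#'   per um of that region's case-mean head diameter.  The temporal-cortex
#'   style region ("BA37") carries a positive effect by default; the
#'   premotor-style region ("BA6") carries none.
#' @param beta_np,beta_nft memory units per pathology unit (neuritic plaque
#'   score, tangle burden); negative by default.
#' @param beta_sex memory units added for males (sex coded 0 = female,
#'   1 = male).
#' @param sex_pathology_shift pathology units added to male NP and NFT means
#'   (negative: males carry less pathology).
#' @param noise_sd residual SD of the episodic-memory composite.
#' @param n_missing number of cases given at least one missing pathology or
#'   memory value (missing at random over NP, NFT, episodic memory).
#' @param p_male probability a case is male.
#' @param age_mean,age_sd cohort age distribution (years).
#' @param np_mean,np_sd,nft_mean,nft_sd female-referenced pathology score
#'   distributions (truncated at 0).
#' @param hd_case_sdlog,len_case_sdlog,dens_case_sdlog SDs (log scale) of
#'   the per-case lognormal factors scaling head diameter, spine length and
#'   spine density; these create the between-case trait variation the models
#'   must detect.
#' @param vol_case_sdlog SD (log scale) of a per-case lognormal factor on
#'   apparent spine volume, emulating case-to-case variation in staining
#'   depth and axial smear: bright-field volume is the least reliable of
#'   the four measurements and varies systematically per preparation.
#' @param volume_noise_sdlog per-spine lognormal noise on the volume model
#'   (tracing/voxelization error).
#' @param voxel_dims voxel edge lengths in um (x, y, z).
#' @param class_geometry per-class measurement distributions; see
#'   \code{\link{class_geometry_defaults}}.
#' @param seed integer seed; the whole cohort is a deterministic function of
#'   the parameter set.
#' @return A validated list of class \code{"cohort_params"}.
#' @export
cohort_params <- function(n_cases = 128,
                          neurons_per_case = c(8, 12),
                          segment_length = c(20, 40),
                          class_mix = c(thin = 0.45, stubby = 0.30,
                                        mushroom = 0.20, filopodia = 0.05),
                          spines_per_10um = 5,
                          regions = c("BA37", "BA6"),
                          beta_hd = c(BA37 = 8, BA6 = 0),
                          beta_np = -0.35,
                          beta_nft = -0.30,
                          beta_sex = -0.15,
                          sex_pathology_shift = -0.35,
                          noise_sd = 0.35,
                          n_missing = 3,
                          p_male = 0.35,
                          age_mean = 90.53,
                          age_sd = 6.06,
                          np_mean = 1.2, np_sd = 0.55,
                          nft_mean = 1.3, nft_sd = 0.60,
                          hd_case_sdlog = 0.10,
                          len_case_sdlog = 0.12,
                          dens_case_sdlog = 0.15,
                          vol_case_sdlog = 0.20,
                          volume_noise_sdlog = 0.15,
                          voxel_dims = c(0.05, 0.05, 0.10),
                          class_geometry = class_geometry_defaults(),
                          seed = 1) {
  p <- as.list(environment())
  if (p$n_cases < 1) stop("n_cases must be >= 1")
  if (length(p$class_mix) != 4 ||
      !setequal(names(p$class_mix), spine_classes()))
    stop("class_mix must be a named 4-vector over ",
         paste(spine_classes(), collapse = ", "))
  if (any(p$class_mix < 0) || abs(sum(p$class_mix) - 1) > 1e-8)
    stop("class_mix must be a probability vector summing to 1")
  p$class_mix <- p$class_mix[spine_classes()]
  for (nm in c("neurons_per_case", "segment_length")) {
    r <- p[[nm]]
    if (length(r) != 2 || any(r <= 0) || r[1] > r[2])
      stop(nm, " must be a positive (min, max) range")
  }
  if (p$spines_per_10um <= 0) stop("spines_per_10um must be positive")
  if (p$noise_sd < 0) stop("noise_sd must be non-negative")
  if (p$n_missing < 0 || p$n_missing >= p$n_cases)
    stop("n_missing must be in [0, n_cases)")
  if (length(p$voxel_dims) != 3 || any(p$voxel_dims <= 0))
    stop("voxel_dims must be 3 positive edge lengths")
  if (is.null(names(p$beta_hd)) || !all(p$regions %in% names(p$beta_hd)))
    stop("beta_hd must be named with an entry for every region")
  p$beta_hd <- p$beta_hd[p$regions]
  class(p) <- "cohort_params"
  p
}

#' Default per-class spine measurement distributions
#'
#' Head diameter and length are lognormal per class; the head-to-neck ratio
#' is uniform on a class-specific band at or above 1 (necks never exceed
#' heads, so constructed geometry reproduces the drawn measures exactly).
#' Values are invented study-shaped defaults — the classification thresholds
#' constrain the classes, not their distributions — and every draw is
#' rejection-sampled until the measured spine classifies as requested.
#'
#' @return Named list (one element per class) of lists with
#'   \code{head_meanlog}, \code{head_sdlog}, \code{hnr_range},
#'   \code{len_meanlog}, \code{len_sdlog}.
#' @export
class_geometry_defaults <- function() {
  list(
    thin = list(head_meanlog = log(0.22), head_sdlog = 0.18,
                hnr_range = c(1.00, 1.08),
                len_meanlog = log(1.40), len_sdlog = 0.35),
    stubby = list(head_meanlog = log(0.48), head_sdlog = 0.15,
                  hnr_range = c(1.00, 1.08),
                  len_meanlog = log(0.70), len_sdlog = 0.25),
    mushroom = list(head_meanlog = log(0.55), head_sdlog = 0.18,
                    hnr_range = c(1.15, 1.80),
                    len_meanlog = log(1.10), len_sdlog = 0.30),
    filopodia = list(head_meanlog = log(0.20), head_sdlog = 0.15,
                     hnr_range = c(1.00, 1.08),
                     len_meanlog = log(3.80), len_sdlog = 0.20)
  )
}
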