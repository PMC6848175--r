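#' Published per-edge streamline-count parameters by group
#'
#' Group means and standard deviations of the number of streamlines (NOS) on
#' the ten subcortical connections reported as significantly reduced in
#' multiple system atrophy, for healthy controls (HC), Parkinson's disease
#' (PD) and multiple system atrophy (MSA). Values are in streamlines (the
#' published table prints them on a 1e6 scale; here they are stored in raw
#' streamline units).
#'
#' These parameters drive [simulate_nos_cohort()]: the ten listed edges get
#' group-specific normals, every other edge a shared, group-invariant null
#' parameterization.
#'
#' @param scale multiplier applied to the stored 1e6-scale values
#'   (default `1e6`, i.e. raw streamline units).
#' @return data.frame with columns `roi_a`, `roi_b`, `edge` (flat position)
#'   and `mean_HC`, `sd_HC`, `mean_PD`, `sd_PD`, `mean_MSA`, `sd_MSA`.
#' @export
nos_group_params <- function(scale = 1e6) {
  p <- data.frame(
    roi_a = c("Left-Pallidum", "Left-Hippocampus", "Left-Pallidum",
              "Left-VentralDC", "Right-Pallidum", "Right-Putamen",
              "Right-Thalamus", "Left-VentralDC",
              "Left-Cerebellum-White-Matter", "Right-VentralDC"),
    roi_b = c("Left-Putamen", "Left-Thalamus", "Left-VentralDC",
              "Left-Cerebellum-White-Matter", "Right-Putamen",
              "Right-Thalamus", "Right-VentralDC",
              "Right-Cerebellum-White-Matter",
              "Right-Cerebellum-White-Matter",
              "Right-Cerebellum-White-Matter"),
    mean_HC  = c(1.4874, 1.0230, 1.1713, 0.7598, 1.3556, 0.7936, 2.7867,
                 0.0918, 4.4335, 0.8462),
    sd_HC    = c(0.2522, 0.2549, 0.4372, 0.2172, 0.2265, 0.2888, 0.4611,
                 0.0623, 1.4225, 0.2694),
    mean_PD  = c(1.5197, 0.9295, 1.2162, 0.8399, 1.4148, 0.6769, 2.8886,
                 0.0834, 4.1623, 0.9045),
    sd_PD    = c(0.2627, 0.2975, 0.4139, 0.2092, 0.2195, 0.2435, 0.4822,
                 0.0503, 1.2313, 0.2629),
    mean_MSA = c(1.2184, 0.7847, 0.8819, 0.5747, 1.1536, 0.5442, 2.4535,
                 0.0471, 2.3522, 0.5694),
    sd_MSA   = c(0.2599, 0.2147, 0.3154, 0.2734, 0.3044, 0.3885, 0.5392,
                 0.0426, 1.0320, 0.2649),
    stringsAsFactors = FALSE
  )
  num <- grep("^(mean|sd)_", names(p))
  p[num] <- lapply(p[num], function(x) x * scale)
  p$edge <- edge_position(p$roi_a, p$roi_b)
  p[c("roi_a", "roi_b", "edge", names(p)[num])]
}

#' Published per-ROI diffusion-feature parameters by group
#'
#' Group means and standard deviations of mean fractional anisotropy (FA,
#' unitless) and mean diffusivity (MD, mm^2/s) for the subcortical ROIs with
#' reported significant group effects. Drives [simulate_feature_tables()];
#' ROIs without published rows receive a shared, group-invariant default.
#'
#' @return data.frame with columns `measure` (`"FA"` or `"MD"`), `roi` and
#'   `mean_HC`, `sd_HC`, `mean_PD`, `sd_PD`, `mean_MSA`, `sd_MSA`.
#' @export
feature_group_params <- function() {
  fa <- data.frame(
    measure = "FA",
    roi = c("Left-Amygdala", "Left-VentralDC", "Right-Thalamus",
            "Right-VentralDC", "Right-Cerebellum-White-Matter"),
    mean_HC  = c(0.2585, 0.4327, 0.4218, 0.4731, 0.3351),
    sd_HC    = c(0.019, 0.024, 0.024, 0.033, 0.026),
    mean_PD  = c(0.2535, 0.4279, 0.4155, 0.4766, 0.3357),
    sd_PD    = c(0.020, 0.029, 0.025, 0.037, 0.020),
    mean_MSA = c(0.2689, 0.4116, 0.3997, 0.4462, 0.2884),
    sd_MSA   = c(0.029, 0.027, 0.026, 0.030, 0.041),
    stringsAsFactors = FALSE
  )
  md <- data.frame(
    measure = "MD",
    roi = c("Left-Accumbens-area", "Left-Putamen", "Left-VentralDC",
            "Right-Pallidum", "Right-Thalamus",
            "Right-Cerebellum-White-Matter"),
    mean_HC  = c(8.755e-4, 7.739e-4, 1.206e-3, 7.725e-4, 1.248e-3, 9.187e-4),
    sd_HC    = c(5.5e-5, 4.5e-5, 9.9e-5, 4.3e-5, 1.0e-4, 7.5e-5),
    mean_PD  = c(9.095e-4, 7.914e-4, 1.232e-3, 7.794e-4, 1.271e-3, 9.162e-4),
    sd_PD    = c(6.7e-5, 4.9e-5, 1.1e-4, 4.5e-5, 1.1e-4, 7.1e-5),
    mean_MSA = c(9.213e-4, 8.161e-4, 1.313e-3, 8.084e-4, 1.350e-3, 1.141e-3),
    sd_MSA   = c(7.7e-5, 7.8e-5, 1.0e-4, 7.9e-5, 1.1e-4, 1.9e-4),
    stringsAsFactors = FALSE
  )
  rbind(fa, md)
}

#' Default cohort composition
#'
#' Sample sizes and male/female splits of the study groups: HC n = 54
#' (26 male / 28 female), PD n = 65 (48/17), MSA n = 31 (19/12).
#'
#' @return Named list with `n_per_group` and `gender_split` (male, female
#'   counts per group).
#' @export
default_cohort_design <- function() {
  list(
    n_per_group = c(HC = 54L, PD = 65L, MSA = 31L),
    gender_split = list(HC = c(male = 26L, female = 28L),
                        PD = c(male = 48L, female = 17L),
                        MSA = c(male = 19L, female = 12L))
  )
}
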