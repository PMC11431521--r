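#' Published clinical characteristics of the lung-cancer study cohort
#'
#' The printed cohort-characteristics table of the clinical study this
#' package models: 85 lung-cancer cases and 28 benign-lung-disease
#' controls recruited among patients under suspicion of lung cancer.
#' These counts parameterize the synthetic cohort generator
#' ([default_sim_params()]) and are the inputs for recomputing the
#' study's cohort statistics (smoking chi-square test, stage-IV
#' proportion, pooled mean age).
#'
#' @return A list with elements:
#' \describe{
#'   \item{n_case, n_control}{group sizes (85, 28).}
#'   \item{age}{per-group mean and SD of age in years.}
#'   \item{sex}{2 x 2 count matrix (female/male x case/control).}
#'   \item{smoking}{4 x 2 count matrix (smoker/ex-smoker/never-smoker/missing
#'     x case/control); the `missing` row is excluded from testing.}
#'   \item{stage_counts}{cases per IASLC stage, `c(I=9, II=6, III=18, IV=52)`.}
#'   \item{cfdna}{cfDNA availability: 81 samples with concentration, 74 of
#'     those with variant calls, 7 with concentration but insufficient
#'     material for variant analysis.}
#' }
#' @export
study_cohort_counts <- function() {
  list(
    n_case = 85L,
    n_control = 28L,
    age = list(case = c(mean = 70.4, sd = 8.5),
               control = c(mean = 67.0, sd = 14.4)),
    sex = matrix(c(45L, 40L, 17L, 11L), nrow = 2,
                 dimnames = list(c("female", "male"), c("case", "control"))),
    smoking = matrix(c(30L, 43L, 12L, 0L, 5L, 12L, 9L, 2L), nrow = 4,
                     dimnames = list(c("smoker", "ex-smoker", "never-smoker", "missing"),
                                     c("case", "control"))),
    stage_counts = c(I = 9L, II = 6L, III = 18L, IV = 52L),
    cfdna = c(n_with_cfdna = 81L, n_with_ngs = 74L, n_insufficient = 7L)
  )
}
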