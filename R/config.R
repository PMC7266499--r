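#' Analysis configuration
#'
#' Central knobs of the pipeline with their defaults: the minimum number of
#' observations for a protein to be retained (20), the significance level
#' (0.05), the SAM fudge factor s0 (0.001, applied to log10 intensities),
#' the number of label permutations for FDR estimation (250; exhaustive
#' enumeration is used automatically when there are fewer distinct label
#' assignments), annotation term size bounds (10-100 members present in the
#' dataset), the cross-validation fold count (6) and the CV precision bound
#' (0.20, the clinically accepted assay-precision limit).
#'
#' @param min_observations,alpha,s0,n_permutations,term_size_min,term_size_max,k_folds,cv_threshold
#'   See description.
#' @param rng_seed Integer seed used by randomized stages.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(min_observations = 20, alpha = 0.05, s0 = 0.001,
                            n_permutations = 250, rng_seed = 0L,
                            term_size_min = 10, term_size_max = 100,
                            k_folds = 6, cv_threshold = 0.20) {
  stopifnot(min_observations >= 1, alpha > 0, s0 >= 0, n_permutations >= 1,
            term_size_min > 0, term_size_max > term_size_min,
            k_folds >= 2, cv_threshold > 0)
  structure(
    list(min_observations = min_observations, alpha = alpha, s0 = s0,
         n_permutations = n_permutations, rng_seed = as.integer(rng_seed),
         term_size_min = term_size_min, term_size_max = term_size_max,
         k_folds = k_folds, cv_threshold = cv_threshold),
    class = "analysis_config"
  )
}
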