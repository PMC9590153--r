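#' Tuning parameters for the haplotyping pipeline
#'
#' Collects every threshold used by the three inference stages.
#'
#' @param min_frac Minimum fraction of individuals (with at least one
#'   non-missing dosage in the block) in which a haplotype must be required
#'   before it enters the inventory (default 0.10).
#' @param relaxed_frac Fraction for the single relaxed final cycle of the
#'   unrelated-material stage (default 0.01).
#' @param relaxed_min_count Minimum number of individuals for the relaxed
#'   cycle (default 2).
#' @param alpha Double-reduction frequency used in the gamete model
#'   (default 0.025).
#' @param epsilon Probability that a dosage score is off by one
#'   (default 0.025).
#' @param p_ratio Candidate parental combinations are retained when their
#'   chi-squared P value is at least `p_ratio` times the best P value
#'   (default 0.001).
#' @param p_min Absolute floor on the chi-squared P value of retained
#'   candidates (default 1e-8).
#' @param max_parent_combs Maximum number of parental haplotype-combination
#'   pairs to score for one family; beyond it the family is demoted to
#'   unrelated material (default 150000).
#' @param impute_p_ratio Imputations in a family are accepted only if the
#'   chi-squared P value including the imputed offspring is at least
#'   `impute_p_ratio` times the P value without them (default 0.1).
#' @param impute_max_frac Imputations are accepted only if fewer than this
#'   fraction of the family is imputed (default 0.5).
#' @param max_iter Hard cap on Stage-1 fixpoint iterations (default 50).
#' @return A list of class `hap_params`.
#' @export
hap_params <- function(min_frac = 0.1, relaxed_frac = 0.01,
                       relaxed_min_count = 2L,
                       alpha = 0.025, epsilon = 0.025,
                       p_ratio = 0.001, p_min = 1e-8,
                       max_parent_combs = 150000,
                       impute_p_ratio = 0.1, impute_max_frac = 0.5,
                       max_iter = 50L) {
  stopifnot(relaxed_frac > 0, relaxed_frac <= min_frac, min_frac <= 1,
            alpha >= 0, alpha < 1, epsilon >= 0, epsilon < 1,
            p_ratio > 0, p_ratio <= 1, p_min > 0,
            max_parent_combs >= 1,
            impute_p_ratio >= 0, impute_p_ratio <= 1,
            impute_max_frac >= 0, impute_max_frac <= 1,
            relaxed_min_count >= 1, max_iter >= 1)
  structure(list(min_frac = min_frac, relaxed_frac = relaxed_frac,
                 relaxed_min_count = as.integer(relaxed_min_count),
                 alpha = alpha, epsilon = epsilon,
                 p_ratio = p_ratio, p_min = p_min,
                 max_parent_combs = max_parent_combs,
                 impute_p_ratio = impute_p_ratio,
                 impute_max_frac = impute_max_frac,
                 max_iter = as.integer(max_iter)),
            class = "hap_params")
}
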