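# shared fixtures: small synthetic cohorts built in code, reference
# parameter columns, and the truth-recovery comparison helpers

ref_full <- function() reference_params("full_cohort")
ref_lmci <- function() reference_params("lmci_ad")

nonzero_names <- function(params) names(params$w)[params$w != 0]

# scalar gauge alignment: the cascade admits s -> -10 + a(s+10), w -> w/a,
# so fitted weights are comparable to generating weights only after an
# optimal common scale (geometric mean of the magnitude ratios over
# weights that are clearly nonzero on both sides)
gauge_aligned_rel_err <- function(w_est, w_true) {
  nz <- names(w_true)[w_true != 0]
  big <- nz[abs(w_true[nz]) > 0.05 & abs(w_est[nz]) > 1e-6]
  a <- if (length(big) >= 3)
    exp(mean(log(abs(w_true[big])) - log(abs(w_est[big])))) else 1
  abs(w_est[nz] * a - w_true[nz]) / abs(w_true[nz])
}

small_cohort <- function(seed, n = 25, noise = 0.03, visits = c(3, 5),
                         miss = 0, truth = ref_lmci(), ...) {
  generate_cohort(generator_config(
    n_subjects = n, noise_sd = noise, miss_prob = miss,
    visit_range = visits, truth = truth, seed = seed, ...))
}

# cohort whose subjects have enough visits for personalization
personalization_cohort <- function(seed, n = 40, noise = 0.05) {
  generate_cohort(generator_config(
    n_subjects = n, noise_sd = noise, miss_prob = 0,
    visit_range = c(5, 6),
    dps_baseline = list(CN = c(-2, 2), LMCI = c(2, 2), AD = c(6, 2)),
    seed = seed))
}
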