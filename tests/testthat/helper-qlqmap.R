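# Shared fixtures, built in code.

# a tiny deterministic covariate tibble (no randomness)
tiny_covariates <- function(n = 6L) {
  scales <- qlq_scales()
  out <- tibble::tibble(
    patient_id = sprintf("P%02d", rep(seq_len(ceiling(n / 2)), each = 2L))[1:n],
    visit_index = rep(1:2, length.out = n),
    age = seq(40, 70, length.out = n)
  )
  for (i in seq_along(scales)) {
    out[[scales[i]]] <- round(seq(10 + 3 * i, 90 - 2 * i,
                                  length.out = n), 1)
  }
  out
}

# small synthetic estimation dataset with utilities from the shipped truth
small_utility_data <- function(n_patients = 60L, seed = 101L,
                               missing_rate = 0) {
  cfg <- synthetic_config(n_patients = n_patients, visits_mean = 3,
                          seed = seed, missing_rate = missing_rate)
  make_synthetic_dataset(cfg)
}

# simulate from an explicit small ALDVMM truth over simple designs
simple_aldvmm_sim <- function(n, truth, seed) {
  set.seed(seed)
  x <- runif(n)
  z <- runif(n)
  X <- cbind(intercept = 1, x = x)
  Z <- cbind(intercept = 1, z = z)
  sim <- simulate_aldvmm(truth, X, Z, n_draws = 1L, seed = seed + 1L)
  list(y = sim$draws[, 1L], X = X, Z = Z)
}
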