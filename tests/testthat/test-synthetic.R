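test_that("generation is a pure function of config and seed", {
  cfg <- synthetic_config(n_patients = 40L, seed = 123L)
  a <- make_synthetic_dataset(cfg)
  b <- make_synthetic_dataset(cfg)
  expect_identical(a$data, b$data)
  cfg2 <- synthetic_config(n_patients = 40L, seed = 124L)
  c <- make_synthetic_dataset(cfg2)
  expect_false(identical(a$data$eq5d, c$data$eq5d))
})

test_that("covariates respect ranges and hit their target moments", {
  cfg <- synthetic_config(n_patients = 620L, seed = 9L, missing_rate = 0)
  cov <- generate_covariates(cfg)
  expect_gt(nrow(cov), 3000)
  for (s in qlq_scales()) {
    expect_true(all(cov[[s]] >= 0 & cov[[s]] <= 100))
  }
  # realised global-health mean within one standard error of target
  tg <- qlq_scale_targets()
  gh_t <- tg[tg$scale == "global_health", ]
  se <- gh_t$sd / sqrt(nrow(cov))
  expect_lt(abs(mean(cov$global_health) - gh_t$mean), 3 * se)
  expect_lt(abs(sd(cov$global_health) - gh_t$sd) / gh_t$sd, 0.05)
  # functional scales correlate positively with global health, symptoms
  # negatively
  expect_gt(cor(cov$global_health, cov$physical_f), 0.15)
  expect_lt(cor(cov$global_health, cov$fatigue), -0.15)
  # age constant within patient
  by_pat <- tapply(cov$age, cov$patient_id, function(a) diff(range(a)))
  expect_true(all(by_pat == 0))
})

test_that("infeasible marginal targets are rejected", {
  tg <- qlq_scale_targets()
  tg$sd[1] <- 90 # cannot hold mean 61.85 with sd 90 on [0, 100]
  cfg <- synthetic_config(n_patients = 10L, seed = 1L, scale_targets = tg)
  expect_error(generate_covariates(cfg), "infeasible")
})

test_that("utility mode reproduces the anchored distribution shape", {
  cfg <- synthetic_config(n_patients = 602L, seed = 2024L,
                          missing_rate = 0)
  s <- make_synthetic_dataset(cfg)
  y <- s$data$eq5d
  expect_true(all(is_feasible_utility(y)))
  n <- length(y)
  # spike at full health near 23%
  expect_lt(abs(mean(y == 1) - 0.23), 3 * sqrt(0.23 * 0.77 / n))
  # pooled mean near 0.715
  expect_lt(abs(mean(y) - 0.715), 3 * 0.263 / sqrt(n))
  # a few percent below zero
  expect_gt(mean(y < 0), 0.005)
  expect_lt(mean(y < 0), 0.06)
})

test_that("response mode yields sparse level-3 mobility and self-care", {
  cfg <- synthetic_config(n_patients = 640L, seed = 77L, missing_rate = 0,
                          mode = "dimension_latent")
  s <- make_synthetic_dataset(cfg)
  n <- nrow(s$data)
  for (dm in eq5d_dimensions()) {
    expect_true(all(s$data[[dm]] %in% 1:3))
  }
  se <- 3 * sqrt(0.01 * 0.99 / n)
  expect_lt(abs(mean(s$data$mobility == 3) - 0.01), se + 0.003)
  expect_lt(abs(mean(s$data$self_care == 3) - 0.01), se + 0.003)
  # utilities are genuine tariff values
  u_all <- feasible_utilities()
  expect_true(all(vapply(s$data$eq5d,
                         function(u) any(abs(u - u_all) < 1e-9),
                         logical(1))))
})

test_that("missingness injection hits its rate and nothing else", {
  cfg <- synthetic_config(n_patients = 602L, seed = 5L, missing_rate = 0)
  s <- make_synthetic_dataset(cfg)
  expect_identical(inject_missingness(s$data, 0, seed = 1), s$data)
  rate <- 0.042
  injected <- inject_missingness(s$data, rate, seed = 2)
  fc <- filter_complete_cases(injected)
  n <- nrow(s$data)
  se <- sqrt(rate * (1 - rate) / n)
  expect_lt(abs(fc$report$n_dropped / n - rate), 3 * se)
  # retained rows are untouched
  kept_idx <- which(stats::complete.cases(
    injected[, c("age", qlq_scales(), "eq5d")]))
  expect_identical(fc$data, s$data[kept_idx, ])
})
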