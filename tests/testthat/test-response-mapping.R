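# a hand-built response_fit with known coefficients, for contract tests
manual_response_fit <- function(beta_list, kappa_mat, corr = diag(5)) {
  dims <- eq5d_dimensions()
  x_cols <- c(qlq_scales(), "age", "age_sq")
  fits <- lapply(dims, function(dm) {
    b <- stats::setNames(numeric(length(x_cols)), x_cols)
    if (!is.null(beta_list[[dm]])) b[names(beta_list[[dm]])] <- beta_list[[dm]]
    list(beta = b, kappa = stats::setNames(kappa_mat[dm, ],
                                           c("kappa1", "kappa2")),
         vcov = NULL, loglik = NA_real_, pinned = NA_character_)
  })
  names(fits) <- dims
  dimnames(corr) <- list(dims, dims)
  structure(list(dimensions = fits, correlation = corr, x_cols = x_cols,
                 n_obs = 0L, n_clusters = 0L, method = "response"),
            class = "response_fit")
}

test_that("zero coefficients with tercile cutpoints give equal level shares", {
  kap <- matrix(rep(c(qnorm(1 / 3), qnorm(2 / 3)), each = 5), 5,
                dimnames = list(eq5d_dimensions(), NULL))
  fit <- manual_response_fit(list(), kap)
  x2 <- rbind(c(1, rep(0, 15), 0, 0))
  colnames(x2) <- c("intercept", qlq_scales(), "age", "age_sq")
  lp <- level_probabilities(fit, x2)
  for (dm in eq5d_dimensions()) {
    expect_equal(as.numeric(lp[[dm]]), rep(1 / 3, 3), tolerance = 1e-12)
  }
})

test_that("state probabilities form a proper distribution over 243 states", {
  kap <- matrix(rep(c(-0.5, 0.8), each = 5), 5,
                dimnames = list(eq5d_dimensions(), NULL))
  fit <- manual_response_fit(list(pain_discomfort = c(pain = 1.5)), kap)
  dat <- tiny_covariates(1L)
  x2 <- build_design(dat)$X2
  sp <- state_probabilities(fit, x2[1, , drop = FALSE])
  expect_equal(nrow(sp), 243L)
  expect_equal(sum(sp$probability), 1, tolerance = 1e-12)
  expect_true(all(sp$probability >= 0))
  # degenerate marginals concentrate on 11111
  kap1 <- matrix(rep(c(40, 41), each = 5), 5,
                 dimnames = list(eq5d_dimensions(), NULL))
  fit1 <- manual_response_fit(list(), kap1)
  sp1 <- state_probabilities(fit1, x2[1, , drop = FALSE])
  expect_equal(sp1$probability[sp1$state == "11111"], 1)
  expect_equal(sum(sp1$probability[sp1$state != "11111"]), 0)
})

test_that("expected utility is the tariff-weighted state expectation", {
  # uniform state probabilities: expectation equals the mean tariff value
  kap <- matrix(rep(c(qnorm(1 / 3), qnorm(2 / 3)), each = 5), 5,
                dimnames = list(eq5d_dimensions(), NULL))
  fit <- manual_response_fit(list(), kap)
  x2 <- rbind(c(1, rep(0, 15), 0, 0))
  colnames(x2) <- c("intercept", qlq_scales(), "age", "age_sq")
  eu <- predict_response_mean(fit, x2)
  # independence with equal thirds makes all 243 states equally likely
  expect_equal(eu, mean(tariff_table()$utility), tolerance = 1e-10)
  # pits-state certainty gives the floor
  kap_pits <- matrix(rep(c(-41, -40), each = 5), 5,
                     dimnames = list(eq5d_dimensions(), NULL))
  fit_pits <- manual_response_fit(list(), kap_pits)
  expect_equal(predict_response_mean(fit_pits, x2), -0.594)
  # full-health certainty gives 1
  kap_fh <- matrix(rep(c(40, 41), each = 5), 5,
                   dimnames = list(eq5d_dimensions(), NULL))
  expect_equal(predict_response_mean(manual_response_fit(list(), kap_fh),
                                     x2), 1)
})

test_that("simulated correlated-state probabilities match the product rule at identity", {
  kap <- matrix(rep(c(-0.4, 0.9), each = 5), 5,
                dimnames = list(eq5d_dimensions(), NULL))
  fit_ind <- manual_response_fit(list(), kap)
  fit_cor <- manual_response_fit(list(), kap,
                                 corr = diag(5) + 1e-9) # forces simulator
  dat <- tiny_covariates(1L)
  x2 <- build_design(dat)$X2[1, , drop = FALSE]
  p_ind <- state_probabilities(fit_ind, x2)$probability
  n_sim <- 20000L
  p_sim <- state_probabilities(fit_cor, x2, n_sim = n_sim,
                               seed = 42)$probability
  expect_equal(sum(p_sim), 1, tolerance = 1e-12)
  se <- sqrt(pmax(p_ind * (1 - p_ind), 1e-12) / n_sim)
  expect_true(all(abs(p_sim - p_ind) < 4 * se + 2 / n_sim))
})

test_that("ordered probit estimation recovers a known truth", {
  set.seed(314)
  n <- 4000L
  cfg <- synthetic_config(n_patients = 700L, visits_mean = 6,
                          seed = 314, missing_rate = 0,
                          mode = "dimension_latent")
  truth <- default_probit_truth()
  s <- make_synthetic_dataset(cfg, truth = truth)
  fit <- fit_response_mapping(s$data)
  # recovered pain coefficient and cutpoints for the pain dimension
  f_hat <- fit$dimensions$pain_discomfort
  f_true <- truth$dimensions$pain_discomfort
  se <- sqrt(diag(f_hat$vcov))
  est <- f_hat$beta["pain"]
  expect_lt(abs(est - f_true$beta["pain"]), 4 * se[["pain"]])
  expect_lt(abs(f_hat$kappa[1] - f_true$kappa[1]), 0.12)
  expect_lt(abs(f_hat$kappa[2] - f_true$kappa[2]), 0.12)
  # level probabilities sum to one row-wise
  lp <- level_probabilities(fit, build_design(s$data)$X2[1:20, ])
  for (dm in eq5d_dimensions()) {
    expect_equal(rowSums(lp[[dm]]), rep(1, 20))
  }
})

test_that("an unobserved level pins its cutpoint with a warning", {
  set.seed(99)
  dat <- tiny_covariates(80L)
  dat$patient_id <- sprintf("P%03d", 1:80)
  for (s in qlq_scales()) dat[[s]] <- runif(80, 0, 100)
  dat$age <- runif(80, 35, 75)
  # mobility never reaches level 3
  dat$mobility <- sample(1:2, 80, replace = TRUE)
  dat$self_care <- sample(1:3, 80, replace = TRUE)
  dat$usual_activities <- sample(1:3, 80, replace = TRUE)
  dat$pain_discomfort <- sample(1:3, 80, replace = TRUE)
  dat$anxiety_depression <- sample(1:3, 80, replace = TRUE)
  expect_warning(fit <- fit_response_mapping(dat), "pinned")
  f <- fit$dimensions$mobility
  expect_equal(unname(f$kappa[2] - f$kappa[1]), 6)
  # predicted level-3 probability is essentially zero
  lp <- level_probabilities(fit, build_design(dat)$X2)
  expect_lt(max(lp$mobility[, 3]), 1e-4)
})
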