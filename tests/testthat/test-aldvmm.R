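test_that("membership probabilities follow the softmax contract", {
  expect_equal(component_membership(cbind(1, 0.5), matrix(0, 0, 2), K = 1L),
               matrix(1, 1, 1))
  # K = 2, zero coefficients: symmetric halves
  expect_equal(as.numeric(component_membership(cbind(1, 0.3),
                                               rbind(c(0, 0)))),
               c(0.5, 0.5))
  # K = 3, scores (ln 2, ln 1, 0): softmax gives (0.5, 0.25, 0.25)
  expect_equal(as.numeric(component_membership(cbind(1), rbind(log(2), 0))),
               c(0.5, 0.25, 0.25))
  # rows always sum to one and are strictly positive
  set.seed(4)
  Z <- cbind(1, matrix(rnorm(40), 20))
  G <- matrix(rnorm(9), 3)
  P <- component_membership(Z, G)
  expect_equal(rowSums(P), rep(1, 20))
  expect_true(all(P > 0))
})

test_that("component density handles the three outcome regions", {
  # y at full health with latent mean at the threshold: half the mass above
  expect_equal(component_density(1, mu = 0.883, sigma = 0.3), 0.5)
  # y at the floor with latent mean at the floor: symmetric half
  expect_equal(component_density(-0.594, mu = -0.594, sigma = 0.1), 0.5)
  # interior: plain scaled normal density (dnorm(0)/0.2)
  expect_equal(component_density(0.5, mu = 0.5, sigma = 0.2),
               1.99471, tolerance = 1e-5)
  # the gap and out-of-range values are infeasible
  expect_error(component_density(0.95, 0.5, 0.2), "feasible")
  expect_error(component_density(1.2, 0.5, 0.2), "feasible")
  expect_error(component_density(-0.7, 0.5, 0.2), "feasible")
})

test_that("one observation's likelihood integrates to one over the outcome space", {
  bounds <- aldvmm_bounds()
  for (pars in list(c(0.3, 0.25), c(0.9, 0.15), c(-0.4, 0.5))) {
    mu <- pars[1]; s <- pars[2]
    mass_one <- component_density(1, mu, s, bounds)
    mass_floor <- component_density(bounds$floor, mu, s, bounds)
    interior <- stats::integrate(function(t) dnorm(t, mu, s),
                                 bounds$floor, bounds$upper,
                                 rel.tol = 1e-10)$value
    expect_equal(mass_one + mass_floor + interior, 1, tolerance = 1e-7)
  }
})

test_that("log-likelihood is additive and matches a direct oracle", {
  truth <- aldvmm_params(rbind(c(0.8, 0.1), c(0.3, -0.1)),
                         sigma = c(0.2, 0.3), gamma = rbind(c(0.5, -1)))
  sim <- simple_aldvmm_sim(50, truth, seed = 11)
  ll <- aldvmm_loglik(truth, sim$y, sim$X, sim$Z)
  # duplicating every observation doubles the log-likelihood
  ll2 <- aldvmm_loglik(truth, rep(sim$y, 2), rbind(sim$X, sim$X),
                       rbind(sim$Z, sim$Z))
  expect_equal(ll2, 2 * ll)
  # direct mixture-sum oracle, written independently of the implementation
  P <- component_membership(sim$Z, truth$gamma, 2L)
  f1 <- component_density(sim$y, sim$X %*% truth$beta[1, ], truth$sigma[1])
  f2 <- component_density(sim$y, sim$X %*% truth$beta[2, ], truth$sigma[2])
  expect_equal(ll, sum(log(P[, 1] * f1 + P[, 2] * f2)), tolerance = 1e-10)
})

test_that("analytic scores match numerical derivatives", {
  truth <- aldvmm_params(rbind(c(0.85, 0.1), c(0.25, 0.2)),
                         sigma = c(0.15, 0.25), gamma = rbind(c(0.4, -0.5)))
  sim <- simple_aldvmm_sim(120, truth, seed = 21)
  th <- qlqmap:::pack_params(truth)
  f <- function(t) aldvmm_loglik(qlqmap:::unpack_params(t, 2L, 2L, 2L),
                                 sim$y, sim$X, sim$Z)
  g_an <- colSums(qlqmap:::aldvmm_score_i(truth, sim$y, sim$X, sim$Z))
  g_num <- vapply(seq_along(th), function(j) {
    h <- 1e-6
    tp <- th; tm <- th
    tp[j] <- tp[j] + h; tm[j] <- tm[j] - h
    (f(tp) - f(tm)) / (2 * h)
  }, numeric(1))
  expect_equal(g_an, g_num, tolerance = 1e-5)
})

test_that("fitted likelihood dominates the generating parameters", {
  truth <- aldvmm_params(rbind(c(0.85, 0.1), c(0.25, 0.2)),
                         sigma = c(0.15, 0.25), gamma = rbind(c(0.4, -0.5)))
  sim <- simple_aldvmm_sim(600, truth, seed = 31)
  fit <- fit_aldvmm(y = sim$y, X = sim$X, Z = sim$Z, n_components = 2L,
                    control = aldvmm_control(n_restarts = 4L, seed = 5L))
  expect_gte(fit$report$loglik,
             aldvmm_loglik(truth, sim$y, sim$X, sim$Z))
  expect_true(fit$report$converged)
  # label convention: components ordered by decreasing mean membership
  Pbar <- colMeans(component_membership(sim$Z, fit$params$gamma, 2L))
  expect_true(Pbar[1] >= Pbar[2])
})

test_that("adding a component never lowers the optimum", {
  truth <- aldvmm_params(rbind(c(0.85, 0.1), c(0.25, 0.2)),
                         sigma = c(0.15, 0.25), gamma = rbind(c(0.4, -0.5)))
  sim <- simple_aldvmm_sim(500, truth, seed = 41)
  ll <- vapply(1:2, function(K) {
    fit_aldvmm(y = sim$y, X = sim$X, Z = sim$Z, n_components = K,
               control = aldvmm_control(n_restarts = 3L,
                                        seed = 7L))$report$loglik
  }, numeric(1))
  expect_gte(ll[2], ll[1] - 1e-4)
})

test_that("expected utility matches Monte Carlo and respects limits", {
  truth <- aldvmm_params(rbind(c(0.3, 0.4)), sigma = 0.2,
                         gamma = matrix(0, 0, 2))
  X <- cbind(1, c(0, 0.5, 1))
  Z <- cbind(1, c(0, 0.5, 1))
  pm <- predict_aldvmm_mean(truth, X, Z)
  mc <- simulate_aldvmm(truth, X, Z, n_draws = 1e6, seed = 9)
  mc_mean <- rowMeans(mc$draws)
  mc_se <- apply(mc$draws, 1, sd) / 1000
  expect_true(all(abs(pm - mc_mean) < 3 * mc_se))
  # latent mean far above the threshold: prediction tends to full health
  hi <- aldvmm_params(rbind(c(50, 0)), sigma = 0.2, gamma = matrix(0, 0, 2))
  expect_equal(predict_aldvmm_mean(hi, X, Z), rep(1, 3), tolerance = 1e-9)
  lo <- aldvmm_params(rbind(c(-50, 0)), sigma = 0.2, gamma = matrix(0, 0, 2))
  expect_equal(predict_aldvmm_mean(lo, X, Z), rep(-0.594, 3),
               tolerance = 1e-9)
})

test_that("simulated draws never land in infeasible zones", {
  truth <- aldvmm_params(rbind(c(0.9, 0), c(0.1, 0.3)),
                         sigma = c(0.4, 0.5), gamma = rbind(c(0, 1)))
  set.seed(2)
  X <- cbind(1, runif(200)); Z <- cbind(1, runif(200))
  sim <- simulate_aldvmm(truth, X, Z, n_draws = 50, seed = 3)
  expect_true(all(is_feasible_utility(as.numeric(sim$draws))))
  # degenerate scale pins draws at the latent mean
  deg <- aldvmm_params(rbind(c(0.5, 0)), sigma = 1e-12,
                       gamma = matrix(0, 0, 2))
  simd <- simulate_aldvmm(deg, X, Z, n_draws = 5, seed = 4)
  expect_true(all(abs(simd$draws - 0.5) < 1e-9))
  # empirical mean agrees with the analytic expectation
  pm <- predict_aldvmm_mean(truth, X, Z)
  big <- simulate_aldvmm(truth, X, Z, n_draws = 4000, seed = 5)
  se <- sd(as.numeric(big$draws)) / sqrt(4000 * 200)
  expect_lt(abs(mean(big$draws) - mean(pm)), 3 * se * sqrt(200) * 2)
})

test_that("information criteria follow their definitions", {
  truth <- aldvmm_params(rbind(c(0.7, 0.1)), sigma = 0.25,
                         gamma = matrix(0, 0, 2))
  sim <- simple_aldvmm_sim(300, truth, seed = 51)
  fit <- fit_aldvmm(y = sim$y, X = sim$X, Z = sim$Z, n_components = 1L,
                    control = aldvmm_control(n_restarts = 2L, seed = 6L))
  r <- fit$report
  expect_equal(r$aic, 2 * r$n_params - 2 * r$loglik)
  expect_equal(r$bic, r$n_params * log(r$n_obs) - 2 * r$loglik)
  expect_true(is.finite(r$qic))
})

test_that("tidy and glance expose the fit in broom shape", {
  truth <- aldvmm_params(rbind(c(0.8, 0.1), c(0.3, -0.1)),
                         sigma = c(0.2, 0.3), gamma = rbind(c(0.5, -1)))
  sim <- simple_aldvmm_sim(400, truth, seed = 61)
  fit <- fit_aldvmm(y = sim$y, X = sim$X, Z = sim$Z, n_components = 2L,
                    control = aldvmm_control(n_restarts = 3L, seed = 8L))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 2 * 2 + 2 + 1 * 2) # betas + scales + gammas
  expect_true(all(c("block", "term", "estimate", "std.error") %in%
                    names(td)))
  expect_true(all(is.finite(td$std.error)))
  expect_s3_class(glance(fit), "tbl_df")
})
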