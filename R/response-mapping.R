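#' Fit the indirect (response-mapping) model
#'
#' Stage one of response mapping: for each of the five EQ-5D dimensions,
#' fit an ordered probit of the level response (1/2/3) on the comparator
#' covariate design (QLQ-C30 scores /100, age and age squared). Level
#' probabilities follow `P(1) = Phi(k1 - xb)`, `P(2) = Phi(k2 - xb) -
#' Phi(k1 - xb)`, `P(3) = 1 - Phi(k2 - xb)` with strictly increasing
#' cutpoints. Dimensions are estimated independently; an optional Gaussian
#' latent correlation matrix can be estimated from the association of
#' generalised residuals and used at prediction time via a seeded
#' simulation estimator.
#'
#' When a dimension has an unobserved level (sparse level-3 cells occur in
#' practice: only ~1% of respondents report level 3 for mobility or
#' self-care), the affected cutpoint is not identified; the dimension is
#' then fitted as a binary probit and the missing cutpoint pinned 6 latent
#' units above the identified one, with a warning.
#'
#' @param data A complete-case mapping tibble carrying the five dimension
#'   response columns.
#' @param estimate_correlation Estimate the 5x5 latent residual correlation
#'   matrix (default `FALSE`: independent errors, identity correlation).
#' @return An object of class `response_fit`: per-dimension coefficient
#'   vectors `beta`, cutpoints `kappa` (2 per dimension), cluster-robust
#'   covariances, the latent `correlation` matrix, and per-dimension notes
#'   on pinned cutpoints.
#' @export
fit_response_mapping <- function(data, estimate_correlation = FALSE) {
  d <- build_design(data)
  if (is.null(d$responses)) {
    stop("data has no EQ-5D dimension response columns", call. = FALSE)
  }
  X <- d$X2[, -1, drop = FALSE] # polr supplies its own cutpoints
  dims <- eq5d_dimensions()
  fits <- vector("list", length(dims))
  names(fits) <- dims
  for (dm in dims) {
    yd <- d$responses[, dm]
    fits[[dm]] <- fit_one_ordered_probit(yd, X, d$cluster, dm)
  }
  corr <- diag(5)
  dimnames(corr) <- list(dims, dims)
  if (estimate_correlation) {
    corr <- latent_residual_correlation(fits, d$responses, X)
  }
  structure(list(
    dimensions = fits, correlation = corr, x_cols = colnames(X),
    n_obs = nrow(X), n_clusters = length(unique(d$cluster)),
    method = "response"
  ), class = "response_fit")
}

fit_one_ordered_probit <- function(yd, X, cluster, name) {
  levels_seen <- sort(unique(yd))
  if (length(levels_seen) < 2L) {
    stop("dimension '", name, "' has a single observed level", call. = FALSE)
  }
  # normalise column scales (age^2 is ~10^3 while scores are ~1) so the
  # probit Hessian stays well-conditioned; transform estimates back after
  scl <- pmax(apply(abs(X), 2L, mean), 1e-8)
  Xs <- sweep(X, 2L, scl, "/")
  p <- ncol(X)
  if (all(1:3 %in% levels_seen)) {
    df <- data.frame(y = factor(yd, levels = 1:3, ordered = TRUE), Xs)
    fit <- MASS::polr(y ~ ., data = df, method = "probit", Hess = TRUE)
    beta <- stats::coef(fit) / scl
    kappa <- as.numeric(fit$zeta)
    vc <- tryCatch(sandwich::vcovCL(fit, cluster = cluster),
                   error = function(e) NULL)
    if (!is.null(vc)) {
      J <- diag(c(1 / scl, 1, 1))
      vc <- J %*% vc %*% J
      dimnames(vc) <- list(c(colnames(X), "kappa1", "kappa2"),
                           c(colnames(X), "kappa1", "kappa2"))
    }
    ll <- as.numeric(stats::logLik(fit))
    pinned <- NA_character_
  } else {
    # one level unobserved: binary probit, pin the unidentified cutpoint
    missing_level <- setdiff(1:3, levels_seen)
    warning("dimension '", name, "': level ", missing_level,
            " unobserved; cutpoint pinned at +6 on the latent scale",
            call. = FALSE)
    hi <- yd > min(levels_seen) # split at the identified boundary
    df <- data.frame(y = as.integer(hi), Xs)
    fit <- stats::glm(y ~ ., data = df, family = stats::binomial("probit"))
    cf <- stats::coef(fit)
    beta <- cf[-1] / scl
    # P(y > level) = Phi(xb - kappa) so kappa = -intercept
    k_id <- -cf[1]
    kappa <- if (missing_level == 3L) c(k_id, k_id + 6) else c(k_id - 6, k_id)
    vc <- tryCatch(sandwich::vcovCL(fit, cluster = cluster),
                   error = function(e) NULL)
    if (!is.null(vc)) {
      # reorder (intercept, betas) -> (betas, kappa1 = -intercept)
      J <- rbind(cbind(matrix(0, p, 1), diag(1 / scl)),
                 c(-1, numeric(p)))
      vc <- J %*% vc %*% t(J)
      dimnames(vc) <- list(c(colnames(X), "kappa_id"),
                           c(colnames(X), "kappa_id"))
    }
    ll <- as.numeric(stats::logLik(fit))
    pinned <- paste0("level ", missing_level)
  }
  names(beta) <- colnames(X)
  names(kappa) <- c("kappa1", "kappa2")
  if (kappa[1] >= kappa[2]) stop("cutpoints not increasing for '", name, "'",
                                 call. = FALSE)
  list(beta = beta, kappa = kappa, vcov = vc, loglik = ll, pinned = pinned)
}

# expected latent residual given the observed level (generalised residual)
latent_residual_correlation <- function(fits, responses, X) {
  dims <- eq5d_dimensions()
  R <- matrix(NA_real_, nrow(X), 5L, dimnames = list(NULL, dims))
  for (i in seq_along(dims)) {
    f <- fits[[dims[i]]]
    xb <- as.numeric(X %*% f$beta)
    lo <- c(-Inf, f$kappa)[responses[, dims[i]]] - xb
    hi <- c(f$kappa, Inf)[responses[, dims[i]]] - xb
    denom <- pmax(pnorm(hi) - pnorm(lo), 1e-12)
    R[, i] <- (dnorm(lo) - dnorm(hi)) / denom # E[eps | level]
  }
  C <- stats::cor(R)
  # shrink towards identity until positive definite
  lambda <- 0
  repeat {
    Cs <- (1 - lambda) * C + lambda * diag(5)
    if (min(eigen(Cs, symmetric = TRUE, only.values = TRUE)$values) > 1e-6) {
      break
    }
    lambda <- lambda + 0.05
  }
  dimnames(Cs) <- dimnames(C)
  Cs
}

#' Per-dimension level probabilities
#'
#' @param fit A `response_fit`.
#' @param X2 Comparator design matrix including intercept column (as from
#'   [build_design()]`$X2`); the intercept is dropped internally.
#' @return A list of five n x 3 matrices of level probabilities; each row
#'   sums to one.
#' @export
level_probabilities <- function(fit, X2) {
  X <- rbind(X2)[, -1, drop = FALSE]
  out <- list()
  for (dm in eq5d_dimensions()) {
    f <- fit$dimensions[[dm]]
    xb <- as.numeric(X %*% f$beta)
    p1 <- pnorm(f$kappa[1] - xb)
    p2 <- pnorm(f$kappa[2] - xb) - p1
    p3 <- 1 - pnorm(f$kappa[2] - xb)
    out[[dm]] <- cbind(p1, p2, p3)
  }
  out
}

#' Probabilities of all 243 EQ-5D-3L states for one covariate row
#'
#' Under the default independent-errors assumption the state probability is
#' the product of the five marginal level probabilities. With a
#' non-identity latent correlation matrix, state probabilities are
#' five-dimensional normal rectangle probabilities, estimated by a seeded
#' Monte-Carlo rectangle simulator (draws of the latent vector classified
#' into states), which guarantees they still sum to one.
#'
#' @param fit A `response_fit`.
#' @param x2_row A single row of the comparator design (with intercept).
#' @param n_sim Simulation draws for the correlated case.
#' @param seed Seed for the correlated-case simulator.
#' @return A tibble: the 243 states of [enumerate_states()] with a
#'   `probability` column summing to 1.
#' @export
state_probabilities <- function(fit, x2_row, n_sim = 500L, seed = 1L) {
  states <- enumerate_states()
  S <- as.matrix(states[, eq5d_dimensions()])
  if (identical_correlation(fit$correlation)) {
    marg <- level_probabilities(fit, rbind(x2_row))
    pr <- rep(1, nrow(S))
    for (i in seq_along(eq5d_dimensions())) {
      pr <- pr * marg[[i]][1L, S[, i]]
    }
  } else {
    pr <- simulate_state_probs(fit, rbind(x2_row), n_sim, seed)
  }
  states$probability <- as.numeric(pr)
  states
}

identical_correlation <- function(C, tol = 1e-10) {
  max(abs(C - diag(nrow(C)))) < tol
}

simulate_state_probs <- function(fit, x2_row, n_sim, seed) {
  X <- rbind(x2_row)[, -1, drop = FALSE]
  dims <- eq5d_dimensions()
  set.seed(as.integer(seed))
  Lc <- chol(fit$correlation)
  E <- matrix(rnorm(n_sim * 5L), n_sim, 5L) %*% Lc
  levels <- matrix(1L, n_sim, 5L)
  for (i in seq_along(dims)) {
    f <- fit$dimensions[[dims[i]]]
    lat <- as.numeric(X %*% f$beta) + E[, i]
    levels[, i] <- 1L + (lat > f$kappa[1]) + (lat > f$kappa[2])
  }
  idx <- 1L + (levels[, 5] - 1L) + 3L * (levels[, 4] - 1L) +
    9L * (levels[, 3] - 1L) + 27L * (levels[, 2] - 1L) +
    81L * (levels[, 1] - 1L)
  tabulate(idx, nbins = 243L) / n_sim
}

#' Expected utility from a response-mapping fit (stage two)
#'
#' Tariff-weighted expectation over the 243 states:
#' `sum_s P(state s | x) * utility(s)`.
#'
#' @param fit A `response_fit`.
#' @param X2 Comparator design matrix (with intercept).
#' @param value_set Tariff from [uk3l_value_set()].
#' @param n_sim,seed Passed to the correlated-case simulator.
#' @return Numeric vector of expected utilities in `[-0.594, 1]`.
#' @export
predict_response_mean <- function(fit, X2, value_set = uk3l_value_set(),
                                  n_sim = 500L, seed = 1L) {
  X2 <- rbind(X2)
  states <- enumerate_states()
  u <- score_state(states[, eq5d_dimensions()], value_set)
  if (identical_correlation(fit$correlation)) {
    # vectorised product over the lexicographic state grid
    marg <- level_probabilities(fit, X2)
    S <- as.matrix(states[, eq5d_dimensions()])
    out <- numeric(nrow(X2))
    PR <- matrix(1, nrow(X2), 243L)
    for (i in seq_along(eq5d_dimensions())) {
      PR <- PR * marg[[i]][, S[, i], drop = FALSE]
    }
    as.numeric(PR %*% u)
  } else {
    vapply(seq_len(nrow(X2)), function(r) {
      sum(state_probabilities(fit, X2[r, , drop = FALSE], n_sim,
                              seed + r)$probability * u)
    }, numeric(1))
  }
}

#' Predict expected utilities from a response-mapping fit
#'
#' @param object A `response_fit`.
#' @param newdata A mapping tibble; or supply the comparator design `X2`.
#' @param X2 Optional explicit design matrix.
#' @param value_set Tariff.
#' @param ... Unused.
#' @return Numeric vector of expected utilities.
#' @export
predict.response_fit <- function(object, newdata = NULL, X2 = NULL,
                                 value_set = uk3l_value_set(), ...) {
  if (!is.null(newdata)) X2 <- build_design(newdata)$X2
  stopifnot(!is.null(X2))
  predict_response_mean(object, X2, value_set)
}

#' Tidy a response-mapping fit
#'
#' @param x A `response_fit`.
#' @param ... Unused.
#' @return A tibble with one row per dimension per term (coefficients and
#'   cutpoints) and cluster-robust standard errors where available.
#' @export
tidy.response_fit <- function(x, ...) {
  purrr::imap_dfr(x$dimensions, function(f, dm) {
    terms <- c(names(f$beta), names(f$kappa))
    est <- c(f$beta, f$kappa)
    se <- rep(NA_real_, length(est))
    if (!is.null(f$vcov)) {
      v <- sqrt(pmax(diag(f$vcov), 0))
      se[seq_len(min(length(v), length(se)))] <-
        v[seq_len(min(length(v), length(se)))]
    }
    tibble::tibble(dimension = dm, term = terms, estimate = est,
                   std.error = se, pinned = f$pinned)
  })
}

#' @export
glance.response_fit <- function(x, ...) {
  tibble::tibble(
    n_obs = x$n_obs, n_clusters = x$n_clusters,
    loglik = sum(vapply(x$dimensions, `[[`, numeric(1), "loglik")),
    n_pinned = sum(!is.na(vapply(x$dimensions, `[[`, character(1),
                                 "pinned")))
  )
}

#' @export
print.response_fit <- function(x, ...) {
  cat("Response mapping: five ordered probits ->",
      "tariff-weighted expectation over 243 states\n")
  cat(sprintf("  n = %d observations, %d clusters\n", x$n_obs, x$n_clusters))
  if (!identical_correlation(x$correlation)) {
    cat("  latent correlation layer: estimated (simulated state probabilities)\n")
  }
  invisible(x)
}
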