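#' @importFrom stats dnorm pnorm optim qnorm rnorm runif sd quantile
NULL

#' Control options for ALDVMM estimation
#'
#' @param n_restarts Number of optimisation starts (the first is a
#'   deterministic quantile-based start, the rest are randomised
#'   perturbations). Mixture likelihoods are multimodal, so keep this > 1
#'   for real fits.
#' @param seed Integer seed governing the randomised starts.
#' @param tol Convergence tolerance on the per-observation gradient
#'   max-norm (`max |d loglik / d theta| / n`).
#' @param max_iter Maximum BFGS iterations per start.
#' @param sigma_min Scale below which a component is declared degenerate.
#' @return A list of class `aldvmm_control`.
#' @export
aldvmm_control <- function(n_restarts = 20L, seed = 1L, tol = 1e-6,
                           max_iter = 500L, sigma_min = 5e-3) {
  structure(list(n_restarts = as.integer(n_restarts), seed = as.integer(seed),
                 tol = tol, max_iter = as.integer(max_iter),
                 sigma_min = sigma_min),
            class = "aldvmm_control")
}

#' Bounds of the adjusted utility scale
#'
#' @param upper Largest feasible utility below full health (UK: 0.883).
#' @param floor Lowest feasible utility (UK pits state: -0.594).
#' @param full_health Utility of full health (1).
#' @return List of class `aldvmm_bounds`.
#' @export
aldvmm_bounds <- function(upper = 0.883, floor = -0.594, full_health = 1) {
  stopifnot(floor < upper, upper < full_health)
  structure(list(upper = upper, floor = floor, full_health = full_health),
            class = "aldvmm_bounds")
}

#' Construct an ALDVMM parameter set
#'
#' @param beta K x p matrix of component mean coefficients (one row per
#'   component, columns follow the component design matrix X).
#' @param sigma Length-K vector of positive component scales.
#' @param gamma (K-1) x q matrix of membership multinomial-logit
#'   coefficients over the membership design Z; component K is the
#'   reference. For K = 1 supply a 0 x q matrix.
#' @return List of class `aldvmm_params`.
#' @export
aldvmm_params <- function(beta, sigma, gamma) {
  beta <- rbind(beta)
  K <- nrow(beta)
  stopifnot(length(sigma) == K, all(sigma > 0))
  gamma <- if (is.null(gamma)) {
    matrix(0, 0L, 0L)
  } else {
    matrix(gamma, nrow = K - 1L)
  }
  stopifnot(nrow(gamma) == K - 1L)
  structure(list(beta = beta, sigma = as.numeric(sigma), gamma = gamma,
                 K = K), class = "aldvmm_params")
}

## ---- parameter packing -----------------------------------------------

pack_params <- function(par) {
  c(as.vector(t(par$beta)), log(par$sigma),
    if (par$K > 1L) as.vector(t(par$gamma)))
}

unpack_params <- function(theta, K, p, q) {
  beta <- matrix(theta[seq_len(K * p)], nrow = K, byrow = TRUE)
  # clamp log-scales so a wild line-search step cannot underflow exp() to 0;
  # the collapse barrier in the objective steers the search back
  sigma <- exp(pmin(pmax(theta[K * p + seq_len(K)], -30), 5))
  gamma <- if (K > 1L) {
    matrix(theta[K * p + K + seq_len((K - 1L) * q)], nrow = K - 1L,
           byrow = TRUE)
  } else {
    matrix(0, 0L, q)
  }
  aldvmm_params(beta, sigma, gamma)
}

n_aldvmm_params <- function(K, p, q) K * p + K + (K - 1L) * q

## ---- likelihood pieces ------------------------------------------------

#' Mixture component membership probabilities
#'
#' Softmax of the membership linear indices with component K as the
#' reference (zero) category.
#'
#' @param Z Membership design matrix (n x q) or a single row.
#' @param gamma (K-1) x q coefficient matrix (component K is reference).
#' @param K Number of components.
#' @return n x K matrix of probabilities; each row is strictly positive and
#'   sums to one.
#' @export
component_membership <- function(Z, gamma, K = nrow(rbind(gamma)) + 1L) {
  Z <- rbind(Z)
  if (K == 1L) return(matrix(1, nrow(Z), 1L))
  scores <- cbind(Z %*% t(rbind(gamma)), 0)
  scores <- scores - apply(scores, 1L, max)
  e <- exp(scores)
  e / rowSums(e)
}

# classify observations against the bounds; errors on infeasible values
classify_y <- function(y, bounds, tol = 1e-8) {
  bad <- y > bounds$full_health + tol | y < bounds$floor - tol |
    (y > bounds$upper + tol & y < bounds$full_health - tol)
  if (any(bad)) {
    stop("utility value(s) outside the feasible zone [",
         bounds$floor, ", ", bounds$upper, "] U {", bounds$full_health,
         "}: e.g. ", y[bad][1], call. = FALSE)
  }
  type <- integer(length(y)) # 0 interior, 1 at full health, -1 at floor
  type[abs(y - bounds$full_health) <= tol] <- 1L
  type[abs(y - bounds$floor) <= tol] <- -1L
  type
}

#' Censored-normal component likelihood contribution
#'
#' The per-component density of an adjusted censored normal: observations at
#' full health carry the upper tail mass above the gap threshold, the pits
#' state carries the lower tail mass, and interior values the normal
#' density.
#'
#' @param y Observed utilities (feasible values only).
#' @param mu,sigma Component latent mean(s) and scale.
#' @param bounds An [aldvmm_bounds()] object.
#' @param log Return the log contribution?
#' @return Numeric vector of likelihood contributions.
#' @export
component_density <- function(y, mu, sigma, bounds = aldvmm_bounds(),
                              log = FALSE) {
  stopifnot(all(sigma > 0))
  type <- classify_y(y, bounds)
  lf <- numeric(length(y))
  up <- type == 1L
  lo <- type == -1L
  mid <- type == 0L
  mu <- rep_len(mu, length(y))
  sigma <- rep_len(sigma, length(y))
  if (any(up)) {
    lf[up] <- pnorm((mu[up] - bounds$upper) / sigma[up], log.p = TRUE)
  }
  if (any(lo)) {
    lf[lo] <- pnorm((bounds$floor - mu[lo]) / sigma[lo], log.p = TRUE)
  }
  if (any(mid)) {
    lf[mid] <- dnorm((y[mid] - mu[mid]) / sigma[mid], log = TRUE) -
      log(sigma[mid])
  }
  if (log) lf else exp(lf)
}

# n x K matrix of log component contributions
log_component_matrix <- function(y, MU, sigma, type, bounds) {
  n <- length(y)
  K <- ncol(MU)
  LF <- matrix(0, n, K)
  up <- type == 1L
  lo <- type == -1L
  mid <- type == 0L
  for (c in seq_len(K)) {
    s <- sigma[c]
    if (any(up)) LF[up, c] <- pnorm((MU[up, c] - bounds$upper) / s,
                                    log.p = TRUE)
    if (any(lo)) LF[lo, c] <- pnorm((bounds$floor - MU[lo, c]) / s,
                                    log.p = TRUE)
    if (any(mid)) LF[mid, c] <- dnorm((y[mid] - MU[mid, c]) / s, log = TRUE) -
        log(s)
  }
  LF
}

log_membership_matrix <- function(Z, gamma, K) {
  if (K == 1L) return(matrix(0, nrow(Z), 1L))
  scores <- cbind(Z %*% t(gamma), 0)
  m <- apply(scores, 1L, max)
  scores - (m + log(rowSums(exp(scores - m))))
}

#' ALDVMM log-likelihood
#'
#' Sum over observations of the log mixture likelihood
#' `log sum_c p_c(z) f_c(y | x)`, where `p_c` is the softmax membership
#' probability and `f_c` the censored-normal component contribution.
#'
#' @param params An [aldvmm_params()] object.
#' @param y Observed utilities.
#' @param X Component design matrix (n x p).
#' @param Z Membership design matrix (n x q).
#' @param bounds An [aldvmm_bounds()] object.
#' @return The log-likelihood (scalar).
#' @export
aldvmm_loglik <- function(params, y, X, Z, bounds = aldvmm_bounds()) {
  sum(aldvmm_loglik_i(params, y, X, Z, bounds))
}

aldvmm_loglik_i <- function(params, y, X, Z, bounds = aldvmm_bounds()) {
  X <- rbind(X); Z <- rbind(Z)
  type <- classify_y(y, bounds)
  MU <- X %*% t(params$beta)
  LF <- log_component_matrix(y, MU, params$sigma, type, bounds)
  LP <- log_membership_matrix(Z, params$gamma, params$K)
  A <- LP + LF
  m <- apply(A, 1L, max)
  m + log(rowSums(exp(A - m)))
}

# per-observation score matrix (n x npar), analytic
aldvmm_score_i <- function(params, y, X, Z, bounds = aldvmm_bounds()) {
  X <- rbind(X); Z <- rbind(Z)
  n <- length(y)
  K <- params$K
  p <- ncol(X)
  q <- ncol(Z)
  type <- classify_y(y, bounds)
  MU <- X %*% t(params$beta)
  LF <- log_component_matrix(y, MU, params$sigma, type, bounds)
  LP <- log_membership_matrix(Z, params$gamma, K)
  A <- LP + LF
  m <- apply(A, 1L, max)
  ll <- m + log(rowSums(exp(A - m)))
  W <- exp(A - ll) # posterior responsibilities, n x K
  P <- exp(LP)

  up <- type == 1L
  lo <- type == -1L
  mid <- type == 0L
  dmu <- matrix(0, n, K)  # d log f / d mu
  deta <- matrix(0, n, K) # d log f / d log sigma
  for (c in seq_len(K)) {
    s <- params$sigma[c]
    if (any(mid)) {
      z <- (y[mid] - MU[mid, c]) / s
      dmu[mid, c] <- z / s
      deta[mid, c] <- z^2 - 1
    }
    if (any(up)) {
      a <- (MU[up, c] - bounds$upper) / s
      mills <- exp(dnorm(a, log = TRUE) - pnorm(a, log.p = TRUE))
      dmu[up, c] <- mills / s
      deta[up, c] <- -a * mills
    }
    if (any(lo)) {
      b <- (bounds$floor - MU[lo, c]) / s
      mills <- exp(dnorm(b, log = TRUE) - pnorm(b, log.p = TRUE))
      dmu[lo, c] <- -mills / s
      deta[lo, c] <- -b * mills
    }
  }
  npar <- n_aldvmm_params(K, p, q)
  S <- matrix(0, n, npar)
  for (c in seq_len(K)) {
    S[, (c - 1L) * p + seq_len(p)] <- (W[, c] * dmu[, c]) * X
  }
  S[, K * p + seq_len(K)] <- W * deta
  if (K > 1L) {
    for (c in seq_len(K - 1L)) {
      S[, K * p + K + (c - 1L) * q + seq_len(q)] <- (W[, c] - P[, c]) * Z
    }
  }
  S
}

## ---- starting values ---------------------------------------------------

aldvmm_start <- function(y, X, Z, K, bounds, jitter = 0, rng = NULL) {
  p <- ncol(X)
  q <- ncol(Z)
  # split observations into K severity groups by y quantile
  qs <- quantile(y, probs = seq(0, 1, length.out = K + 1L))
  grp <- cut(y, breaks = unique(c(-Inf, qs[-c(1L, K + 1L)], Inf)),
             labels = FALSE)
  if (length(unique(grp)) < K) grp <- sample(rep_len(seq_len(K), length(y)))
  beta <- matrix(0, K, p)
  sigma <- numeric(K)
  for (c in seq_len(K)) {
    yc <- y[grp == c]
    mu0 <- mean(yc)
    # latent mean above the threshold when the group is mostly full health
    if (mean(yc >= bounds$full_health - 1e-8) > 0.5) {
      mu0 <- bounds$upper + 0.1
    }
    beta[c, 1L] <- mu0
    sigma[c] <- max(sd(yc), 0.08)
  }
  gamma <- matrix(0, max(K - 1L, 0L), q)
  if (jitter > 0) {
    beta[, 1L] <- beta[, 1L] + rng(K) * jitter
    sigma <- sigma * exp(rng(K) * jitter)
    if (K > 1L) gamma[, 1L] <- rng(K - 1L) * jitter
  }
  aldvmm_params(beta, sigma, gamma)
}

## ---- fitting ------------------------------------------------------------

#' Fit an adjusted limited dependent variable mixture model
#'
#' Maximum-likelihood estimation of a K-component mixture of censored
#' normals for EQ-5D-3L utilities. Each component is normal on a latent
#' scale, censored above at the gap threshold (latent values above it are
#' observed as full health, 1) and below at the pits-state floor; component
#' membership probabilities follow a multinomial logit in the membership
#' covariates. Estimation uses BFGS from multiple starts; the best local
#' optimum wins (ties broken by the lowest start index). Components are
#' relabelled in decreasing order of average membership probability so that
#' labels are stable across runs.
#'
#' @param data A complete-case mapping tibble (see [read_mapping_data()]);
#'   the standard design of [build_design()] is used. Alternatively supply
#'   `y`, `X`, `Z` (and optionally `cluster`) directly and leave `data`
#'   `NULL`.
#' @param n_components Number of mixture components K (the source analysis
#'   considered 1-4).
#' @param control An [aldvmm_control()] list.
#' @param bounds An [aldvmm_bounds()] object.
#' @param y,X,Z,cluster Optional explicit outcome vector, component design,
#'   membership design and cluster ids (used when `data` is `NULL`).
#' @return An object of class `aldvmm_fit`: a list with `params`
#'   ([aldvmm_params()]), `report` (a one-row tibble of fit statistics:
#'   loglik, n_params, aic, bic, qic, convergence diagnostics), `vcov`
#'   (cluster-robust sandwich covariance of the packed parameter vector),
#'   the designs' column names and the bounds.
#' @export
fit_aldvmm <- function(data = NULL, n_components = 2L,
                       control = aldvmm_control(), bounds = aldvmm_bounds(),
                       y = NULL, X = NULL, Z = NULL, cluster = NULL) {
  if (!is.null(data)) {
    d <- build_design(data)
    y <- d$y; X <- d$X; Z <- d$Z; cluster <- d$cluster
    if (is.null(y)) stop("data has no eq5d utility column", call. = FALSE)
  }
  stopifnot(!is.null(y), !is.null(X), !is.null(Z))
  X <- rbind(X); Z <- rbind(Z)
  if (is.null(cluster)) cluster <- seq_along(y)
  K <- as.integer(n_components)
  p <- ncol(X)
  q <- ncol(Z)
  npar <- n_aldvmm_params(K, p, q)
  if (length(y) <= npar) {
    stop("need more observations than parameters (", npar, ")",
         call. = FALSE)
  }
  classify_y(y, bounds) # validate outcomes up front

  # soft barrier against component collapse (sigma -> 0 blows up the
  # mixture likelihood at data points); inert at any optimum with all
  # scales above sigma_barrier, so estimates and vcov are unaffected there
  sigma_barrier <- log(0.015)
  barrier_w <- 1e3
  eta_idx <- K * p + seq_len(K)
  negll <- function(theta) {
    par <- unpack_params(theta, K, p, q)
    ll <- aldvmm_loglik(par, y, X, Z, bounds)
    if (!is.finite(ll)) return(1e12)
    pen <- sum(barrier_w * pmax(sigma_barrier - theta[eta_idx], 0)^2)
    -ll + pen
  }
  neggrad <- function(theta) {
    par <- unpack_params(theta, K, p, q)
    g <- -colSums(aldvmm_score_i(par, y, X, Z, bounds))
    g[!is.finite(g)] <- 0
    g[eta_idx] <- g[eta_idx] -
      2 * barrier_w * pmax(sigma_barrier - theta[eta_idx], 0)
    g
  }
  # scale optimisation steps to covariate magnitudes (age is in years)
  col_scale <- function(M) pmax(apply(abs(M), 2L, mean), 1e-3)
  # packing order is component-major: beta_1, ..., beta_K, log sigmas, gammas
  parscale <- c(rep(1 / col_scale(X), K), rep(1, K),
                if (K > 1L) rep(1 / col_scale(Z), K - 1L))

  set.seed(control$seed)
  start_seeds <- sample.int(.Machine$integer.max - 1L, control$n_restarts)
  best <- NULL
  n_used <- 0L
  for (s in seq_len(control$n_restarts)) {
    set.seed(start_seeds[s])
    rng <- function(k) rnorm(k)
    st <- aldvmm_start(y, X, Z, K, bounds,
                       jitter = if (s == 1L) 0 else 0.25, rng = rng)
    theta0 <- pack_params(st)
    opt <- tryCatch(
      optim(theta0, negll, neggrad, method = "BFGS",
            control = list(maxit = control$max_iter, reltol = 1e-9,
                           parscale = parscale)),
      error = function(e) NULL
    )
    n_used <- n_used + 1L
    if (is.null(opt)) next
    par <- unpack_params(opt$par, K, p, q)
    if (any(par$sigma < control$sigma_min)) next # degenerate component
    cand <- list(theta = opt$par, value = -opt$value, start = s,
                 seed = start_seeds[s])
    if (is.null(best) || cand$value > best$value + 1e-9) best <- cand
  }
  if (is.null(best)) {
    stop("ALDVMM estimation failed: no start converged to a ",
         "non-degenerate optimum (K = ", K, ", ", control$n_restarts,
         " starts)", call. = FALSE)
  }
  # polish the winner until the scaled gradient norm meets tol
  theta <- best$theta
  for (i in 1:3) {
    g_norm <- max(abs(neggrad(theta))) / length(y)
    if (g_norm < control$tol) break
    opt <- optim(theta, negll, neggrad, method = "BFGS",
                 control = list(maxit = control$max_iter, reltol = 1e-14,
                                parscale = parscale))
    theta <- opt$par
  }
  g_norm <- max(abs(neggrad(theta))) / length(y)
  params <- unpack_params(theta, K, p, q)
  if (any(params$sigma < control$sigma_min)) {
    stop("degenerate component scale at the optimum (sigma -> 0)",
         call. = FALSE)
  }

  # relabel components by decreasing average membership probability
  Pbar <- colMeans(component_membership(Z, params$gamma, K))
  ord <- order(Pbar, decreasing = TRUE)
  params <- relabel_params(params, ord)
  theta <- pack_params(params)

  ll <- aldvmm_loglik(params, y, X, Z, bounds)
  S <- aldvmm_score_i(params, y, X, Z, bounds)
  H <- tryCatch(stats::optimHess(theta, negll, neggrad),
                error = function(e) NULL)
  vc <- cluster_sandwich(H, S, cluster)
  aic <- 2 * npar - 2 * ll
  bic <- npar * log(length(y)) - 2 * ll
  qic <- if (!is.null(vc$bread)) {
    -2 * ll + 2 * sum(diag(vc$J %*% vc$vcov))
  } else {
    NA_real_
  }
  report <- tibble::tibble(
    n_obs = length(y), n_clusters = length(unique(cluster)),
    n_params = npar, loglik = ll, aic = aic, bic = bic, qic = qic,
    converged = g_norm < max(control$tol, 1e-4),
    grad_norm = g_norm, n_restarts_used = n_used,
    best_start = best$start, best_start_seed = best$seed
  )
  structure(list(
    params = params, report = report, vcov = vc$vcov, bounds = bounds,
    x_cols = colnames(X), z_cols = colnames(Z), n_components = K,
    cluster = cluster, method = "aldvmm"
  ), class = "aldvmm_fit")
}

relabel_params <- function(params, ord) {
  K <- params$K
  beta <- params$beta[ord, , drop = FALSE]
  sigma <- params$sigma[ord]
  if (K > 1L) {
    G <- rbind(params$gamma, 0)[ord, , drop = FALSE] # scores incl. reference
    gamma <- sweep(G[-K, , drop = FALSE], 2L, G[K, ]) # new reference = last
  } else {
    gamma <- params$gamma
  }
  aldvmm_params(beta, sigma, gamma)
}

# cluster-robust sandwich from a Hessian of -loglik and per-obs scores
cluster_sandwich <- function(H, S, cluster) {
  if (is.null(H)) return(list(vcov = NULL, bread = NULL, J = NULL))
  bread <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(bread)) return(list(vcov = NULL, bread = NULL, J = H))
  Sg <- rowsum(S, group = as.character(cluster))
  G <- nrow(Sg)
  meat <- crossprod(Sg) * G / max(G - 1L, 1L)
  list(vcov = bread %*% meat %*% bread, bread = bread, J = H)
}

## ---- prediction and simulation -----------------------------------------

truncnorm_mean <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma
  b <- (hi - mu) / sigma
  denom <- pnorm(b) - pnorm(a)
  m <- mu + sigma * (dnorm(a) - dnorm(b)) / pmax(denom, 1e-300)
  # when essentially no mass lies inside, the interior term is weightless
  m[denom < 1e-12] <- (lo + hi) / 2
  m
}

#' Expected utility under an ALDVMM parameter set
#'
#' The analytic mean of the censored mixture: for each component, full
#' health (1) with the probability of the latent exceeding the gap
#' threshold, the floor with the probability of falling below it, and the
#' doubly-truncated normal mean in between; averaged over membership
#' probabilities. Predictions therefore always lie in the feasible interval
#' and can never fall in the gap-free forbidden zones.
#'
#' @param params An [aldvmm_params()] object.
#' @param X,Z Design matrices (rows aligned).
#' @param bounds An [aldvmm_bounds()] object.
#' @return Numeric vector of expected utilities, one per row.
#' @export
predict_aldvmm_mean <- function(params, X, Z, bounds = aldvmm_bounds()) {
  X <- rbind(X); Z <- rbind(Z)
  MU <- X %*% t(params$beta)
  P <- component_membership(Z, params$gamma, params$K)
  out <- numeric(nrow(X))
  for (c in seq_len(params$K)) {
    s <- params$sigma[c]
    mu <- MU[, c]
    phi_up <- pnorm((bounds$upper - mu) / s)
    phi_lo <- pnorm((bounds$floor - mu) / s)
    m <- truncnorm_mean(mu, s, bounds$floor, bounds$upper)
    ec <- (1 - phi_up) * bounds$full_health + phi_lo * bounds$floor +
      (phi_up - phi_lo) * m
    out <- out + P[, c] * ec
  }
  out
}

#' Simulate utilities from an ALDVMM parameter set
#'
#' For each covariate row, draws a component from the membership
#' probabilities, then a latent normal, then censors: latent values at or
#' above the gap threshold map to full health (1), values at or below the
#' floor map to the floor, the rest are observed as-is. No draw can land in
#' the infeasible gap.
#'
#' @inheritParams predict_aldvmm_mean
#' @param n_draws Draws per row.
#' @param seed Integer seed (mandatory, for reproducibility).
#' @param offset Optional per-row latent mean shift (e.g. a patient random
#'   effect), recycled to `nrow(X)`.
#' @return A list with `draws` and `component`, both n x n_draws matrices.
#' @export
simulate_aldvmm <- function(params, X, Z, n_draws = 1000L, seed,
                            bounds = aldvmm_bounds(), offset = 0) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  X <- rbind(X); Z <- rbind(Z)
  n <- nrow(X)
  MU <- X %*% t(params$beta) + rep_len(offset, n)
  P <- component_membership(Z, params$gamma, params$K)
  set.seed(as.integer(seed))
  cp <- if (params$K > 1L) {
    t(apply(P, 1L, cumsum))[, -params$K, drop = FALSE]
  } else {
    NULL
  }
  draws <- matrix(NA_real_, n, n_draws)
  comp <- matrix(NA_integer_, n, n_draws)
  for (j in seq_len(n_draws)) {
    u <- runif(n)
    cj <- if (params$K == 1L) rep(1L, n) else 1L + rowSums(u > cp)
    mu_j <- MU[cbind(seq_len(n), cj)]
    latent <- rnorm(n, mu_j, params$sigma[cj])
    yj <- latent
    yj[latent >= bounds$upper] <- bounds$full_health
    yj[latent <= bounds$floor] <- bounds$floor
    # draws censored at the threshold itself belong to full health
    draws[, j] <- yj
    comp[, j] <- cj
  }
  list(draws = draws, component = comp)
}

## ---- methods ------------------------------------------------------------

#' @export
print.aldvmm_fit <- function(x, ...) {
  cat("Adjusted limited dependent variable mixture model (K =",
      x$n_components, ")\n")
  cat(sprintf("  n = %d observations, %d clusters; loglik = %.4f\n",
              x$report$n_obs, x$report$n_clusters, x$report$loglik))
  cat(sprintf("  AIC = %.2f  BIC = %.2f  QIC = %.2f\n",
              x$report$aic, x$report$bic, x$report$qic))
  cat("  component scales:",
      paste(sprintf("%.3f", x$params$sigma), collapse = ", "), "\n")
  invisible(x)
}

#' Predict expected utilities from a fitted ALDVMM
#'
#' @param object An `aldvmm_fit`.
#' @param newdata A mapping tibble; when `NULL` prediction requires explicit
#'   `X` and `Z`.
#' @param X,Z Optional explicit design matrices.
#' @param ... Unused.
#' @return Numeric vector of expected utilities.
#' @export
predict.aldvmm_fit <- function(object, newdata = NULL, X = NULL, Z = NULL,
                               ...) {
  if (!is.null(newdata)) {
    d <- build_design(newdata)
    X <- d$X; Z <- d$Z
  }
  stopifnot(!is.null(X), !is.null(Z))
  predict_aldvmm_mean(object$params, X, Z, object$bounds)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an ALDVMM fit into one row per coefficient
#'
#' @param x An `aldvmm_fit`.
#' @param ... Unused.
#' @return A tibble with `block` (component / scale / membership), `term`,
#'   `component`, `estimate` and cluster-robust `std.error`.
#' @export
tidy.aldvmm_fit <- function(x, ...) {
  K <- x$params$K
  p <- length(x$x_cols)
  q <- length(x$z_cols)
  se <- if (!is.null(x$vcov)) sqrt(pmax(diag(x$vcov), 0)) else
    rep(NA_real_, n_aldvmm_params(K, p, q))
  rows <- list()
  k0 <- 0L
  for (c in seq_len(K)) {
    rows[[length(rows) + 1L]] <- tibble::tibble(
      block = "component", component = c, term = x$x_cols,
      estimate = x$params$beta[c, ], std.error = se[k0 + seq_len(p)])
    k0 <- k0 + p
  }
  rows[[length(rows) + 1L]] <- tibble::tibble(
    block = "scale", component = seq_len(K), term = "log(sigma)",
    estimate = log(x$params$sigma), std.error = se[k0 + seq_len(K)])
  k0 <- k0 + K
  if (K > 1L) {
    for (c in seq_len(K - 1L)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        block = "membership", component = c, term = x$z_cols,
        estimate = x$params$gamma[c, ], std.error = se[k0 + seq_len(q)])
      k0 <- k0 + q
    }
  }
  dplyr::bind_rows(rows)
}

#' One-row model summary of an ALDVMM fit
#'
#' @param x An `aldvmm_fit`.
#' @param ... Unused.
#' @return A one-row tibble (the fit report).
#' @export
glance.aldvmm_fit <- function(x, ...) x$report
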