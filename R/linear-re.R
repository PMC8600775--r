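#' Fit the random-effects linear comparator
#'
#' A linear regression of the EQ-5D utility on the comparator design
#' (QLQ-C30 scores /100, age and age squared) with a patient-level random
#' intercept, estimated by maximum likelihood via [lme4::lmer()]. When no
#' patient contributes more than one visit the model collapses to pooled
#' OLS. Predictions use the fixed effects only (population level), since
#' mapping targets out-of-sample patients; they are deliberately NOT
#' clamped, so they can leave the feasible utility zone -- the documented
#' flaw of linear mapping that the diagnostics expose.
#'
#' Cluster-robust (patient-level) covariance of the fixed effects is
#' computed by a GLS sandwich: with `V_i = sigma_u^2 Z_i Z_i' + sigma^2 I`,
#' the bread is `(sum X_i' V_i^-1 X_i)^-1` and the meat stacks the
#' per-cluster weighted residual outer products.
#'
#' @param data A complete-case mapping tibble with an `eq5d` column.
#' @return Object of class `linear_re_fit`: `coefficients` (fixed effects),
#'   `sigma_u` (random-intercept SD), `sigma_e` (residual SD), `vcov`
#'   (cluster-robust), and a `report` tibble (loglik, aic, bic, n).
#' @export
fit_linear_re <- function(data) {
  d <- build_design(data)
  if (is.null(d$y)) stop("data has no eq5d utility column", call. = FALSE)
  X <- d$X2
  y <- d$y
  cluster <- as.character(d$cluster)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("singular comparator design (collinear ",
                               "covariates)", call. = FALSE)
  replicated <- any(table(cluster) > 1L)
  # normalise column scales (age^2 dwarfs the /100 scores) for the
  # optimiser; fixed effects are transformed back below
  scl <- c(1, pmax(apply(abs(X[, -1, drop = FALSE]), 2L, mean), 1e-8))
  names(scl) <- colnames(X)
  Xs <- sweep(X, 2L, scl, "/")
  if (replicated) {
    df <- data.frame(y = y, Xs[, -1, drop = FALSE], .pid = cluster,
                     check.names = FALSE)
    fml <- stats::reformulate(c(sprintf("`%s`", colnames(X)[-1]),
                                "(1 | .pid)"), response = "y")
    fit <- lme4::lmer(fml, data = df, REML = FALSE)
    fe <- lme4::fixef(fit)
    vc <- as.data.frame(lme4::VarCorr(fit))
    sigma_u <- vc$sdcor[vc$grp == ".pid"]
    sigma_e <- vc$sdcor[vc$grp == "Residual"]
    ll <- as.numeric(stats::logLik(fit))
    npar <- length(fe) + 2L
  } else {
    fit <- stats::lm(y ~ Xs - 1)
    fe <- stats::coef(fit)
    names(fe) <- sub("^Xs", "", names(fe))
    sigma_u <- 0
    sigma_e <- summary(fit)$sigma
    ll <- as.numeric(stats::logLik(fit))
    npar <- length(fe) + 1L
  }
  beta <- stats::setNames(as.numeric(fe)[order_to_design(names(fe), X)],
                          colnames(X)) / scl
  vcr <- gls_cluster_vcov(y, X, beta, sigma_u, sigma_e, cluster)
  n <- length(y)
  report <- tibble::tibble(
    n_obs = n, n_clusters = length(unique(cluster)), n_params = npar,
    loglik = ll, aic = 2 * npar - 2 * ll, bic = npar * log(n) - 2 * ll,
    qic = NA_real_, sigma_u = sigma_u, sigma_e = sigma_e,
    converged = TRUE
  )
  structure(list(coefficients = beta, sigma_u = sigma_u, sigma_e = sigma_e,
                 vcov = vcr, report = report, x_cols = colnames(X),
                 method = "linear"),
            class = "linear_re_fit")
}

# map lme4/lm coefficient names back onto the design column order
order_to_design <- function(nms, X) {
  clean <- gsub("`", "", nms)
  clean[clean == "(Intercept)"] <- "intercept"
  match(colnames(X), clean)
}

gls_cluster_vcov <- function(y, X, beta, sigma_u, sigma_e, cluster) {
  r <- as.numeric(y - X %*% beta)
  ids <- split(seq_along(y), cluster)
  p <- ncol(X)
  bread_inv <- matrix(0, p, p)
  meat <- matrix(0, p, p)
  for (idx in ids) {
    Xi <- X[idx, , drop = FALSE]
    ri <- r[idx]
    ni <- length(idx)
    # V_i^-1 via Woodbury for the exchangeable structure
    a <- 1 / sigma_e^2
    b <- -sigma_u^2 / (sigma_e^2 * (sigma_e^2 + ni * sigma_u^2))
    XtVi <- a * t(Xi) + b * tcrossprod(colSums(Xi), rep(1, ni))
    bread_inv <- bread_inv + XtVi %*% Xi
    u <- XtVi %*% ri
    meat <- meat + tcrossprod(u)
  }
  G <- length(ids)
  bread <- solve(bread_inv)
  bread %*% (meat * G / max(G - 1, 1)) %*% bread
}

#' Predict utilities from the linear comparator
#'
#' @param object A `linear_re_fit`.
#' @param newdata A mapping tibble; or supply `X2` directly.
#' @param X2 Optional comparator design matrix.
#' @param ... Unused.
#' @return Fixed-effect linear predictions (unclamped).
#' @export
predict.linear_re_fit <- function(object, newdata = NULL, X2 = NULL, ...) {
  if (!is.null(newdata)) X2 <- build_design(newdata)$X2
  stopifnot(!is.null(X2))
  as.numeric(rbind(X2) %*% object$coefficients)
}

#' @export
tidy.linear_re_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$coefficients), estimate = as.numeric(x$coefficients),
    std.error = sqrt(pmax(diag(x$vcov), 0))
  )
}

#' @export
glance.linear_re_fit <- function(x, ...) x$report

#' @export
print.linear_re_fit <- function(x, ...) {
  cat("Random-intercept linear comparator (ML)\n")
  cat(sprintf("  n = %d, clusters = %d; sigma_u = %.4f, sigma_e = %.4f\n",
              x$report$n_obs, x$report$n_clusters, x$sigma_u, x$sigma_e))
  invisible(x)
}
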