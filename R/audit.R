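#' Mixture variance via the law of total variance
#'
#' `sum p_c (sd_c^2 + mean_c^2) - (sum p_c mean_c)^2`: the overall variance
#' of a mixture reconstructed from component probabilities, means and SDs.
#'
#' @param probs Component probabilities (must sum to 1 within `tol`).
#' @param means,sds Component means and standard deviations.
#' @param tol Tolerance on `sum(probs) - 1`.
#' @return The total variance (scalar).
#' @examples
#' total_variance(c(0.2213, 0.3213, 0.1686, 0.2888),
#'                c(0.6720, 0.8238, 0.4740, 0.7781),
#'                c(0.070, 0.242, 0.371, 0.126)) # ~0.0628
#' @export
total_variance <- function(probs, means, sds, tol = 1e-8) {
  stopifnot(length(probs) == length(means), length(means) == length(sds))
  if (abs(sum(probs) - 1) > tol) {
    stop("component probabilities must sum to 1", call. = FALSE)
  }
  sum(probs * (sds^2 + means^2)) - sum(probs * means)^2
}

sample_skewness <- function(x) {
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  mean((x - m)^3) / s^3
}

#' Predictive simulation audit of a fitted ALDVMM
#'
#' Simulates `n_draws` utilities from the fitted mixture for every
#' observation in the estimation data and compares distributional summaries
#' of the pooled simulated draws with the observed utilities: the
#' proportion exactly at full health, the mean, the variance and the
#' skewness (third standardised central moment, population form). Also
#' summarises the draws by mixture component (share of draws, mean, SD),
#' which is how the per-component plot is built.
#'
#' @param fit An `aldvmm_fit` (or an [aldvmm_params()] plus explicit
#'   designs).
#' @param data The estimation dataset (complete cases).
#' @param n_draws Draws per observation (default 1000).
#' @param seed Integer seed.
#' @return A list of class `simulation_audit` with `summary` (tibble, one
#'   row each for simulated and observed) and `components` (tibble: per-
#'   component draw share, mean, SD).
#' @export
uncertainty_audit <- function(fit, data, n_draws = 1000L, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  d <- build_design(data)
  if (is.null(d$y)) stop("data has no eq5d utility column", call. = FALSE)
  params <- if (inherits(fit, "aldvmm_fit")) fit$params else fit
  bounds <- if (inherits(fit, "aldvmm_fit")) fit$bounds else aldvmm_bounds()
  sim <- simulate_aldvmm(params, d$X, d$Z, n_draws = n_draws, seed = seed,
                         bounds = bounds)
  draws <- as.numeric(sim$draws)
  comp <- as.integer(sim$component)
  obs <- d$y
  summarise_one <- function(x, label) {
    tibble::tibble(
      series = label, n = length(x),
      prop_at_one = mean(x >= bounds$full_health - 1e-9),
      mean = mean(x), variance = stats::var(x) * (length(x) - 1) / length(x),
      skewness = sample_skewness(x)
    )
  }
  comps <- tibble::tibble(component = comp, draw = draws) |>
    dplyr::group_by(.data$component) |>
    dplyr::summarise(share = dplyr::n() / length(draws),
                     mean = mean(.data$draw), sd = stats::sd(.data$draw),
                     .groups = "drop")
  structure(list(
    summary = dplyr::bind_rows(summarise_one(draws, "simulated"),
                               summarise_one(obs, "observed")),
    components = comps,
    n_draws = n_draws, seed = as.integer(seed)
  ), class = "simulation_audit")
}

#' Plot the per-component simulated utility distributions
#'
#' @param object A `simulation_audit` -- but the histogram needs the raw
#'   draws, so this autoplot accepts the output of [simulate_aldvmm()]
#'   attached via `draws`/`component` arguments instead when available.
#' @param draws,component Optional matrices from [simulate_aldvmm()].
#' @param ... Unused.
#' @return A ggplot object (faceted per-component histogram when draws are
#'   supplied, otherwise a component summary bar chart).
#' @export
autoplot.simulation_audit <- function(object, draws = NULL,
                                      component = NULL, ...) {
  if (!is.null(draws) && !is.null(component)) {
    df <- tibble::tibble(draw = as.numeric(draws),
                         component = factor(as.integer(component)))
    return(
      ggplot2::ggplot(df, ggplot2::aes(x = .data$draw)) +
        ggplot2::geom_histogram(bins = 60) +
        ggplot2::facet_wrap(~component, scales = "free_y") +
        ggplot2::labs(x = "Simulated EQ-5D-3L utility", y = "Draws") +
        ggplot2::theme_minimal()
    )
  }
  ggplot2::ggplot(object$components,
                  ggplot2::aes(x = factor(.data$component), y = .data$mean)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.2) +
    ggplot2::labs(x = "Component", y = "Mean simulated utility (+/- SD)") +
    ggplot2::theme_minimal()
}

#' @export
print.simulation_audit <- function(x, ...) {
  cat("Predictive simulation audit (", x$n_draws, "draws/observation)\n")
  print(as.data.frame(x$summary), row.names = FALSE)
  invisible(x)
}
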