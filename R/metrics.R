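#' Prediction accuracy metrics
#'
#' Mean error, mean absolute error and root mean squared error of predicted
#' against observed utilities, plus the two means and the absolute
#' difference of means (the columns of the usual model-comparison table).
#' Errors are `predicted - observed`.
#'
#' @param observed,predicted Equal-length numeric vectors.
#' @return A one-row tibble: `mean_error`, `mae`, `rmse`, `mean_observed`,
#'   `mean_predicted`, `abs_diff_means`.
#' @export
compute_metrics <- function(observed, predicted) {
  if (length(observed) == 0L || length(observed) != length(predicted)) {
    stop("observed and predicted must be equal-length, non-empty",
         call. = FALSE)
  }
  e <- predicted - observed
  tibble::tibble(
    mean_error = mean(e),
    mae = mean(abs(e)),
    rmse = sqrt(mean(e^2)),
    mean_observed = mean(observed),
    mean_predicted = mean(predicted),
    abs_diff_means = abs(mean(predicted) - mean(observed))
  )
}

#' Empirical CDF overlay of observed and predicted utilities
#'
#' Tabulates empirical CDFs of the observed utilities and of each method's
#' predictions on a shared grid, and reports the maximum vertical CDF gap
#' (a Kolmogorov-style statistic) per method. The CDF view is the most
#' informative display of where a mapping model misfits across the
#' severity range.
#'
#' @param observed Numeric vector of observed utilities.
#' @param predictions Named list of numeric prediction vectors (same length
#'   as `observed`), one element per method.
#' @param grid_size Number of grid points.
#' @return A list of class `cdf_overlay`: `curves` (long tibble: `u`,
#'   `series`, `cdf`) and `gaps` (tibble: `method`, `max_gap`).
#' @export
cdf_overlay <- function(observed, predictions, grid_size = 512L) {
  stopifnot(is.list(predictions), length(predictions) > 0L)
  if (is.null(names(predictions)) || any(!nzchar(names(predictions)))) {
    stop("predictions must be a named list", call. = FALSE)
  }
  all_u <- c(observed, unlist(predictions, use.names = FALSE))
  grid <- sort(unique(c(seq(min(all_u), max(all_u),
                            length.out = grid_size), all_u)))
  Fobs <- stats::ecdf(observed)
  curves <- list(tibble::tibble(u = grid, series = "observed",
                                cdf = Fobs(grid)))
  gaps <- list()
  for (m in names(predictions)) {
    Fm <- stats::ecdf(predictions[[m]])
    curves[[length(curves) + 1L]] <-
      tibble::tibble(u = grid, series = m, cdf = Fm(grid))
    gaps[[length(gaps) + 1L]] <-
      tibble::tibble(method = m, max_gap = max(abs(Fm(grid) - Fobs(grid))))
  }
  structure(list(curves = dplyr::bind_rows(curves),
                 gaps = dplyr::bind_rows(gaps)),
            class = "cdf_overlay")
}

#' Plot a CDF overlay
#'
#' @param object A `cdf_overlay`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cdf_overlay <- function(object, ...) {
  ggplot2::ggplot(object$curves,
                  ggplot2::aes(x = .data$u, y = .data$cdf,
                               colour = .data$series)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "EQ-5D-3L utility", y = "Cumulative probability",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Mean observed vs mean predicted utility by global-health severity band
#'
#' Bins the global health score (0-100) into equal-width bins and reports
#' per-bin mean observed and predicted utilities and their difference
#' (`predicted - observed`). This is the diagnostic that exposes the
#' classic linear-mapping bias: over-prediction in the sickest bins and
#' under-prediction in the healthiest.
#'
#' @param observed,predicted Equal-length utility vectors.
#' @param global_health Global health scores on 0-100, same length.
#' @param n_bins Number of equal-width bins (default 10).
#' @return A tibble of class `severity_table`: `bin`, `gh_lo`, `gh_hi`,
#'   `n`, `mean_observed`, `mean_predicted`, `bias`. Empty bins appear with
#'   `n = 0` and missing means.
#' @export
mean_by_severity <- function(observed, predicted, global_health,
                             n_bins = 10L) {
  stopifnot(length(observed) == length(predicted),
            length(observed) == length(global_health))
  breaks <- seq(0, 100, length.out = n_bins + 1L)
  bin <- cut(global_health, breaks = breaks, include.lowest = TRUE,
             labels = FALSE)
  out <- tibble::tibble(
    bin = seq_len(n_bins),
    gh_lo = breaks[-length(breaks)],
    gh_hi = breaks[-1]
  )
  agg <- tibble::tibble(bin = bin, observed = observed,
                        predicted = predicted) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_observed = mean(.data$observed),
                     mean_predicted = mean(.data$predicted),
                     .groups = "drop")
  out <- dplyr::left_join(out, agg, by = "bin") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L),
                  bias = .data$mean_predicted - .data$mean_observed)
  class(out) <- c("severity_table", class(out))
  out
}

#' Plot mean observed vs predicted by severity band
#'
#' @param object A `severity_table` from [mean_by_severity()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.severity_table <- function(object, ...) {
  mid <- (object$gh_lo + object$gh_hi) / 2
  long <- tidyr::pivot_longer(
    dplyr::mutate(object, gh_mid = mid),
    cols = c("mean_observed", "mean_predicted"),
    names_to = "series", values_to = "mean_utility")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$gh_mid,
                                     y = .data$mean_utility,
                                     colour = .data$series)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "Global health status (0-100)",
                  y = "Mean EQ-5D-3L utility", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Model-comparison table across mapping methods
#'
#' Builds the standard comparison table: MAE, RMSE, AIC, BIC, QIC, mean
#' prediction and the absolute difference from the observed mean, one row
#' per fitted method. Information criteria are only reported for mixture
#' models; they are left blank for the linear and response-mapping rows
#' because likelihoods across model families for different dependent
#' variables are not comparable.
#'
#' @param data A complete-case mapping tibble with an `eq5d` column.
#' @param fits Named list of fitted models (`aldvmm_fit`, `response_fit`,
#'   `linear_re_fit` objects, any mix).
#' @return A tibble with one row per method.
#' @export
compare_models <- function(data, fits) {
  d <- build_design(data)
  obs <- d$y
  rows <- purrr::imap(fits, function(f, nm) {
    pred <- stats::predict(f, newdata = data)
    m <- compute_metrics(obs, pred)
    ic_ok <- inherits(f, "aldvmm_fit")
    rep <- if (!is.null(f$report)) f$report else glance(f)
    tibble::tibble(
      method = nm,
      mae = m$mae, rmse = m$rmse,
      aic = if (ic_ok) rep$aic else NA_real_,
      bic = if (ic_ok) rep$bic else NA_real_,
      qic = if (ic_ok) rep$qic else NA_real_,
      mean_predicted = m$mean_predicted,
      abs_diff = m$abs_diff_means,
      mean_error = m$mean_error
    )
  })
  dplyr::bind_rows(rows)
}
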