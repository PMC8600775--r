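#' Write fitted mapping parameters to a plain-text file
#'
#' Serialises a fitted model to JSON so that predictions can be reproduced
#' later (the packaged analogue of a distributable utility calculator). All
#' three model families are supported.
#'
#' @param fit An `aldvmm_fit`, `response_fit` or `linear_re_fit`, or a bare
#'   [aldvmm_params()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_params <- function(fit, path) {
  obj <- if (inherits(fit, "aldvmm_fit")) {
    list(method = "aldvmm",
         x_cols = fit$x_cols, z_cols = fit$z_cols,
         beta = unname(apply(fit$params$beta, 1L, identity,
                             simplify = FALSE)),
         sigma = fit$params$sigma,
         gamma = if (fit$params$K > 1L) {
           unname(apply(fit$params$gamma, 1L, identity, simplify = FALSE))
         } else {
           list()
         },
         bounds = unclass(fit$bounds))
  } else if (inherits(fit, "aldvmm_params")) {
    list(method = "aldvmm", x_cols = NULL, z_cols = NULL,
         beta = unname(apply(fit$beta, 1L, identity, simplify = FALSE)),
         sigma = fit$sigma,
         gamma = if (fit$K > 1L) {
           unname(apply(fit$gamma, 1L, identity, simplify = FALSE))
         } else {
           list()
         },
         bounds = unclass(aldvmm_bounds()))
  } else if (inherits(fit, "response_fit")) {
    list(method = "response",
         x_cols = fit$x_cols,
         dimensions = lapply(fit$dimensions, function(f) {
           list(beta = as.list(f$beta), kappa = as.numeric(f$kappa),
                pinned = f$pinned)
         }),
         correlation = unname(apply(fit$correlation, 1L, identity,
                                    simplify = FALSE)))
  } else if (inherits(fit, "linear_re_fit")) {
    list(method = "linear",
         x_cols = fit$x_cols,
         coefficients = as.list(fit$coefficients),
         sigma_u = fit$sigma_u, sigma_e = fit$sigma_e)
  } else {
    stop("unsupported model object", call. = FALSE)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read fitted mapping parameters from a plain-text file
#'
#' @param path A file written by [write_params()].
#' @return A model object of the matching class, sufficient for prediction
#'   (covariances and fit reports are not serialised).
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path,
                               call. = FALSE)
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
                    stop("malformed parameter file: ", conditionMessage(e),
                         call. = FALSE)
                  })
  if (is.null(obj$method)) stop("malformed parameter file: no method field",
                                call. = FALSE)
  switch(
    obj$method,
    aldvmm = {
      as_mat <- function(x) {
        if (is.matrix(x)) x else if (is.list(x)) {
          do.call(rbind, lapply(x, unlist))
        } else {
          rbind(x)
        }
      }
      beta <- as_mat(obj$beta)
      gamma <- if (length(obj$gamma) > 0) as_mat(obj$gamma) else
        matrix(0, 0L, 0L)
      params <- aldvmm_params(beta, obj$sigma, gamma)
      b <- obj$bounds
      structure(list(params = params, report = NULL, vcov = NULL,
                     bounds = aldvmm_bounds(b$upper, b$floor, b$full_health),
                     x_cols = obj$x_cols, z_cols = obj$z_cols,
                     n_components = params$K, method = "aldvmm"),
                class = "aldvmm_fit")
    },
    response = {
      dims <- lapply(obj$dimensions, function(f) {
        list(beta = unlist(f$beta),
             kappa = stats::setNames(as.numeric(f$kappa),
                                     c("kappa1", "kappa2")),
             vcov = NULL, loglik = NA_real_,
             pinned = if (is.null(f$pinned)) NA_character_ else f$pinned)
      })
      corr <- obj$correlation
      if (is.list(corr)) corr <- do.call(rbind, lapply(corr, unlist))
      corr <- rbind(corr)
      structure(list(dimensions = dims, correlation = corr,
                     x_cols = obj$x_cols, n_obs = 0L, n_clusters = 0L,
                     method = "response"),
                class = "response_fit")
    },
    linear = {
      structure(list(coefficients = unlist(obj$coefficients),
                     sigma_u = obj$sigma_u, sigma_e = obj$sigma_e,
                     vcov = NULL, report = NULL, x_cols = obj$x_cols,
                     method = "linear"),
                class = "linear_re_fit")
    },
    stop("unknown method in parameter file: ", obj$method, call. = FALSE)
  )
}
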