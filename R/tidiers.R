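#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a transfer entropy estimate
#'
#' @param x A `te_result`.
#' @param ... Unused.
#' @return One-row tibble: `method`, `tau`, `te_bits`, and the estimator's
#'   settings.
#' @export
tidy.te_result <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(method = x$method, tau = x$tau, te_bits = x$te_bits),
    tibble::as_tibble(x$params)
  )
}

#' Tidy a surrogate test: one row per surrogate draw
#'
#' @param x A `te_surrogate`.
#' @param ... Unused.
#' @export
tidy.te_surrogate <- function(x, ...) {
  tibble::tibble(surrogate = seq_along(x$te_surrogates),
                 te_bits = x$te_surrogates)
}

#' One-row summary of a surrogate test
#'
#' @param x A `te_surrogate`.
#' @param ... Unused.
#' @export
glance.te_surrogate <- function(x, ...) {
  tibble::tibble(method = x$method, tau = x$tau, te_bits = x$te_original,
                 percentile_95 = x$percentile_95,
                 n_surrogates = length(x$te_surrogates),
                 significant = x$significant)
}

#' Per-lag rows of a lag scan
#'
#' @param x A `te_scan`.
#' @param ... Unused.
#' @export
tidy.te_scan <- function(x, ...) {
  tibble::as_tibble(x)
}

#' One-row summary of a lag scan: the best significant lag
#'
#' @param x A `te_scan`.
#' @param ... Unused.
#' @export
glance.te_scan <- function(x, ...) {
  tibble::tibble(method = attr(x, "method", exact = TRUE),
                 best_tau = attr(x, "best_tau", exact = TRUE),
                 te_bits = attr(x, "best_te", exact = TRUE),
                 n_lags = nrow(x),
                 n_significant = sum(x$significant))
}

#' Per-subject rows of a pre/post study
#'
#' @param x A `prepost_study`.
#' @param ... Unused.
#' @export
tidy.prepost_study <- function(x, ...) x$subjects

#' Group-level summary of a pre/post study
#'
#' @param x A `prepost_study`.
#' @param ... Unused.
#' @export
glance.prepost_study <- function(x, ...) x$groups
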