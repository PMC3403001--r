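#' Ordinal sampling: replace values by their ranks
#'
#' Replaces each value of a series by its rank in the sorted series, the
#' "ordinal sampling" step that makes the counting estimators robust to
#' outliers and exactly invariant under strictly increasing transforms of
#' the data. Ranks run from 1 (smallest) to `N` (largest) and always form a
#' permutation of `1:N`.
#'
#' Ties are broken by occurrence order (a stable sort) so that the output is
#' a true permutation and histogram counts stay integer-exact; set
#' `ties = "random"` (with `seed`) to break ties uniformly at random
#' instead. Tied values are rare in the continuous signals this package
#' targets, so the choice is a convention, not a model assumption.
#'
#' @param x Numeric vector, all values finite.
#' @param ties How to break ties: `"first"` (occurrence order, default) or
#'   `"random"`.
#' @param seed Optional integer seed used only when `ties = "random"`.
#' @return Integer vector of ranks, a permutation of `seq_along(x)`.
#' @examples
#' rank_transform(c(3, 1, 2))
#' rank_transform(c(2, 2, 1)) # tie broken by occurrence order
#' @export
rank_transform <- function(x, ties = c("first", "random"), seed = NULL) {
  ties <- match.arg(ties)
  check_series(x)
  if (ties == "first") {
    r <- rank(x, ties.method = "first")
  } else {
    r <- if (is.null(seed)) {
      rank(x, ties.method = "random")
    } else {
      withr::with_seed(seed, rank(x, ties.method = "random"))
    }
  }
  as.integer(r)
}

check_series <- function(x, arg = deparse(substitute(x))) {
  if (!is.numeric(x) || length(x) < 1L) {
    stop(sprintf("`%s` must be a non-empty numeric vector", arg), call. = FALSE)
  }
  bad <- which(!is.finite(x))
  if (length(bad) > 0L) {
    stop(sprintf("`%s` contains non-finite value(s) at index %s", arg,
                 paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

#' Build the lagged triplet point cloud
#'
#' Assembles the (target, target past, lagged source) triples
#' `(y[i], y[i-1], x[i-tau])` that every estimator consumes. The target past
#' always uses lag one; `tau` lags the source only. With `tau = 0` the
#' source value concurrent with the target is used. The number of usable
#' triples is `P = N - max(tau, 1)`.
#'
#' @param x Source series (numeric or integer ranks), length `N`.
#' @param y Target series, same length as `x`.
#' @param tau Integer source lag, `0 <= tau <= N - 2`.
#' @param ranked Logical flag recording whether the coordinates are ranks of
#'   whole series; stored as an attribute and checked by the estimators.
#' @return A tibble of class `te_triplets` with columns `target`,
#'   `target_past`, `source_past` and attributes `tau`, `ranked`,
#'   `n_source` (the original series length `N`, which for ranked input is
#'   also the upper end of the rank range).
#' @examples
#' build_triplets(1:4, 5:8, tau = 1)
#' @export
build_triplets <- function(x, y, tau, ranked = FALSE) {
  check_series(x)
  check_series(y)
  n <- length(x)
  if (length(y) != n) {
    stop(sprintf("`x` and `y` must have equal length (got %d and %d)",
                 n, length(y)), call. = FALSE)
  }
  tau <- as.integer(tau)
  if (length(tau) != 1L || is.na(tau) || tau < 0L || tau > n - 2L) {
    stop(sprintf("`tau` must satisfy 0 <= tau <= N - 2 = %d", n - 2L),
         call. = FALSE)
  }
  start <- max(tau, 1L) + 1L  # first index i for which y[i-1] and x[i-tau] exist
  i <- start:n
  out <- tibble::tibble(
    target      = y[i],
    target_past = y[i - 1L],
    source_past = x[i - tau]
  )
  structure(out,
            class = c("te_triplets", class(out)),
            tau = tau, ranked = isTRUE(ranked), n_source = n)
}

triplet_attr <- function(triplets, what) attr(triplets, what, exact = TRUE)

assert_triplets <- function(triplets, ranked = NULL) {
  if (!inherits(triplets, "te_triplets")) {
    stop("expected a `te_triplets` object from build_triplets()", call. = FALSE)
  }
  if (!is.null(ranked)) {
    is_ranked <- isTRUE(triplet_attr(triplets, "ranked"))
    if (ranked && !is_ranked) {
      stop("this estimator requires rank-transformed (ordinal) input; ",
           "rank series with rank_transform() first", call. = FALSE)
    }
    if (!ranked && is_ranked) {
      stop("this estimator requires raw (unranked) coordinates: ",
           "distance is meaningful only on the original scale", call. = FALSE)
    }
  }
  invisible(triplets)
}
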