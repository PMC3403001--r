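#' Temporally shuffled surrogate of a source series
#'
#' Returns a uniform random permutation of the source values. Shuffling
#' destroys the temporal structure linking the source to the target while
#' preserving the source's marginal distribution exactly, so repeated
#' shuffles give the null distribution of transfer entropy under "no
#' directed coupling". Only the source is ever shuffled; the target keeps
#' its autocorrelation.
#'
#' @param x Numeric vector, length >= 2.
#' @param seed Optional integer seed for reproducibility.
#' @return A permutation of `x`.
#' @export
shuffle_surrogate <- function(x, seed = NULL) {
  check_series(x)
  if (length(x) < 2L) stop("need at least 2 values to shuffle", call. = FALSE)
  if (is.null(seed)) sample(x) else withr::with_seed(seed, sample(x))
}

#' Surrogate-data significance test for directed coupling
#'
#' Computes the transfer entropy from `x` to `y` at lag `tau`, then
#' recomputes it for `n_surrogates` independently shuffled copies of the
#' source. The coupling is deemed significant when the original estimate
#' exceeds the empirical 95th percentile of the surrogate values
#' (percentile by linear interpolation between order statistics,
#' `stats::quantile()` type 7; with 100 surrogates this is essentially
#' "larger than the 95th largest").
#'
#' @inheritParams estimate_te
#' @param n_surrogates Number of shuffled surrogates (>= 20).
#' @param seed Integer seed; all shuffles derive from it.
#' @return A list of class `te_surrogate`: `te_original`, `te_surrogates`,
#'   `percentile_95`, `significant`, plus `method`, `tau`, `seed`.
#' @export
surrogate_test <- function(x, y, tau, method = c("fixed_bin", "kde", "dv"),
                           Q = 5L, alpha = 1, dv_level = 0.05,
                           n_surrogates = 100L, seed = NULL) {
  method <- match.arg(method)
  if (n_surrogates < 20L) {
    stop("`n_surrogates` must be at least 20 for a usable 95th percentile",
         call. = FALSE)
  }
  check_series(x)
  check_series(y)
  n <- length(x)
  stopifnot(length(y) == n)
  tau <- as.integer(tau)
  i_t <- (max(tau, 1L) + 1L):n   # triplet target indices
  i_s <- i_t - tau

  # per-surrogate estimator over a shuffled source, with everything that
  # does not depend on the source precomputed once
  if (method == "kde") {
    trip <- build_triplets(x, y, tau, ranked = FALSE)
    Kt <- kde_kernel_matrix(trip$target, alpha)
    Ktp <- kde_kernel_matrix(trip$target_past, alpha)
    te0 <- kde_core(trip$target, trip$target_past, trip$source_past,
                    alpha, Kt, Ktp)
    est <- function(src_full) {
      kde_core(trip$target, trip$target_past, src_full[i_s], alpha, Kt, Ktp)
    }
    draw <- function() sample(x)
  } else {
    # shuffling the raw source then ranking equals shuffling its ranks
    u <- rank_transform(x)
    v <- rank_transform(y)
    tgt <- v[i_t]
    tp <- v[i_t - 1L]
    if (method == "fixed_bin") {
      edges <- seq(1, n, length.out = Q + 1L)
      bin <- function(w) findInterval(w, edges, rightmost.closed = TRUE,
                                      all.inside = TRUE)
      a_bin <- bin(tgt)
      b_bin <- bin(tp)
      u_bin <- bin(u)
      te0 <- fb_core_binned(a_bin, b_bin, u_bin[i_s], Q)
      est <- function(su) fb_core_binned(a_bin, b_bin, su[i_s], Q)
      draw <- function() sample(u_bin)
    } else {
      te0 <- dv_core(tgt, tp, u[i_s], n, significance = dv_level)
      est <- function(su) dv_core(tgt, tp, su[i_s], n,
                                  significance = dv_level)
      draw <- function() sample(u)
    }
  }
  run <- function() vapply(seq_len(n_surrogates), function(s) est(draw()),
                           numeric(1))
  te_sur <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  p95 <- unname(stats::quantile(te_sur, 0.95, type = 7))
  structure(
    list(te_original = te0, te_surrogates = te_sur, percentile_95 = p95,
         significant = te0 > p95, method = method, tau = as.integer(tau),
         seed = seed),
    class = "te_surrogate"
  )
}

#' @export
print.te_surrogate <- function(x, ...) {
  cat(sprintf(
    "Surrogate test (%s, tau = %d): TE = %.4f bits, 95th pct of %d surrogates = %.4f -> %s\n",
    x$method, x$tau, x$te_original, length(x$te_surrogates),
    x$percentile_95, if (x$significant) "significant" else "not significant"))
  invisible(x)
}

#' Scan source lags and locate the strongest significant coupling
#'
#' Runs [surrogate_test()] at each lag in `tau_range` and reports the lag
#' with the largest transfer entropy among those that pass the surrogate
#' test (`best_tau`), or `NA` when no lag is significant — in a screening
#' pipeline such a pair is dropped from further analysis. Surrogates are
#' shuffled independently at each lag, using a per-lag seed stream derived
#' from `seed`. No multiple-testing correction is applied across lags;
#' treat per-lag significance accordingly.
#'
#' @inheritParams surrogate_test
#' @param tau_range Integer vector of lags to scan (default `1:5`).
#' @return A tibble of class `te_scan` with one row per lag (`tau`,
#'   `te_bits`, `percentile_95`, `significant`) and attributes `best_tau`,
#'   `best_te` and `method`.
#' @export
scan_lags <- function(x, y, tau_range = 1:5,
                      method = c("fixed_bin", "kde", "dv"),
                      Q = 5L, alpha = 1, dv_level = 0.05,
                      n_surrogates = 100L, seed = NULL) {
  method <- match.arg(method)
  if (length(tau_range) < 1L) stop("`tau_range` is empty", call. = FALSE)
  rows <- purrr::map(seq_along(tau_range), function(k) {
    tau <- tau_range[[k]]
    lag_seed <- if (is.null(seed)) NULL else derive_seed(seed, 7L, tau)
    st <- surrogate_test(x, y, tau, method = method, Q = Q, alpha = alpha,
                         dv_level = dv_level, n_surrogates = n_surrogates,
                         seed = lag_seed)
    tibble::tibble(tau = as.integer(tau), te_bits = st$te_original,
                   percentile_95 = st$percentile_95,
                   significant = st$significant)
  })
  out <- dplyr::bind_rows(rows)
  sig <- dplyr::filter(out, .data$significant)
  best_tau <- if (nrow(sig)) sig$tau[[which.max(sig$te_bits)]] else NA_integer_
  best_te <- if (nrow(sig)) max(sig$te_bits) else NA_real_
  structure(out, class = c("te_scan", class(out)),
            best_tau = best_tau, best_te = best_te, method = method,
            seed = seed)
}

#' One-sided rank-sum comparison of two transfer entropy samples
#'
#' Wilcoxon rank-sum (Mann-Whitney) test of the alternative that `te_high`
#' is stochastically larger than `te_low`. Used to decide whether transfer
#' entropy increased between two conditions (e.g. adjacent SNR levels).
#' Completely tied degenerate samples return p = 0.5 with a warning.
#'
#' @param te_low,te_high Numeric samples of TE values (bits).
#' @return The one-sided p-value.
#' @export
compare_unpaired <- function(te_low, te_high) {
  stopifnot(length(te_low) >= 1L, length(te_high) >= 1L)
  if (length(unique(c(te_low, te_high))) == 1L) {
    warning("all values tied; returning p = 0.5")
    return(0.5)
  }
  stats::wilcox.test(te_high, te_low, alternative = "greater",
                     exact = NULL)$p.value
}

#' One-sided signed-rank comparison of paired transfer entropies
#'
#' Wilcoxon signed-rank test of the alternative that the post-condition
#' transfer entropy exceeds the pre-condition value, pairing by subject.
#' Subjects whose coupling fails the surrogate screen should be excluded
#' before calling this.
#'
#' @param te_pre,te_post Equal-length numeric vectors, paired by subject.
#' @return The one-sided p-value.
#' @export
compare_paired <- function(te_pre, te_post) {
  if (length(te_pre) != length(te_post)) {
    stop("`te_pre` and `te_post` must be paired (equal length)",
         call. = FALSE)
  }
  if (length(te_pre) < 4L) {
    stop("signed-rank test needs at least 4 pairs", call. = FALSE)
  }
  if (all(te_post == te_pre)) {
    warning("all pairs tied; returning p = 0.5")
    return(0.5)
  }
  stats::wilcox.test(te_post, te_pre, paired = TRUE,
                     alternative = "greater", exact = NULL)$p.value
}

# deterministic mixing of small integers into a seed < 2^31; the 69069
# multiplier keeps every intermediate below 2^53, so this is exact in
# double arithmetic
derive_seed <- function(...) {
  parts <- c(...)
  h <- 2166136261 %% 2147483647
  for (p in parts) {
    h <- (h * 69069 + as.numeric(p) %% 2147483647) %% 2147483647
  }
  as.integer(h %% 2147483629 + 1)
}
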