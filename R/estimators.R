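#' Point estimators for a two-sample mark-recapture experiment
#'
#' A two-sample mark-recapture experiment on a stream reach yields an outcome
#' triple: `m` fish caught, marked and released in sample 1, `c_prime` fish
#' caught in sample 2, of which `r_prime` carry marks. `mrr_estimate()` is the
#' classical mark-recapture ratio (MRR) estimator `c'm/r'`, which is undefined
#' when no marked fish are recaptured. `chapman_estimate()` is Chapman's
#' modification `(m+1)(c'+1)/(r'+1) - 1`, defined (with finite moments) for
#' every possible outcome.
#'
#' All three arguments are recycled to a common length, so outcome columns of
#' a data frame can be passed directly.
#'
#' @param m Integer count of fish caught and marked in sample 1.
#' @param c_prime Integer count of fish caught in sample 2.
#' @param r_prime Integer count of marked fish among the sample-2 catch.
#'   Must satisfy `r_prime <= m` and `r_prime <= c_prime`.
#'
#' @return A numeric vector of abundance estimates. `mrr_estimate()` returns
#'   `NA` (the undefined flag, not an error) wherever `r_prime == 0`;
#'   `chapman_estimate()` is always finite.
#'
#' @examples
#' mrr_estimate(100, 150, 50)     # Dahl's trout tarn: 300
#' chapman_estimate(100, 150, 50) # 298.04
#' mrr_estimate(3, 4, 0)          # no recaptures: NA
#' chapman_estimate(3, 4, 0)      # still defined: 19
#' @export
mrr_estimate <- function(m, c_prime, r_prime) {
  check_outcome(m, c_prime, r_prime)
  out <- c_prime * m / r_prime
  out[r_prime == 0] <- NA_real_
  out
}

#' @rdname mrr_estimate
#' @export
chapman_estimate <- function(m, c_prime, r_prime) {
  check_outcome(m, c_prime, r_prime)
  (m + 1) * (c_prime + 1) / (r_prime + 1) - 1
}

check_outcome <- function(m, c_prime, r_prime) {
  if (any(m < 0 | c_prime < 0 | r_prime < 0, na.rm = TRUE)) {
    stop("outcome counts must be nonnegative", call. = FALSE)
  }
  if (any(m != round(m) | c_prime != round(c_prime) | r_prime != round(r_prime))) {
    stop("outcome counts must be integers", call. = FALSE)
  }
  if (any(r_prime > m | r_prime > c_prime)) {
    stop("recaptures r_prime cannot exceed m or c_prime", call. = FALSE)
  }
  invisible(TRUE)
}

#' Estimate abundance for a table of mark-recapture outcomes
#'
#' Data-frame-first wrapper around [mrr_estimate()] and [chapman_estimate()]:
#' takes a data frame with columns `m`, `c_prime`, `r_prime` (one row per
#' experiment) and appends both estimates.
#'
#' @param data A data frame with integer columns `m`, `c_prime`, `r_prime`.
#'
#' @return A tibble: the input columns plus `mrr` (`NA` when undefined),
#'   `mrr_defined`, and `chapman`.
#'
#' @examples
#' outcomes <- tibble::tibble(m = c(100, 3), c_prime = c(150, 4), r_prime = c(50, 0))
#' estimate_abundance(outcomes)
#' @export
estimate_abundance <- function(data) {
  stopifnot(all(c("m", "c_prime", "r_prime") %in% names(data)))
  tibble::as_tibble(data) |>
    dplyr::mutate(
      mrr = mrr_estimate(.data$m, .data$c_prime, .data$r_prime),
      mrr_defined = .data$r_prime > 0,
      chapman = chapman_estimate(.data$m, .data$c_prime, .data$r_prime)
    )
}

#' Maximum-likelihood estimates of abundance and capture probabilities
#'
#' Viewing the outcome `(m, c_prime, r_prime)` as data under the multinomial
#' capture-history model (see [outcome_pmf()]), the maximum-likelihood
#' estimators are `n_hat = c'm/r'`, `q_hat = r'/c'` (sample-1 capture
#' probability) and `q_prime_hat = r'/m` (sample-2 capture probability).
#' These satisfy the identities `q_hat = m/n_hat` and `q_prime_hat = c'/n_hat`.
#'
#' @inheritParams mrr_estimate
#'
#' @return A tibble with columns `m`, `c_prime`, `r_prime`, `n_hat`, `q_hat`,
#'   `q_prime_hat`. Rows with a zero denominator (`r_prime`, `m` or `c_prime`
#'   equal to 0) are flagged with `NA` estimates rather than an error.
#'
#' @examples
#' capture_mle(100, 150, 50) # n_hat 300, q_hat 1/3, q_prime_hat 1/2
#' @export
capture_mle <- function(m, c_prime, r_prime) {
  check_outcome(m, c_prime, r_prime)
  len <- max(length(m), length(c_prime), length(r_prime))
  m <- rep_len(m, len); c_prime <- rep_len(c_prime, len)
  r_prime <- rep_len(r_prime, len)
  ok <- r_prime > 0 & m > 0 & c_prime > 0
  tibble::tibble(
    m = m, c_prime = c_prime, r_prime = r_prime,
    n_hat = ifelse(ok, c_prime * m / r_prime, NA_real_),
    q_hat = ifelse(ok, r_prime / c_prime, NA_real_),
    q_prime_hat = ifelse(ok, r_prime / m, NA_real_)
  )
}

#' Multinomial probability of a mark-recapture outcome
#'
#' Under spatial closure each of the `n` fish falls in one of four capture
#' histories, with cell probabilities `pi_11 = qq'`, `pi_10 = q(1-q')`,
#' `pi_01 = (1-q)q'`, `pi_00 = (1-q)(1-q')`. The probability of observing the
#' outcome `(m, c_prime, r_prime)` is the multinomial pmf over those cells,
#' positive if and only if the number of distinct fish handled,
#' `k' = m + c_prime - r_prime`, does not exceed `n`.
#'
#' Outcomes violating the constitutive constraints (`m <= n`,
#' `r_prime <= c_prime <= n`, `r_prime <= m`, `k' <= n`) get probability 0,
#' not an error, so grid sweeps over outcomes need no special casing.
#'
#' @param n True abundance (nonnegative integer).
#' @param q,q_prime Capture probabilities for samples 1 and 2, in (0, 1).
#' @inheritParams mrr_estimate
#'
#' @return Numeric vector of probabilities in `[0, 1]`.
#'
#' @examples
#' outcome_pmf(1, 0.5, 0.5, m = 1, c_prime = 1, r_prime = 1) # qq' = 0.25
#' @export
outcome_pmf <- function(n, q, q_prime, m, c_prime, r_prime) {
  stopifnot(n >= 0, n == round(n), q > 0, q < 1, q_prime > 0, q_prime < 1)
  len <- max(length(m), length(c_prime), length(r_prime))
  m <- rep_len(m, len); c_prime <- rep_len(c_prime, len)
  r_prime <- rep_len(r_prime, len)
  k <- m + c_prime - r_prime
  ok <- m >= 0 & c_prime >= 0 & r_prime >= 0 &
    m <= n & c_prime <= n & r_prime <= pmin(m, c_prime) & k <= n
  log_cells <- log(c(q * q_prime, q * (1 - q_prime), (1 - q) * q_prime,
                     (1 - q) * (1 - q_prime)))
  out <- numeric(len)
  mi <- m[ok]; ci <- c_prime[ok]; ri <- r_prime[ok]; ki <- k[ok]
  lp <- lgamma(n + 1) - lgamma(ri + 1) - lgamma(mi - ri + 1) -
    lgamma(ci - ri + 1) - lgamma(n - ki + 1) +
    ri * log_cells[1] + (mi - ri) * log_cells[2] +
    (ci - ri) * log_cells[3] + (n - ki) * log_cells[4]
  out[ok] <- exp(lp)
  out
}

#' Enumerate all admissible outcomes of a closed two-sample experiment
#'
#' Returns every triple `(m, c_prime, r_prime)` with positive probability for
#' a closed reach of abundance `n`, together with its multinomial probability
#' and Chapman estimate. Useful for exact expectations at small `n`.
#'
#' @inheritParams outcome_pmf
#'
#' @return A tibble with columns `m`, `c_prime`, `r_prime`, `prob`, `chapman`.
#' @examples
#' d <- outcome_distribution(4, 0.3, 0.6)
#' sum(d$prob) # 1
#' @export
outcome_distribution <- function(n, q, q_prime) {
  grid <- tidyr::expand_grid(m = 0:n, c_prime = 0:n, r_prime = 0:n) |>
    dplyr::filter(.data$r_prime <= pmin(.data$m, .data$c_prime),
                  .data$m + .data$c_prime - .data$r_prime <= n)
  grid |>
    dplyr::mutate(
      prob = outcome_pmf(n, q, q_prime, .data$m, .data$c_prime, .data$r_prime),
      chapman = chapman_estimate(.data$m, .data$c_prime, .data$r_prime)
    )
}

#' Conditional mean of Chapman's estimator given the sample sizes
#'
#' Conditioning on observed `m` and `c_prime`, the only randomness left is the
#' number of recaptures, which is hypergeometric. The conditional expectation
#' of Chapman's estimator has the closed form: `n` when `c_prime >= n - m`,
#' and `n - (n-m)!(n-c')! / [n!(n-m-c'-1)!]` otherwise, so the conditional
#' bias is never positive. Factorials are evaluated in the log-gamma domain,
#' accurate to about 1e-9 relative for `n` up to 1e4.
#'
#' @param n True abundance.
#' @param m,c_prime Observed sample-1 and sample-2 catch counts, each `<= n`.
#'
#' @return Numeric vector of conditional expected values, always `<= n`.
#'
#' @examples
#' conditional_chapman_mean(10, 6, 5) # census branch: 10
#' conditional_chapman_mean(10, 3, 3) # 8.8333...
#' @export
conditional_chapman_mean <- function(n, m, c_prime) {
  len <- max(length(n), length(m), length(c_prime))
  n <- rep_len(n, len); m <- rep_len(m, len); c_prime <- rep_len(c_prime, len)
  stopifnot(m >= 0, m <= n, c_prime >= 0, c_prime <= n)
  out <- numeric(len)
  full <- c_prime >= n - m
  out[full] <- n[full]
  i <- !full
  deficit <- exp(lgamma(n[i] - m[i] + 1) + lgamma(n[i] - c_prime[i] + 1) -
                   lgamma(n[i] + 1) - lgamma(n[i] - m[i] - c_prime[i]))
  out[i] <- n[i] - deficit
  out
}
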