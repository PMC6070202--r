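#' Exact moments and bias of Chapman's estimator
#'
#' Unconditional expected value and relative biases of Chapman's estimator
#' `N* = (M+1)(C'+1)/(R'+1) - 1` for three sampling situations, each exact for
#' any abundance (no large-sample approximation):
#'
#' * `closed_moments()` — a spatially closed reach of abundance `n` sampled
#'   twice with capture probabilities `q`, `q_prime`. The expectation is
#'   `n - (1-q)(1-q')n (1-qq')^(n-1)`, always below `n`.
#' * `standard_moments()` — the standard scheme on a reach open to dispersal:
#'   each of the `n` fish present at sample 1 exits before sample 2 with
#'   probability `p`, and on average `i_tilde` unmarked immigrants are present
#'   at sample 2. Expected sample-2 abundance is `E(N') = n(1-p) + i_tilde`.
#' * `modified_moments()` — the modified expanded-reach scheme: the reach is
#'   split into zones U, C, D; sample 1 marks only in the central zone C (with
#'   capture probability `q`), sample 2 covers the whole reach (probability
#'   `q_prime`). Each fish in zone j exits the whole reach with probability
#'   `p_j`; immigration mean is `i_tilde`.
#'
#' Every expectation has the geometric form `omega - phi * lam^(x-1)` with
#' `0 < lam < 1` and `x = n` (closed, standard) or `x = n_c` (modified), so
#' the sampling-variation term `phi * lam^(x-1)` vanishes geometrically as
#' abundance grows and `omega` is the large-population limit. The power is
#' computed as `exp((x-1) log lam)` and stays stable for `x` up to about 1e6.
#'
#' `modified_moments()` reduces exactly to `standard_moments()` when
#' `n_u = n_d = 0`, `n_c = n`, `p_c = p`, and `standard_moments()` reduces
#' exactly to `closed_moments()` when `p = 0` and `i_tilde = 0`.
#'
#' All arguments are vectorized (recycled to a common length); one row is
#' returned per design.
#'
#' @param n True reach abundance at sample 1 (positive integer).
#' @param q,q_prime Capture probabilities for samples 1 and 2, in (0, 1).
#'   For the modified scheme `q` applies to zone C at sample 1 and `q_prime`
#'   to the whole reach at sample 2.
#' @param p Exit probability between samples, in `[0, 1)`.
#' @param i_tilde Mean number of immigrants present at sample 2 (`>= 0`).
#' @param n_u,n_c,n_d Zone abundances at sample 1 (nonnegative; `n_c >= 1`).
#' @param p_u,p_c,p_d Per-zone probabilities of exiting the whole study reach,
#'   each in `[0, 1)`.
#'
#' @return A tibble with one row per design and columns `scheme`, `n`
#'   (study-reach abundance at sample 1), `omega`, `phi`, `lam` (the geometric
#'   decomposition), `geom_term` (the sampling-variation term
#'   `phi * lam^(x-1)`), `expected_value` (`E(N*)`), `expected_n2` (`E(N')`),
#'   `rel_bias_n` (`[E(N*) - n]/n`) and `rel_bias_en2`
#'   (`[E(N*) - E(N')]/E(N')`), both as fractions (multiply by 100 for
#'   percent).
#'
#' @examples
#' closed_moments(100, 0.1, 0.1)$rel_bias_n    # about -0.30
#' standard_moments(150, 0.1, 0.1, p = 0.1 / 3, i_tilde = 5)
#' modified_moments(50, 50, 50, q = 1 - 0.9^3, q_prime = 0.1,
#'                  p_u = 0.05, p_c = 0, p_d = 0.05, i_tilde = 5)
#' @export
closed_moments <- function(n, q, q_prime) {
  check_prob(q, "q"); check_prob(q_prime, "q_prime")
  stopifnot(n >= 1, n == round(n))
  omega <- n
  phi <- (1 - q) * (1 - q_prime) * n
  lam <- 1 - q * q_prime
  moment_tibble("closed", n, omega, phi, lam,
                geom_term = phi * geom_pow(lam, n - 1), expected_n2 = n)
}

#' @rdname closed_moments
#' @export
standard_moments <- function(n, q, q_prime, p, i_tilde) {
  check_prob(q, "q"); check_prob(q_prime, "q_prime")
  if (any(p < 0 | p >= 1)) stop("exit probability p must lie in [0, 1)", call. = FALSE)
  if (any(i_tilde < 0)) stop("i_tilde must be nonnegative", call. = FALSE)
  stopifnot(n >= 1, n == round(n))
  s <- 1 - p                      # staying probability
  omega <- n + i_tilde / s
  lam <- 1 - q * q_prime * s
  phi <- (omega * (1 - q * q_prime * s) - n * q * (1 - q_prime * s)) *
    (1 - q_prime * s)
  moment_tibble("standard", n, omega, phi, lam,
                geom_term = phi * geom_pow(lam, n - 1),
                expected_n2 = n * s + i_tilde)
}

#' @rdname closed_moments
#' @export
modified_moments <- function(n_u, n_c, n_d, q, q_prime, p_u, p_c, p_d, i_tilde) {
  check_prob(q, "q"); check_prob(q_prime, "q_prime")
  if (any(n_u < 0 | n_c < 0 | n_d < 0)) {
    stop("zone abundances must be nonnegative", call. = FALSE)
  }
  stopifnot(n_c >= 1, n_c == round(n_c))
  for (pp in list(p_u, p_c, p_d)) {
    if (any(pp < 0 | pp >= 1)) stop("zone exit probabilities must lie in [0, 1)", call. = FALSE)
  }
  if (any(i_tilde < 0)) stop("i_tilde must be nonnegative", call. = FALSE)
  n <- n_u + n_c + n_d
  p_tilde <- (n_u * p_u + n_c * p_c + n_d * p_d) / n
  en2 <- n * (1 - p_tilde) + i_tilde
  s <- 1 - p_c
  omega <- en2 / s
  lam <- 1 - q * q_prime * s
  phi <- (omega * (1 - q * q_prime * s) - n_c * q * (1 - q_prime * s)) *
    (1 - q_prime * s)
  moment_tibble("modified", n, omega, phi, lam,
                geom_term = phi * geom_pow(lam, n_c - 1), expected_n2 = en2)
}

#' Bias of Chapman's estimator with respect to total population size
#'
#' Recasts the dispersal designs in terms of a closed total population spread
#' over the study reach and the reaches upstream (US) and downstream (DS) of
#' it. Each fish in location j at sample 1 is in the study reach at sample 2
#' with a transfer probability `p_{j,S}`; immigration mean becomes
#' `i_tilde = n_us * p_us_s + n_ds * p_ds_s` and the moment formulas carry
#' over with the staying probability replaced by the study-reach (or zone-C)
#' transfer probability.
#'
#' The asymptotic sign of the bias with respect to `n_T = n + n_us + n_ds`
#' is the sign of `omega - n_T`: negative for all abundances whenever
#' `omega <= n_T` (in particular when the in-reach transfer probability
#' exceeds all outside ones), positive for sufficiently large `n` when
#' `omega > n_T`, and vanishing when all transfer probabilities are equal
#' (`omega = n_T`, thorough mixing).
#'
#' @param scheme `"standard"` or `"modified"`.
#' @param n Study-reach abundance at sample 1 (standard scheme).
#' @param n_us,n_ds Abundances upstream/downstream of the study reach.
#' @param q,q_prime Capture probabilities (see [closed_moments()]).
#' @param p_s_s Probability a study-reach fish is in the reach at sample 2
#'   (standard scheme; equals `1 - p`).
#' @param p_us_s,p_ds_s Transfer probabilities from the outside reaches into
#'   the study reach, each in `[0, 1)`.
#' @param n_u,n_c,n_d Zone abundances (modified scheme).
#' @param p_u_s,p_c_s,p_d_s Per-zone probabilities of remaining in the study
#'   reach at sample 2 (modified scheme).
#'
#' @return The [closed_moments()] tibble plus `n_t`, `rel_bias_nt`
#'   (`[E(N*) - n_T]/n_T`) and `asymptotic_sign_nt` (-1, 0 or 1, the sign of
#'   `omega - n_T`, i.e. of the large-`n` bias with respect to `n_T`).
#'
#' @examples
#' # thorough mixing: all transfer probabilities equal, bias vanishes at large n
#' total_population_moments("standard", n = 100, n_us = 50, n_ds = 50,
#'                          q = 0.5, q_prime = 0.5,
#'                          p_s_s = 0.6, p_us_s = 0.6, p_ds_s = 0.6)
#' @export
total_population_moments <- function(scheme = c("standard", "modified"),
                                     n = NULL, n_us, n_ds, q, q_prime,
                                     p_s_s = NULL, p_us_s, p_ds_s,
                                     n_u = NULL, n_c = NULL, n_d = NULL,
                                     p_u_s = NULL, p_c_s = NULL, p_d_s = NULL) {
  scheme <- match.arg(scheme)
  if (any(p_us_s < 0 | p_us_s >= 1) || any(p_ds_s < 0 | p_ds_s >= 1)) {
    stop("outside transfer probabilities must lie in [0, 1)", call. = FALSE)
  }
  i_tilde <- n_us * p_us_s + n_ds * p_ds_s
  if (scheme == "standard") {
    stopifnot(!is.null(n), !is.null(p_s_s), p_s_s > 0, p_s_s <= 1)
    res <- standard_moments(n, q, q_prime, p = 1 - p_s_s, i_tilde = i_tilde)
  } else {
    stopifnot(!is.null(n_u), !is.null(n_c), !is.null(n_d),
              !is.null(p_u_s), !is.null(p_c_s), !is.null(p_d_s),
              p_c_s > 0, p_c_s <= 1)
    n <- n_u + n_c + n_d
    res <- modified_moments(n_u, n_c, n_d, q, q_prime,
                            p_u = 1 - p_u_s, p_c = 1 - p_c_s, p_d = 1 - p_d_s,
                            i_tilde = i_tilde)
  }
  n_t <- n + n_us + n_ds
  res |>
    dplyr::mutate(
      n_t = n_t,
      rel_bias_nt = ((.data$omega - n_t) - .data$geom_term) / n_t,
      asymptotic_sign_nt = sign_zero(.data$omega - n_t)
    )
}

#' Exact expectation of Chapman's estimator by exhaustive enumeration
#'
#' Independent verification oracle for the closed-form moment expressions.
#' The generative model is enumerated exactly: sample-1 captures in zone C
#' are binomial, each fish exits (the whole study reach) with its zone's exit
#' probability, a fixed (degenerate) number of unmarked immigrants is present
#' at sample 2, and sample-2 captures are Bernoulli for every fish present.
#' The expectation of Chapman's estimator is accumulated over the exact joint
#' distribution of the sufficient counts (marked, recaptured, unmarked and
#' immigrant captures), with the unmarked-capture distribution obtained by
#' convolving the per-zone binomial pmfs. No large-sample or continuity
#' approximation is involved.
#'
#' With `n_u = n_d = 0` and `p_c = p` this is the standard-scheme model; with
#' additionally `p = 0`, `n_immigrants = 0` it is the closed model. Because
#' Chapman's estimator is linear in the sample-2 catch given the marked and
#' recaptured counts, the expectation depends on the immigrant distribution
#' only through its mean, so the degenerate immigrant count loses no
#' generality for first moments.
#'
#' @inheritParams closed_moments
#' @param n_immigrants Fixed immigrant count (so `i_tilde = n_immigrants`).
#' @param max_total Enumeration feasibility bound on the total number of
#'   individuals (default 12); larger problems are refused.
#'
#' @return The exact expected value of Chapman's estimator (scalar).
#'
#' @examples
#' chapman_expectation_exact(n_c = 3, q = 0.5, q_prime = 0.5)
#' closed_moments(3, 0.5, 0.5)$expected_value # identical
#' @export
chapman_expectation_exact <- function(n_c, q, q_prime, n_u = 0, n_d = 0,
                                      p_u = 0, p_c = 0, p_d = 0,
                                      n_immigrants = 0, max_total = 12) {
  total <- n_u + n_c + n_d + n_immigrants
  if (total > max_total) {
    stop("enumeration refused: ", total, " individuals exceeds the bound of ",
         max_total, call. = FALSE)
  }
  check_prob(q, "q"); check_prob(q_prime, "q_prime")
  expectation <- 0
  for (m in 0:n_c) {
    p_m <- dbinom(m, n_c, q)
    # unmarked fish captured in sample 2: convolution over zones + immigrants
    d_unmarked <- Reduce(
      convolve_pmf,
      list(dbinom(0:n_u, n_u, (1 - p_u) * q_prime),
           dbinom(0:(n_c - m), n_c - m, (1 - p_c) * q_prime),
           dbinom(0:n_d, n_d, (1 - p_d) * q_prime),
           dbinom(0:n_immigrants, n_immigrants, q_prime))
    )
    for (r in 0:m) {
      p_r <- dbinom(r, m, (1 - p_c) * q_prime)
      u <- seq_along(d_unmarked) - 1
      est <- (m + 1) * (r + u + 1) / (r + 1) - 1
      expectation <- expectation + p_m * p_r * sum(d_unmarked * est)
    }
  }
  expectation
}

# exact pmf convolution of two nonnegative-count distributions
convolve_pmf <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1)
  for (i in seq_along(a)) {
    idx <- i:(i + length(b) - 1)
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

geom_pow <- function(lam, k) exp(k * log(lam))

sign_zero <- function(x, tol = 1e-9) {
  out <- sign(x)
  out[abs(x) <= tol] <- 0
  out
}

check_prob <- function(x, name) {
  if (any(x <= 0 | x >= 1)) {
    stop(name, " must lie strictly between 0 and 1", call. = FALSE)
  }
  invisible(TRUE)
}

# relative biases are assembled from (omega - benchmark) and the geometric
# sampling-variation term separately: forming expected_value first and
# subtracting the benchmark would cancel catastrophically once the geometric
# term falls below machine precision relative to n
moment_tibble <- function(scheme, n, omega, phi, lam, geom_term, expected_n2) {
  tibble::tibble(
    scheme = scheme, n = n, omega = omega, phi = phi, lam = lam,
    geom_term = geom_term,
    expected_value = omega - geom_term,
    expected_n2 = expected_n2,
    rel_bias_n = ((omega - n) - geom_term) / n,
    rel_bias_en2 = ((omega - expected_n2) - geom_term) / expected_n2
  )
}
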