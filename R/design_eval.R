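#' Capture probability as a function of sampling effort
#'
#' With active sampling (e.g. electrofishing) at constant search rate and
#' capture efficiency, the capture probability after sampling a habitat of
#' size `V` for duration `T` is `q(T) = 1 - exp(-alpha r T / V)`: increasing
#' in effort, decreasing in habitat size.
#'
#' @param alpha Capture efficiency (proportion of encountered fish caught).
#' @param search_rate Area or volume searched per unit time.
#' @param duration Sampling duration.
#' @param habitat_size Area or volume of the sampled zone or reach.
#'
#' @return Capture probability in (0, 1).
#' @examples
#' capture_probability_from_effort(0.5, 10, log(2) / 5, 1) # 0.5
#' @export
capture_probability_from_effort <- function(alpha, search_rate, duration,
                                            habitat_size) {
  if (any(alpha <= 0 | search_rate <= 0 | duration <= 0 | habitat_size <= 0)) {
    stop("all effort-model parameters must be positive", call. = FALSE)
  }
  1 - exp(-alpha * search_rate * duration / habitat_size)
}

#' Effort-equivalent capture probability for a sub-zone
#'
#' If a zone is `1/k` the size of the expanded reach, one pass through the
#' expanded reach at capture probability `q_expanded` equals `k` passes
#' through the zone, giving zone capture probability
#' `1 - (1 - q_expanded)^k` at the same total effort.
#'
#' @param q_expanded Capture probability over the expanded reach, in (0, 1).
#' @param k Reach expansion factor (`>= 1`).
#'
#' @return Capture probability for the sub-zone at equal effort.
#' @examples
#' effort_equivalent_capture(0.1, 3) # 0.271
#' effort_equivalent_capture(0.3, 3) # 0.657
#' @export
effort_equivalent_capture <- function(q_expanded, k) {
  check_prob(q_expanded, "q_expanded")
  stopifnot(k >= 1)
  1 - (1 - q_expanded)^k
}

# capture probabilities and dispersal parameters implied by the five-zone
# comparison model for a given reach/scheme choice
five_zone_design <- function(n0, p0, q0, reach, scheme, k = 3) {
  q_zone <- effort_equivalent_capture(q0, k)
  switch(
    paste(scheme, reach, sep = "."),
    standard.original = list(n = n0, q = q_zone, q_prime = q_zone,
                             p = p0, i_tilde = n0 * p0),
    standard.expanded = list(n = 3 * n0, q = q0, q_prime = q0,
                             p = p0 / 3, i_tilde = n0 * p0),
    modified.expanded = list(n = 3 * n0, q = q_zone, q_prime = q0,
                             p_u = p0 / 2, p_c = 0, p_d = p0 / 2,
                             i_tilde = n0 * p0),
    stop("the modified scheme requires the expanded reach", call. = FALSE)
  )
}

#' Relative bias of Chapman's estimator in the five-zone comparison model
#'
#' Standardized design-comparison model: a stream segment of five equal-length
#' zones (US, U, C, D, DS), each holding `n0` fish at sample 1. Dispersal is
#' isotropic and local: a fish exits its zone with probability `p0` (`p0/2`
#' up, `p0/2` down) and can move only to an adjacent zone, so immigration and
#' emigration balance and `E(N') = n`. The study reach is zone C alone
#' (`reach = "original"`, exit probability `p0`) or zones U+C+D
#' (`reach = "expanded"`, mean exit probability `p0/3`); either way
#' `i_tilde = n0 p0`. Sampling effort is held constant across designs, so
#' single-zone sampling uses the effort-equivalent capture probability
#' `1 - (1 - q0)^3` (see [effort_equivalent_capture()]) while whole-reach
#' sampling uses `q0`.
#'
#' Because dispersal is balanced, the relative bias with respect to `n`
#' equals the relative bias with respect to `E(N')`.
#'
#' @param n0 Per-zone abundance at sample 1 (`>= 1`).
#' @param p0 Single-zone exit probability, in (0, 1).
#' @param q0 Baseline (expanded-reach) capture probability, in (0, 1).
#' @param reach `"original"` (zone C only) or `"expanded"` (zones U+C+D).
#' @param scheme `"standard"` (both samples over the whole study reach) or
#'   `"modified"` (sample 1 in zone C only; requires the expanded reach).
#' @param k Reach expansion factor used for effort standardization
#'   (3 in the five-zone model).
#'
#' @return A tibble: `n0`, `p0`, `q0`, `reach`, `scheme`, the capture pair
#'   `q`, `q_prime` actually used, `prb` (percent relative bias,
#'   `100 * rel_bias_n`), and the underlying moment columns of
#'   [standard_moments()] / [modified_moments()].
#'
#' @examples
#' five_zone_bias(50, 0.1, 0.1, reach = "expanded", scheme = "standard")$prb # -16.4
#' five_zone_bias(50, 0.3, 0.1, reach = "expanded", scheme = "modified")$prb # -20.9
#' @export
five_zone_bias <- function(n0, p0, q0, reach = c("expanded", "original"),
                           scheme = c("standard", "modified"), k = 3) {
  reach <- match.arg(reach)
  scheme <- match.arg(scheme)
  stopifnot(n0 >= 1)
  check_prob(p0, "p0"); check_prob(q0, "q0")
  d <- five_zone_design(n0, p0, q0, reach, scheme, k)
  res <- if (scheme == "standard") {
    standard_moments(d$n, d$q, d$q_prime, d$p, d$i_tilde)
  } else {
    modified_moments(n0, n0, n0, d$q, d$q_prime, d$p_u, d$p_c, d$p_d, d$i_tilde)
  }
  dplyr::bind_cols(
    tibble::tibble(n0 = n0, p0 = p0, q0 = q0, reach = reach,
                   q = d$q, q_prime = d$q_prime,
                   prb = 100 * res$rel_bias_n),
    res
  ) |>
    dplyr::relocate("scheme", .after = "reach")
}

#' Asymptotic relative bias and its geometric approach
#'
#' In the five-zone comparison model the relative bias has the form
#' `b = b_inf - beta * lam^(n_x - 1)` with `n_x = n` (standard scheme) or
#' `n_x = n_c` (modified scheme). For the standard scheme
#' `b_inf = p / (1 - p)` with `p = p0` (original reach) or `p0/3`
#' (expanded), and
#' `beta = ((1 - qq'(1-p))/(1-p) - q(1 - q'(1-p))) (1 - q'(1-p))`.
#' For the modified scheme `b_inf = 0` and
#' `beta = (1 - qq' - q(1-q')/3)(1 - q')`. Capture probabilities are
#' effort-standardized exactly as in [five_zone_bias()].
#'
#' @inheritParams five_zone_bias
#'
#' @return A tibble: `scheme`, `reach`, `p0`, `q0`, `q`, `q_prime`, `b_inf`
#'   (asymptotic relative bias, a fraction), `beta`, `lam`.
#'
#' @examples
#' asymptotic_bias(0.1, 0.1, reach = "original", scheme = "standard")$b_inf # 1/9
#' @export
asymptotic_bias <- function(p0, q0, reach = c("expanded", "original"),
                            scheme = c("standard", "modified"), k = 3) {
  reach <- match.arg(reach)
  scheme <- match.arg(scheme)
  check_prob(p0, "p0"); check_prob(q0, "q0")
  q_zone <- effort_equivalent_capture(q0, k)
  if (scheme == "standard") {
    p <- if (reach == "original") p0 else p0 / 3
    q <- if (reach == "original") q_zone else q0
    q_prime <- q
    s <- 1 - p
    b_inf <- p / s
    lam <- 1 - q * q_prime * s
    beta <- ((1 - q * q_prime * s) / s - q * (1 - q_prime * s)) *
      (1 - q_prime * s)
  } else {
    if (reach != "expanded") stop("the modified scheme requires the expanded reach", call. = FALSE)
    q <- q_zone
    q_prime <- q0
    b_inf <- 0 * p0
    lam <- 1 - q * q_prime
    beta <- (1 - q * q_prime - q * (1 - q_prime) / 3) * (1 - q_prime)
  }
  tibble::tibble(scheme = scheme, reach = reach, p0 = p0, q0 = q0,
                 q = q, q_prime = q_prime, b_inf = b_inf, beta = beta,
                 lam = lam)
}

#' Critical abundance for the asymptotic bias approximation
#'
#' Smallest study-reach abundance `n` at which the asymptotic relative bias
#' `b_inf` approximates the exact relative bias to within `tol` (default
#' 1e-2, i.e. one percentage point). From the geometric form of the bias the
#' bound is `n >= 1 + (-log10(tol) + log10(beta)) / |log10(lam)|` for the
#' standard scheme; for the modified scheme the bound applies to zone-C
#' abundance, and with equal zones `n = 3 n_c`, so the whole expression is
#' multiplied by 3. The result is the ceiling of the real-valued bound,
#' floored at 1 (the bound can be negative when `beta < tol`).
#'
#' @param asym A tibble from [asymptotic_bias()] (columns `scheme`, `b_inf`,
#'   `beta`, `lam`).
#' @param tol Approximation tolerance on the relative-bias scale.
#'
#' @return The input tibble with an integer `n_crit` column appended.
#'
#' @examples
#' critical_abundance(asymptotic_bias(0.1, 0.1, "original", "standard"))$n_crit # 62
#' @export
critical_abundance <- function(asym, tol = 1e-2) {
  stopifnot(all(c("scheme", "beta", "lam") %in% names(asym)), tol > 0)
  if (any(asym$beta <= 0)) stop("beta must be positive", call. = FALSE)
  bound <- 1 + (-log10(tol) + log10(asym$beta)) / abs(log10(asym$lam))
  bound <- ifelse(asym$scheme == "modified", 3 * bound, bound)
  dplyr::mutate(asym, n_crit = pmax(1L, as.integer(ceiling(bound))))
}

five_zone_cases <- function() {
  tibble::tibble(
    scheme = c("standard", "standard", "modified"),
    reach = c("original", "expanded", "expanded")
  )
}

#' Design-comparison tables over the standard parameter grids
#'
#' `table1_grid()` evaluates the percent relative bias of Chapman's estimator
#' for every combination of per-zone abundance `n0`, baseline capture
#' probability `q0` and zone-exit probability `p0`, for the three sampling
#' implementations of the five-zone model (standard scheme on the original
#' reach, standard and modified schemes on the expanded reach).
#' `table2_grid()` evaluates the asymptotic percent relative bias and the
#' critical abundance `n_crit` on its own grid.
#'
#' @param n0,q0,p0 Parameter grids (defaults are the standard comparison
#'   grids).
#' @param tol Tolerance passed to [critical_abundance()].
#'
#' @return Long-format tibbles, one row per (parameters, scheme, reach)
#'   combination: `table1_grid()` with column `prb` (percent relative bias,
#'   full precision; round to one decimal for display) and `table2_grid()`
#'   with `n_crit` and `prb_inf`.
#'
#' @examples
#' t1 <- table1_grid(n0 = 50, q0 = 0.1)
#' round(t1$prb, 1)
#' @export
table1_grid <- function(n0 = c(50, 100, 200, 300),
                        q0 = c(0.1, 0.3, 0.5, 0.7, 0.9),
                        p0 = c(0.1, 0.3, 0.5)) {
  grid <- tidyr::expand_grid(n0 = n0, q0 = q0, five_zone_cases(), p0 = p0)
  purrr::pmap(grid, function(n0, q0, scheme, reach, p0) {
    five_zone_bias(n0, p0, q0, reach = reach, scheme = scheme)
  }) |>
    purrr::list_rbind() |>
    dplyr::select("n0", "q0", "scheme", "reach", "q", "q_prime", "p0", "prb")
}

#' @rdname table1_grid
#' @export
table2_grid <- function(p0 = c(0.1, 0.3, 0.5),
                        q0 = c(0.1, 0.2, 0.3, 0.5, 0.7, 0.9),
                        tol = 1e-2) {
  grid <- tidyr::expand_grid(p0 = p0, q0 = q0, five_zone_cases())
  purrr::pmap(grid, function(p0, q0, scheme, reach) {
    critical_abundance(asymptotic_bias(p0, q0, reach = reach, scheme = scheme),
                       tol = tol)
  }) |>
    purrr::list_rbind() |>
    dplyr::mutate(prb_inf = 100 * .data$b_inf) |>
    dplyr::select("p0", "q0", "scheme", "reach", "q", "q_prime",
                  "n_crit", "prb_inf")
}
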