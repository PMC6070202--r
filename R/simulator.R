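#' Configure the individual-based two-sample simulation
#'
#' Builds the scenario for the spatially explicit simulator: a 1-D stream of
#' five contiguous zones (upstream buffer, U, C, D, downstream buffer) laid
#' out on a single axis with upstream at lower coordinates. Zones are
#' half-open intervals `[lo, hi)`, so a fish exactly on a boundary belongs to
#' the downstream-adjacent zone. The study reach is zones U+C+D (default) or
#' zone C alone (for original-reach comparisons).
#'
#' Initial fish counts are `n_per_zone` in each of U, C, D and
#' `bs_ratio * (n_per_zone / zone length) * buffer length` in each buffer
#' (rounded), so `bs_ratio = 1` gives equal density everywhere (balanced
#' dispersal on average) and `bs_ratio > 1` biases dispersal inward. Counts
#' can be overridden per zone via `counts`.
#'
#' Sample 1 covers the whole study reach (standard scheme) or zone C only
#' (modified scheme). By default the modified scheme's sample-1 capture
#' probability is effort-equalized to `1 - (1 - q0)^3` (same sampling
#' duration as a whole-reach pass); set `q1 = q0` for the equal-probability
#' variant. With `study_reach = "C"` both capture probabilities default to
#' the effort-equalized single-zone value.
#'
#' @param n_per_zone Initial fish count in each study-reach zone.
#' @param q0 Baseline capture probability (sample 2, whole study reach).
#' @param scheme `"standard"` or `"modified"`.
#' @param delta Maximum movement distance (`>= 0`, same units as zone
#'   lengths).
#' @param bs_ratio Buffer-to-study-reach initial density ratio.
#' @param zone_lengths Lengths of the five zones (upstream buffer, U, C, D,
#'   downstream buffer).
#' @param study_reach `"UCD"` (expanded reach) or `"C"` (original reach;
#'   standard scheme only).
#' @param beta_shapes Shape parameters of the symmetric beta movement kernel.
#' @param n_iter Number of simulation iterations.
#' @param q1 Sample-1 capture probability override (`NULL` for the defaults
#'   described above).
#' @param counts Optional explicit initial counts for the five zones,
#'   overriding `n_per_zone`/`bs_ratio`.
#'
#' @return An object of class `sim_config`.
#'
#' @examples
#' cfg <- simulation_config(n_per_zone = 100, q0 = 0.3, delta = 60)
#' cfg$n # 300 fish in the study reach
#' @export
simulation_config <- function(n_per_zone = 100, q0 = 0.3,
                              scheme = c("standard", "modified"),
                              delta = 60, bs_ratio = 1,
                              zone_lengths = c(90, 30, 30, 30, 90),
                              study_reach = c("UCD", "C"),
                              beta_shapes = c(4, 4),
                              n_iter = 10000, q1 = NULL, counts = NULL) {
  scheme <- match.arg(scheme)
  study_reach <- match.arg(study_reach)
  check_prob(q0, "q0")
  stopifnot(length(zone_lengths) == 5, all(zone_lengths > 0),
            delta >= 0, bs_ratio > 0, n_per_zone >= 1,
            length(beta_shapes) == 2, all(beta_shapes > 0),
            n_iter >= 2)
  if (study_reach == "C" && scheme == "modified") {
    stop("the modified scheme requires the expanded study reach", call. = FALSE)
  }
  if (is.null(counts)) {
    density <- n_per_zone / zone_lengths[3]
    counts <- c(round(bs_ratio * density * zone_lengths[1]),
                n_per_zone, n_per_zone, n_per_zone,
                round(bs_ratio * density * zone_lengths[5]))
  }
  stopifnot(length(counts) == 5, all(counts >= 0), all(counts == round(counts)))
  bounds <- cumsum(c(0, zone_lengths))
  study_zones <- if (study_reach == "UCD") 2:4 else 3
  k <- sum(zone_lengths[2:4]) / zone_lengths[3]
  if (is.null(q1)) {
    q1 <- if (scheme == "modified" || study_reach == "C") {
      effort_equivalent_capture(q0, k)
    } else {
      q0
    }
  }
  q2 <- if (study_reach == "C") effort_equivalent_capture(q0, k) else q0
  structure(
    list(scheme = scheme, study_reach = study_reach, q0 = q0, q1 = q1, q2 = q2,
         delta = delta, bs_ratio = bs_ratio, zone_lengths = zone_lengths,
         bounds = bounds, counts = counts, study_zones = study_zones,
         n = sum(counts[study_zones]), beta_shapes = beta_shapes,
         n_iter = n_iter),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Two-sample mark-recapture simulation scenario\n")
  cat("  scheme:", x$scheme, "  study reach:", x$study_reach,
      " (abundance n =", x$n, ")\n")
  cat("  capture probabilities: q1 =", signif(x$q1, 3),
      " q2 =", signif(x$q2, 3), "\n")
  cat("  movement: Beta(", x$beta_shapes[1], ",", x$beta_shapes[2],
      ") on [-", x$delta, ", ", x$delta, "]\n", sep = "")
  cat("  zone counts:", paste(x$counts, collapse = " "),
      "  iterations:", x$n_iter, "\n")
  invisible(x)
}

#' Initial fish positions for one iteration
#'
#' Places each fish uniformly at random within its zone's half-open interval,
#' using the current RNG state. Counts per zone are exactly as configured.
#'
#' @param config A [simulation_config()] object.
#'
#' @return A tibble with one row per fish: `zone` (1-5, upstream to
#'   downstream), `position`, and `in_reach` (whether the fish starts inside
#'   the study reach).
#' @export
init_positions <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  zone <- rep(1:5, config$counts)
  tibble::tibble(
    zone = zone,
    position = runif(length(zone), config$bounds[zone], config$bounds[zone + 1]),
    in_reach = zone %in% config$study_zones
  )
}

#' Draw signed movement distances from the beta kernel
#'
#' Net longitudinal displacement between samples is `delta * (2X - 1)` with
#' `X ~ Beta(shapes[1], shapes[2])`; the default symmetric Beta(4, 4) kernel
#' has mode 0 and support `[-delta, delta]`. With `delta = 0` the result is
#' exactly 0 for every fish (no RNG draw is consumed).
#'
#' @param n Number of draws.
#' @param delta Maximum movement distance (`>= 0`).
#' @param shapes Beta shape parameters.
#'
#' @return Numeric vector of signed distances in `[-delta, delta]`.
#' @examples
#' set.seed(1)
#' range(draw_displacement(1000, delta = 60)) # within [-60, 60]
#' @export
draw_displacement <- function(n, delta, shapes = c(4, 4)) {
  stopifnot(delta >= 0, length(shapes) == 2, all(shapes > 0))
  if (delta == 0) return(rep(0, n))
  delta * (2 * rbeta(n, shapes[1], shapes[2]) - 1)
}

# one iteration on pre-built position vectors; returns a named numeric vector
sim_iterate <- function(config, zone, lo, hi) {
  n_fish <- length(zone)
  pos <- runif(n_fish, lo, hi)
  reach_lo <- config$bounds[min(config$study_zones)]
  reach_hi <- config$bounds[max(config$study_zones) + 1]
  in_reach1 <- zone %in% config$study_zones
  s1_area <- if (config$scheme == "modified") zone == 3 else in_reach1
  marked <- s1_area & (runif(n_fish) < config$q1)
  pos2 <- pos + draw_displacement(n_fish, config$delta, config$beta_shapes)
  present <- pos2 >= reach_lo & pos2 < reach_hi
  captured2 <- present & (runif(n_fish) < config$q2)
  m <- sum(marked)
  c_prime <- sum(captured2)
  r_prime <- sum(marked & captured2)
  exits <- vapply(2:4, function(z) sum(zone == z & !present), numeric(1))
  c(m = m, c_prime = c_prime, r_prime = r_prime,
    n2 = sum(present),
    estimate = (m + 1) * (c_prime + 1) / (r_prime + 1) - 1,
    exits_u = exits[1], exits_c = exits[2], exits_d = exits[3],
    immigrants = sum(!in_reach1 & present))
}

#' Run a single simulated two-sample experiment
#'
#' Executes one iteration of the individual-based protocol using the current
#' RNG state: place fish, take sample 1 (marking), move every fish once by
#' [draw_displacement()] (marked fish are released at their capture
#' positions; fish leaving the simulated domain are simply outside the study
#' reach), take sample 2 over the study reach, count recaptures, and compute
#' Chapman's estimate.
#'
#' @param config A [simulation_config()] object.
#'
#' @return A one-row tibble: `m`, `c_prime`, `r_prime`, `n2` (true
#'   study-reach abundance at sample 2), `estimate` (Chapman), per-zone exit
#'   counts `exits_u`, `exits_c`, `exits_d` (fish starting in that zone that
#'   ended outside the study reach), and `immigrants`.
#' @export
run_iteration <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  zone <- rep(1:5, config$counts)
  rec <- sim_iterate(config, zone, config$bounds[zone], config$bounds[zone + 1])
  tibble::as_tibble(as.list(rec))
}

#' Run the full individual-based simulation
#'
#' Repeats [run_iteration()] `config$n_iter` times and summarizes the
#' empirical bias and precision of Chapman's estimator. The companion
#' theoretical expectation `E(N*)` is evaluated by feeding the unrounded
#' simulation-averaged exit proportions and immigrant mean into
#' [standard_moments()] or [modified_moments()].
#'
#' @param config A [simulation_config()] object.
#' @param seed Optional integer seed (a single RNG stream is used; identical
#'   seeds give identical results).
#'
#' @return An object of class `mr_simulation`: a list with the `config`, the
#'   per-iteration `records` tibble, the `estimates` vector, and a one-row
#'   `summary` tibble with columns `n`, `p_bar` (mean exit proportion;
#'   additionally `p_bar_u`, `p_bar_c`, `p_bar_d` for the modified scheme),
#'   `i_bar`, `n2_bar`, `r_bar`, `est_mean`, `theory_e`, `b_bar`
#'   (`100 (est_mean - n)/n`), `b_bar_prime` (`100 (est_mean - n2_bar)/
#'   n2_bar`) and `iqr` (linear-interpolation quartiles). Use [tidy()],
#'   [glance()] and [autoplot()] to access records, summary and a histogram.
#'
#' @examples
#' cfg <- simulation_config(n_per_zone = 25, q0 = 0.3, delta = 60, n_iter = 200)
#' sim <- run_simulation(cfg, seed = 1)
#' glance(sim)$b_bar
#' @export
run_simulation <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  zone <- rep(1:5, config$counts)
  lo <- config$bounds[zone]
  hi <- config$bounds[zone + 1]
  records <- matrix(0, nrow = config$n_iter, ncol = 9)
  for (it in seq_len(config$n_iter)) {
    records[it, ] <- sim_iterate(config, zone, lo, hi)
  }
  colnames(records) <- c("m", "c_prime", "r_prime", "n2", "estimate",
                         "exits_u", "exits_c", "exits_d", "immigrants")
  records <- tibble::as_tibble(records)
  structure(
    list(config = config,
         records = records,
         estimates = records$estimate,
         summary = summarize_simulation(config, records)),
    class = "mr_simulation"
  )
}

summarize_simulation <- function(config, records) {
  n <- config$n
  counts <- config$counts
  est_mean <- mean(records$estimate)
  n2_bar <- mean(records$n2)
  i_bar <- mean(records$immigrants)
  exit_props <- c(
    u = mean(records$exits_u) / counts[2],
    c = mean(records$exits_c) / counts[3],
    d = mean(records$exits_d) / counts[4]
  )
  if (config$study_reach == "C") {
    p_bar <- mean(records$exits_c) / counts[3]
    theory <- standard_moments(n, config$q1, config$q2,
                               p = p_bar, i_tilde = i_bar)
  } else if (config$scheme == "standard") {
    p_bar <- sum(c(mean(records$exits_u), mean(records$exits_c),
                   mean(records$exits_d))) / n
    theory <- standard_moments(n, config$q1, config$q2,
                               p = p_bar, i_tilde = i_bar)
  } else {
    p_bar <- sum(c(mean(records$exits_u), mean(records$exits_c),
                   mean(records$exits_d))) / n
    theory <- modified_moments(counts[2], counts[3], counts[4],
                               config$q1, config$q2,
                               p_u = exit_props["u"], p_c = exit_props["c"],
                               p_d = exit_props["d"], i_tilde = i_bar)
  }
  out <- tibble::tibble(
    scheme = config$scheme, n = n, delta = config$delta, q0 = config$q0,
    q1 = config$q1, q2 = config$q2,
    p_bar = p_bar,
    i_bar = i_bar, n2_bar = n2_bar,
    r_bar = mean(records$r_prime),
    est_mean = est_mean,
    theory_e = theory$expected_value,
    b_bar = 100 * (est_mean - n) / n,
    b_bar_prime = 100 * (est_mean - n2_bar) / n2_bar,
    iqr = unname(diff(quantile(records$estimate, c(0.25, 0.75))))
  )
  if (config$scheme == "modified") {
    out <- dplyr::mutate(out,
                         p_bar_u = exit_props[["u"]],
                         p_bar_c = exit_props[["c"]],
                         p_bar_d = exit_props[["d"]],
                         .after = "p_bar")
  }
  out
}

#' @export
print.mr_simulation <- function(x, ...) {
  cat("Individual-based two-sample mark-recapture simulation (",
      x$config$n_iter, " iterations)\n", sep = "")
  print(x$config)
  s <- x$summary
  cat(sprintf("  mean estimate %.1f (theory %.1f), b_bar %.1f%%, IQR %.1f\n",
              s$est_mean, s$theory_e, s$b_bar, s$iqr))
  invisible(x)
}

#' @describeIn run_simulation Per-iteration records as a tibble.
#' @param x An `mr_simulation` object.
#' @param ... Unused.
#' @method tidy mr_simulation
#' @export
tidy.mr_simulation <- function(x, ...) x$records

#' @describeIn run_simulation One-row summary tibble.
#' @method glance mr_simulation
#' @export
glance.mr_simulation <- function(x, ...) x$summary

#' Bin simulated abundance estimates for plotting
#'
#' Deterministic histogram binning of an estimate vector over equal-width
#' bins spanning the observed range; counts always sum to the number of
#' estimates.
#'
#' @param estimates Nonempty numeric vector of abundance estimates.
#' @param bins Number of bins.
#'
#' @return A tibble with `bin_lo`, `bin_hi`, `midpoint`, `count`.
#' @export
histogram_export <- function(estimates, bins = 30) {
  stopifnot(length(estimates) > 0, bins >= 1)
  rng <- range(estimates)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = bins + 1)
  idx <- pmin(findInterval(estimates, breaks, rightmost.closed = TRUE), bins)
  tibble::tibble(
    bin_lo = breaks[-length(breaks)],
    bin_hi = breaks[-1],
    midpoint = (breaks[-1] + breaks[-length(breaks)]) / 2,
    count = tabulate(idx, nbins = bins)
  )
}

#' @describeIn run_simulation Histogram of the simulated estimates, with the
#'   true abundance (solid) and empirical mean (dashed) marked.
#' @param object An `mr_simulation` object.
#' @param bins Number of histogram bins.
#' @method autoplot mr_simulation
#' @export
autoplot.mr_simulation <- function(object, bins = 30, ...) {
  h <- histogram_export(object$estimates, bins)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$midpoint, y = .data$count)) +
    ggplot2::geom_col(width = h$bin_hi[1] - h$bin_lo[1],
                      fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$config$n, colour = "red") +
    ggplot2::geom_vline(xintercept = mean(object$estimates),
                        colour = "blue", linetype = "dashed") +
    ggplot2::labs(
      x = "Chapman abundance estimate", y = "Count",
      title = sprintf("%s scheme, delta = %g, q0 = %g",
                      object$config$scheme, object$config$delta,
                      object$config$q0)
    )
}
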