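# Published design-comparison tables used as fixtures (percent relative
# biases to one decimal; critical abundances as integers). Values are inputs
# to the checks, transcribed from the printed tables.

published_table1 <- function() {
  rows <- list(
    # n0, q0, std-orig PRB (p0 = .1,.3,.5), std-exp PRB, mod-exp PRB
    list(50, 0.1, c(8.9, 35.9, 76.6), c(-16.4, -12.8, -8.9), c(-20.9, -20.9, -20.9)),
    list(50, 0.3, c(11.1, 42.9, 100.0), c(3.5, 11.1, 20.0), c(0.0, 0.0, 0.0)),
    list(50, 0.5, c(11.1, 42.9, 100.0), c(3.5, 11.1, 20.0), c(0.0, 0.0, 0.0)),
    list(50, 0.7, c(11.1, 42.9, 100.0), c(3.5, 11.1, 20.0), c(0.0, 0.0, 0.0)),
    list(50, 0.9, c(11.1, 42.9, 100.0), c(3.5, 11.1, 20.0), c(0.0, 0.0, 0.0)),
    list(100, 0.1, c(11.0, 42.4, 96.4), c(-1.2, 5.0, 11.8), c(-5.3, -5.3, -5.3)),
    list(100, 0.3, c(11.1, 42.9, 100.0), c(3.5, 11.1, 20.0), c(0.0, 0.0, 0.0)),
    list(100, 0.5, c(11.1, 42.9, 100.0), c(3.5, 11.1, 20.0), c(0.0, 0.0, 0.0)),
    list(100, 0.7, c(11.1, 42.9, 100.0), c(3.5, 11.1, 20.0), c(0.0, 0.0, 0.0)),
    list(100, 0.9, c(11.1, 42.9, 100.0), c(3.5, 11.1, 20.0), c(0.0, 0.0, 0.0)),
    list(200, 0.1, c(11.1, 42.9, 99.9), c(3.2, 10.7, 19.3), c(-0.3, -0.3, -0.3)),
    list(200, 0.3, c(11.1, 42.9, 100.0), c(3.5, 11.1, 20.0), c(0.0, 0.0, 0.0)),
    list(200, 0.5, c(11.1, 42.9, 100.0), c(3.5, 11.1, 20.0), c(0.0, 0.0, 0.0)),
    list(200, 0.7, c(11.1, 42.9, 100.0), c(3.5, 11.1, 20.0), c(0.0, 0.0, 0.0)),
    list(200, 0.9, c(11.1, 42.9, 100.0), c(3.5, 11.1, 20.0), c(0.0, 0.0, 0.0)),
    list(300, 0.1, c(11.1, 42.9, 100.0), c(3.4, 11.1, 19.9), c(0.0, 0.0, 0.0)),
    list(300, 0.3, c(11.1, 42.9, 100.0), c(3.5, 11.1, 20.0), c(0.0, 0.0, 0.0)),
    list(300, 0.5, c(11.1, 42.9, 100.0), c(3.5, 11.1, 20.0), c(0.0, 0.0, 0.0)),
    list(300, 0.7, c(11.1, 42.9, 100.0), c(3.5, 11.1, 20.0), c(0.0, 0.0, 0.0)),
    list(300, 0.9, c(11.1, 42.9, 100.0), c(3.5, 11.1, 20.0), c(0.0, 0.0, 0.0))
  )
  p0 <- c(0.1, 0.3, 0.5)
  purrr::map(rows, function(r) {
    tibble::tibble(
      n0 = r[[1]], q0 = r[[2]],
      scheme = rep(c("standard", "standard", "modified"), each = 3),
      reach = rep(c("original", "expanded", "expanded"), each = 3),
      p0 = rep(p0, 3),
      prb = c(r[[3]], r[[4]], r[[5]])
    )
  }) |> purrr::list_rbind()
}

published_table2 <- function() {
  rows <- list(
    # p0, q0, (n_crit, prb_inf) for std-orig, std-exp, mod-exp
    list(0.1, 0.1, 62, 11.1, 458, 3.4, 482, 0.0),
    list(0.1, 0.2, 16, 11.1, 108, 3.4, 124, 0.0),
    list(0.1, 0.3, 7, 11.1, 45, 3.4, 56, 0.0),
    list(0.1, 0.5, 3, 11.1, 13, 3.4, 19, 0.0),
    list(0.1, 0.7, 1, 11.1, 5, 3.4, 8, 0.0),
    list(0.1, 0.9, 1, 11.1, 2, 3.4, 3, 0.0),
    list(0.3, 0.1, 87, 42.9, 502, 11.1, 482, 0.0),
    list(0.3, 0.2, 24, 42.9, 119, 11.1, 124, 0.0),
    list(0.3, 0.3, 11, 42.9, 50, 11.1, 56, 0.0),
    list(0.3, 0.5, 5, 42.9, 15, 11.1, 19, 0.0),
    list(0.3, 0.7, 3, 42.9, 6, 11.1, 8, 0.0),
    list(0.3, 0.9, 3, 42.9, 2, 11.1, 3, 0.0),
    list(0.5, 0.1, 135, 100.0, 553, 20.0, 482, 0.0),
    list(0.5, 0.2, 38, 100.0, 132, 20.0, 124, 0.0),
    list(0.5, 0.3, 19, 100.0, 55, 20.0, 56, 0.0),
    list(0.5, 0.5, 9, 100.0, 17, 20.0, 19, 0.0),
    list(0.5, 0.7, 7, 100.0, 7, 20.0, 8, 0.0),
    list(0.5, 0.9, 6, 100.0, 3, 20.0, 3, 0.0)
  )
  purrr::map(rows, function(r) {
    tibble::tibble(
      p0 = r[[1]], q0 = r[[2]],
      scheme = c("standard", "standard", "modified"),
      reach = c("original", "expanded", "expanded"),
      n_crit = as.integer(c(r[[3]], r[[5]], r[[7]])),
      prb_inf = c(r[[4]], r[[6]], r[[8]])
    )
  }) |> purrr::list_rbind()
}

# Compare computed five-zone biases to the published table. The published
# standard-scheme expanded-reach cells at p0 = 0.1 that print as 3.5 are
# internally inconsistent: the finite-abundance bias is strictly below its
# asymptote 100/29 = 3.4483 (the geometric term is subtracted), and the
# publication prints that same asymptote as 3.4 in its critical-abundance
# table. Those cells look like a two-step rounding artifact (3.4483 -> 3.45
# -> 3.5), so they are checked against the exact value instead of the
# printed digit.
check_published_table1 <- function() {
  joined <- dplyr::inner_join(
    published_table1(), table1_grid(),
    by = c("n0", "q0", "scheme", "reach", "p0"), suffix = c("_pub", "")
  )
  ambiguous <- joined$scheme == "standard" & joined$reach == "expanded" &
    joined$p0 == 0.1 & joined$prb_pub == 3.5
  ok <- abs(joined$prb - joined$prb_pub) <= 0.05 + 1e-9
  ok[ambiguous] <- abs(joined$prb[ambiguous] - 100 / 29) <= 1e-3
  list(joined = joined, ok = ok)
}

# grid of capture pairs reused across property tests
capture_pair_grid <- function() {
  tidyr::expand_grid(q = c(0.1, 0.4, 0.7), q_prime = c(0.2, 0.5, 0.8))
}
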