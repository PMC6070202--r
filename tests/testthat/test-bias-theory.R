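test_that("closed-population bias matches the known benchmark values", {
  expect_equal(100 * closed_moments(100, 0.1, 0.1)$rel_bias_n, -30,
               tolerance = 0.02)
  expect_equal(100 * closed_moments(200, 0.1, 0.1)$rel_bias_n, -11,
               tolerance = 0.01)
  # direct closed form
  res <- closed_moments(100, 0.1, 0.1)
  expect_equal(res$expected_value,
               100 - 0.9 * 0.9 * 100 * (1 - 0.01)^99, tolerance = 1e-12)
  expect_error(closed_moments(100, 0, 0.5), "strictly between")
})

test_that("closed-population relative bias is negative for every design", {
  grid <- tidyr::expand_grid(n = c(1, 3, 10, 50, 500), capture_pair_grid())
  res <- closed_moments(grid$n, grid$q, grid$q_prime)
  expect_true(all(res$rel_bias_n < 0))
  expect_true(all(res$lam > 0 & res$lam < 1))
  expect_true(all(res$phi > 0 & res$phi < res$omega))
})

test_that("moment formulas match exhaustive enumeration on a parameter grid", {
  # closed designs
  closed_grid <- tidyr::expand_grid(n = c(1, 2, 4, 7, 12), capture_pair_grid())
  for (i in seq_len(nrow(closed_grid))) {
    g <- closed_grid[i, ]
    expect_equal(
      chapman_expectation_exact(n_c = g$n, q = g$q, q_prime = g$q_prime),
      closed_moments(g$n, g$q, g$q_prime)$expected_value,
      tolerance = 1e-9
    )
  }
  # standard dispersal designs (single zone with exits and fixed immigration)
  std_grid <- tidyr::expand_grid(n = c(2, 4, 6), p = c(0.1, 0.25, 0.5),
                                 imm = c(0, 2), q = c(0.3, 0.6), q_prime = 0.5)
  for (i in seq_len(nrow(std_grid))) {
    g <- std_grid[i, ]
    expect_equal(
      chapman_expectation_exact(n_c = g$n, q = g$q, q_prime = g$q_prime,
                                p_c = g$p, n_immigrants = g$imm),
      standard_moments(g$n, g$q, g$q_prime, p = g$p, i_tilde = g$imm)$expected_value,
      tolerance = 1e-9
    )
  }
  # modified designs with three zones
  mod_grid <- tidyr::expand_grid(n_side = c(1, 2), n_c = c(2, 3),
                                 p_side = c(0.2, 0.5), p_c = c(0, 0.2),
                                 imm = c(0, 1))
  for (i in seq_len(nrow(mod_grid))) {
    g <- mod_grid[i, ]
    expect_equal(
      chapman_expectation_exact(n_c = g$n_c, q = 0.5, q_prime = 0.4,
                                n_u = g$n_side, n_d = g$n_side,
                                p_u = g$p_side, p_c = g$p_c, p_d = g$p_side,
                                n_immigrants = g$imm),
      modified_moments(g$n_side, g$n_c, g$n_side, 0.5, 0.4,
                       g$p_side, g$p_c, g$p_side, g$imm)$expected_value,
      tolerance = 1e-9
    )
  }
})

test_that("enumeration oracle refuses oversized problems and handles limits", {
  expect_error(chapman_expectation_exact(n_c = 10, q = 0.5, q_prime = 0.5,
                                         n_u = 5, n_d = 5), "refused")
  # p -> 0 limit is continuous with the closed case
  expect_equal(
    chapman_expectation_exact(n_c = 4, q = 0.4, q_prime = 0.6, p_c = 1e-9),
    chapman_expectation_exact(n_c = 4, q = 0.4, q_prime = 0.6),
    tolerance = 1e-6
  )
})

test_that("expectation depends on the immigrant distribution only via its mean", {
  # two-point immigrant distribution {1, 3} w.p. 1/2 each has mean 2;
  # mixture of oracle runs must equal the fixed-count formula at i_tilde = 2
  mix <- 0.5 * chapman_expectation_exact(n_c = 4, q = 0.4, q_prime = 0.5,
                                         p_c = 0.25, n_immigrants = 1) +
    0.5 * chapman_expectation_exact(n_c = 4, q = 0.4, q_prime = 0.5,
                                    p_c = 0.25, n_immigrants = 3)
  expect_equal(mix,
               standard_moments(4, 0.4, 0.5, p = 0.25, i_tilde = 2)$expected_value,
               tolerance = 1e-12)
})

test_that("the reduction chain modified -> standard -> closed is exact", {
  pairs <- capture_pair_grid()
  for (i in seq_len(nrow(pairs))) {
    q <- pairs$q[i]; qp <- pairs$q_prime[i]
    std <- standard_moments(150, q, qp, p = 1 / 30, i_tilde = 5)
    mod <- modified_moments(0, 150, 0, q, qp,
                            p_u = 0, p_c = 1 / 30, p_d = 0, i_tilde = 5)
    expect_equal(mod$expected_value, std$expected_value, tolerance = 1e-12)
    expect_equal(mod$omega, std$omega, tolerance = 1e-12)
    expect_equal(mod$phi, std$phi, tolerance = 1e-12)
    expect_equal(mod$lam, std$lam, tolerance = 1e-12)

    closed <- closed_moments(80, q, qp)
    std0 <- standard_moments(80, q, qp, p = 0, i_tilde = 0)
    expect_equal(std0$expected_value, closed$expected_value, tolerance = 1e-12)
    expect_equal(std0$rel_bias_n, closed$rel_bias_n, tolerance = 1e-12)
  }
})

test_that("large-abundance limits recover the classical approximations", {
  n <- 1e4
  # open reach, standard scheme: E(N*) -> n + i_tilde/(1-p)
  std <- standard_moments(n, 0.3, 0.3, p = 0.2, i_tilde = 50)
  expect_equal(std$expected_value, n + 50 / 0.8, tolerance = 1e-6)
  # modified scheme with p_c = 0: E(N*) -> n(1 - p_tilde) + i_tilde
  mod <- modified_moments(n, n, n, 0.657, 0.3,
                          p_u = 0.15, p_c = 0, p_d = 0.15, i_tilde = 100)
  expect_equal(mod$expected_value, 3 * n * (1 - 0.1) + 100, tolerance = 1e-6)
  # thorough mixing: E(N*) -> n_T
  tot <- total_population_moments("standard", n = n, n_us = 5000, n_ds = 5000,
                                  q = 0.5, q_prime = 0.5,
                                  p_s_s = 0.6, p_us_s = 0.6, p_ds_s = 0.6)
  expect_equal(tot$expected_value, 2e4, tolerance = 1e-6)
  expect_equal(tot$omega, tot$n_t, tolerance = 1e-9)
})

test_that("the sampling-variation term decays geometrically in abundance", {
  for (x in list(closed_moments(1:200, 0.2, 0.3),
                 standard_moments(1:200, 0.2, 0.3, p = 0.1, i_tilde = 4))) {
    gap <- x$geom_term
    expect_equal(gap, x$phi * x$lam^(x$n - 1), tolerance = 1e-12)
    # phi grows only linearly in n, so the decay ratio tends to lam from
    # above and the gap shrinks monotonically once (1 + 1/n) lam < 1
    ratio <- gap[-1] / gap[-length(gap)]
    expect_true(all(diff(gap[20:200]) < 0))
    expect_equal(ratio[199], x$lam[1], tolerance = 1e-2)
    # geometric envelope: per-step shrinkage never exceeds (1 + 1/n) lam
    expect_lt(gap[200] / gap[100], (1.01 * x$lam[1])^100)
  }
})

test_that("total-population bias signs follow the transfer probabilities", {
  # in-reach fish likeliest to stay: negative bias w.r.t. n_T for all n
  for (n in c(5, 50, 500, 5000)) {
    res <- total_population_moments("standard", n = n, n_us = n, n_ds = n,
                                    q = 0.5, q_prime = 0.5,
                                    p_s_s = 0.9, p_us_s = 0.2, p_ds_s = 0.2)
    expect_lt(res$expected_value, res$n_t)
    expect_equal(res$asymptotic_sign_nt, -1)
  }
  # outside fish likelier to enter: positive for sufficiently large n
  res <- total_population_moments("standard", n = 5000, n_us = 5000, n_ds = 5000,
                                  q = 0.5, q_prime = 0.5,
                                  p_s_s = 0.1, p_us_s = 0.9, p_ds_s = 0.9)
  expect_equal(res$asymptotic_sign_nt, 1)
  expect_gt(res$expected_value, res$n_t)
  # equal transfer: omega equals n_T, finite-n bias negative but vanishing
  res <- total_population_moments("standard", n = c(100, 2000),
                                  n_us = 50, n_ds = 50,
                                  q = 0.5, q_prime = 0.5,
                                  p_s_s = 0.6, p_us_s = 0.6, p_ds_s = 0.6)
  expect_equal(res$asymptotic_sign_nt, c(0, 0))
  expect_true(all(res$rel_bias_nt < 0))
  expect_lt(abs(res$rel_bias_nt[2]), abs(res$rel_bias_nt[1]))

  # modified-scheme version of property 1
  res <- total_population_moments("modified", n_us = 100, n_ds = 100,
                                  q = 0.657, q_prime = 0.3,
                                  p_us_s = 0.2, p_ds_s = 0.2,
                                  n_u = 100, n_c = 100, n_d = 100,
                                  p_u_s = 0.9, p_c_s = 0.95, p_d_s = 0.9)
  expect_equal(res$asymptotic_sign_nt, -1)
  expect_lt(res$expected_value, res$n_t)

  expect_error(
    total_population_moments("standard", n = 10, n_us = 10, n_ds = 10,
                             q = 0.5, q_prime = 0.5,
                             p_s_s = 0.5, p_us_s = 1, p_ds_s = 0.2),
    "transfer"
  )
})

test_that("invalid dispersal designs are rejected", {
  expect_error(standard_moments(10, 0.3, 0.3, p = 1, i_tilde = 0), "\\[0, 1\\)")
  expect_error(standard_moments(10, 0.3, 0.3, p = -0.1, i_tilde = 0), "\\[0, 1\\)")
  expect_error(standard_moments(10, 0.3, 0.3, p = 0.2, i_tilde = -1), "nonnegative")
  expect_error(modified_moments(-1, 5, 1, 0.3, 0.3, 0.1, 0, 0.1, 0), "nonnegative")
})
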