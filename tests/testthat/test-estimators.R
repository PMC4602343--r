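# Estimator inversions, saturation handling and orderings.

test_that("analytic inversion round-trips its own expectation", {
  for (k in c(1, 50, 500, 2000)) {
    B <- expected_breakpoints(980, 1020, k)
    est <- dcj_tilde(B, 980, 1020)
    expect_false(est$saturated)
    expect_equal(est$k_hat, k, tolerance = 1e-9)
  }
  expect_equal(dcj_tilde(0, 980, 1020)$k_hat, 0)
})

test_that("saturation is flagged, not raised", {
  est <- dcj_tilde(980, 980, 1020)  # B = a lies beyond the asymptote
  expect_true(est$saturated)
  expect_equal(est$k_hat, Inf)
  expect_error(dcj_tilde(-1, 980, 1020), "in \\[0, a\\]")
  expect_error(dcj_tilde(981, 980, 1020), "in \\[0, a\\]")
  sat <- seq_coding_estimate(100, 100, 110, N = "2n")  # D = 2B >= N/2
  expect_true(sat$saturated)
})

test_that("estimates are monotone in the observed breakpoint count", {
  ks <- vapply(seq(0, 900, by = 50),
               function(B) dcj_tilde(B, 980, 1020)$k_hat, 0)
  expect_true(all(diff(ks) > 0))
  # non-integer observed statistics are accepted (mean-of-replicates use)
  expect_silent(dcj_tilde(123.4, 980, 1020))
})

test_that("sequence-coding with the exact length reproduces the inversion", {
  B <- expected_breakpoints(980, 1020, 500)
  tilde <- dcj_tilde(B, 980, 1020)$k_hat
  expect_equal(seq_coding_estimate(B, 980, 1020, "exact")$k_hat, tilde,
               tolerance = 1e-9)
  # too-short coding overestimates, too-long underestimates
  expect_gt(seq_coding_estimate(B, 980, 1020, "2n")$k_hat, tilde)
  expect_lt(seq_coding_estimate(B, 980, 1020, "n(2n-1)")$k_hat, tilde)
  # numeric N accepted
  expect_equal(seq_coding_estimate(B, 980, 1020, 4 * 980)$N, 3920)
})

test_that("grid inversion recovers k on noiseless curves, ties to smallest k", {
  tab <- eh_expected_cycles(50, 0:60)
  expect_equal(grid_invert(tab[31], tab)$k_hat, 30)
  expect_equal(estimate_eh(eh_expected_cycles(50, 30), 50, 60)$k_hat, 30)
  expect_equal(estimate_bd(bd_expected_components(50, 30), 50, 60)$k_hat, 30)
  expect_equal(grid_invert(expected_breakpoints(10, 12, 7),
                           function(k) expected_breakpoints(10, 12, k),
                           k_max = 40)$k_hat, 7)
  # exact ties break toward the smallest k
  expect_equal(grid_invert(1, c(5, 1, 1, 1))$k_hat, 1)
  expect_equal(grid_invert(0, rep(0, 10))$k_hat, 0)
})

test_that("fictional-vertex bracket: even lower bound 2|a1 - a2|", {
  expect_equal(choose_f(980, 980), 0L)
  expect_equal(choose_f(980, 978), 4L)
  expect_equal(choose_f(978, 980), 4L)
  for (d in 0:5) expect_equal(choose_f(100, 100 - d) %% 2L, 0L)
  expect_equal(choose_f(10, 10, g = 10, upper = 7), 8L)   # rounded to even
  expect_equal(choose_f(10, 10, g = 10, upper = 99), 20L) # capped at 2g
})

test_that("parsimony wraps the observed-graph distance", {
  expect_equal(parsimony_distance(fig_red(), fig_blue())$k_hat, 2)
  g <- augment_genome(build_genome(c(1, 2, 3, 4)))
  expect_equal(parsimony_distance(g, g)$k_hat, 0)
  g2 <- apply_dcj(g, c(2, 3), c(4, 5), choice = 2L)
  expect_equal(parsimony_distance(g, g2)$k_hat, 1)
})

test_that("tidy and glance methods expose estimate fields", {
  est <- dcj_tilde(100, 980, 1020)
  td <- tidy(est)
  expect_false(inherits(td, "dcj_estimate"))
  expect_true(all(c("estimator", "observed", "k_hat", "saturated") %in% names(td)))
  gl <- glance(est)
  expect_named(gl, c("estimator", "k_hat", "saturated"))
})
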