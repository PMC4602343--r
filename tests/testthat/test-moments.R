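# Closed-form expectations: breakpoints, sequence differences, transposition
# cycles, graph components.

test_that("breakpoint expectation: boundary values and one-step enumeration", {
  expect_equal(expected_breakpoints(5, 10, 0), 0)
  # asymptote a(2n-2)/(2n-1)
  expect_equal(expected_breakpoints(2, 4, 1e6), 12 / 7, tolerance = 1e-12)
  # one step equals a * 2/n, verified by enumerating all n(n-1) moves of the
  # augmented three-gene genome (a = 2, n = 4)
  g <- augment_genome(fig_red())
  moves <- dcj_moves(g)
  B1 <- vapply(seq_len(nrow(moves)), function(i) {
    gi <- apply_dcj(g, c(moves$a1[i], moves$b1[i]),
                    c(moves$a2[i], moves$b2[i]), moves$choice[i])
    count_breakpoints(g, gi)
  }, 0L)
  expect_equal(mean(B1), expected_breakpoints(2, 4, 1))
  expect_equal(expected_breakpoints(2, 4, 1), 2 * 2 / 4)
})

test_that("closed form and recurrence agree to floating precision", {
  for (a in c(2, 100, 980)) {
    for (n in c(4, 120, 1020)) {
      k <- 0:300
      closed <- expected_breakpoints(a, n, k)
      recur <- breakpoint_recurrence(a, n, k)
      expect_lt(max(abs(closed - recur) / pmax(closed, 1e-300)), 1e-12)
    }
  }
  expect_equal(breakpoint_recurrence(7, 9, 1), 7 * 2 / 9)
})

test_that("breakpoint expectation is increasing, concave and bounded", {
  k <- 0:2000
  e <- expected_breakpoints(980, 1020, k)
  expect_true(all(diff(e) > 0))
  expect_true(all(diff(diff(e)) < 0))
  expect_true(all(e < 980 * (2 * 1020 - 2) / (2 * 1020 - 1)))
})

test_that("binary substitution expectations: saturation and one-step checks", {
  expect_equal(seq_expected_differences(100, 0), 0)
  expect_equal(seq_expected_differences(100, 1e7), 50)
  # N = 2, one step: the single-site flip makes exactly one difference
  expect_equal(seq_expected_differences(2, 1), 1)
  expect_equal(seq4_expected_differences(64, 0), 0)
  expect_equal(seq4_expected_differences(64, 1e6), 32, tolerance = 1e-9)
  # four-by-four differences equal quarter of the single-site differences of
  # the four-times-longer sequence, at the matched substitution budget
  for (N in c(40, 400)) {
    for (ks in c(1, 5, 20)) {
      ks_prime <- ks * log(1 - 8 / N) / log(1 - 1 / (2 * N))
      expect_equal(seq4_expected_differences(N, ks),
                   seq_expected_differences(4 * N, ks_prime) / 4,
                   tolerance = 1e-12)
      # ~16 single-site steps per four-by-four event (4 sites, 4x length)
      expect_equal(ks_prime / ks, 16, tolerance = 0.2)
    }
  }
})

test_that("sequence-coding of the breakpoint expectation is exact", {
  pm <- proposition_mapping(980, 1020, 0:400)
  expect_equal(pm$ks_exact[1], 0)
  lhs <- seq_expected_differences(pm$N_exact[1], pm$ks_exact) / 2
  rhs <- expected_breakpoints(980, 1020, 0:400)
  expect_equal(lhs, rhs, tolerance = 1e-12)
  # N ~ 4a: relative gap is exactly 1/(2n-2), i.e. ~0.1% around n = 500
  for (n in c(500, 1020, 5000)) {
    a <- n - 40
    pm <- proposition_mapping(a, n, 1)
    rel <- abs(pm$N_exact - pm$N_approx) / pm$N_exact
    expect_equal(rel, 1 / (2 * n - 2), tolerance = 1e-12)
    expect_lt(rel, 1.1e-3)
  }
})

test_that("transposition-cycle series matches the exact small-n pattern", {
  # printed series at n = 2: distance 0,1,0,1,...; cycles 2,1,2,1,...
  expect_equal(eh_formula(2, 0:9), rep(c(0, 1), 5), tolerance = 1e-12)
  expect_equal(eh_expected_cycles(2, 0:9), rep(c(2, 1), 5), tolerance = 1e-12)
  for (n in c(3, 5, 8)) {
    expect_equal(eh_expected_cycles(n, 0), n, tolerance = 1e-12)
  }
  # cycles + distance = n everywhere tested
  for (n in c(4, 9, 30)) {
    k <- 0:40
    expect_equal(eh_expected_cycles(n, k) + eh_formula(n, k), rep(n, 41),
                 tolerance = 1e-9)
  }
})

test_that("cancellation control: larger n still matches the walk's scale", {
  # at n = 120 the alternating coefficients are ~1e33; a correct evaluation
  # must land in [1, n] and pass the internal doubled-precision check
  v <- eh_expected_cycles(120, c(0, 60, 240, 400))
  expect_equal(v[1], 120, tolerance = 1e-9)
  expect_true(all(v >= 1 & v <= 120))
  expect_true(all(diff(v) < 0))
  # deliberately starved precision is refused, not silently wrong
  expect_error(eh_formula(60, 50, frac_limbs = 1L), "precision")
})

test_that("random-multigraph component expectation behaves at the edges", {
  expect_equal(bd_expected_components(200, 0), 200)
  expect_equal(bd_expected_components(50, 1e-9), 50, tolerance = 1e-6)
  k <- 0:400
  e <- bd_expected_components(200, k)
  expect_true(all(diff(e) <= 1e-9))  # coagulation only
  # agreement with Monte-Carlo within the tree-approximation's own bias
  mc <- montecarlo_components(200, 50, replicates = 400, seed = 9)
  expect_lt(abs(bd_expected_components(200, 50) - mc$mean), 1)
})
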