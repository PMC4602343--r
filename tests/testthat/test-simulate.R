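# The DCJ chain simulator, its coupled processes and the multigraph process.

test_that("trajectory boundary conditions and determinism", {
  g0 <- random_genome(g = 12, telomeres = 4, f = 2, seed = 1)
  tr0 <- simulate_dcj(g0, 0, seed = 1, record = c("breakpoints", "real_cycles"))
  n <- genome_params(g0)$n
  expect_equal(nrow(tr0), 1L)
  expect_equal(tr0$breakpoints, 0L)
  expect_equal(tr0$real_cycles, n)

  t1 <- simulate_dcj(g0, 40, seed = 9, couple = TRUE,
                     record = c("breakpoints", "obs_cycles"))
  t2 <- simulate_dcj(g0, 40, seed = 9, couple = TRUE,
                     record = c("breakpoints", "obs_cycles"))
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  expect_equal(t1$perm_cycles[1], n)
  expect_equal(t1$k, 0:40)
})

test_that("tracked statistics agree with from-scratch recomputation", {
  g0 <- random_genome(g = 18, telomeres = 2, f = 0, seed = 3)
  tr <- simulate_dcj(g0, 60, seed = 4,
                     record = c("breakpoints", "real_cycles", "obs_cycles"))
  fin <- attr(tr, "final_genome")
  expect_equal(tail(tr$breakpoints, 1), count_breakpoints(g0, fin))
  expect_equal(tail(tr$real_cycles, 1),
               length(real_breakpoint_graph(g0, fin)$cycle_lengths))
  expect_equal(tail(tr$obs_cycles, 1),
               length(observed_breakpoint_graph(g0, fin)$cycle_lengths))
  expect_equal(tail(tr$obs_distance, 1),
               dcj_distance(observed_breakpoint_graph(g0, fin)))
  # matching stays perfect, vertex budget constant
  expect_perfect_matching(fin)
  expect_equal(length(fin$mate), length(g0$mate))
})

test_that("simulated breakpoint means follow the closed-form expectation", {
  g0 <- random_genome(g = 40, telomeres = 4, f = 0, seed = 5)  # a=38, n=42
  reps <- 80
  ks <- c(10, 40)
  B <- matrix(0L, reps, length(ks))
  for (r in seq_len(reps)) {
    tr <- simulate_dcj(g0, max(ks), seed = 100 + r, record = "breakpoints")
    B[r, ] <- tr$breakpoints[ks + 1]
  }
  for (i in seq_along(ks)) {
    m <- mean(B[, i]); se <- sd(B[, i]) / sqrt(reps)
    expect_lt(abs(m - expected_breakpoints(38, 42, ks[i])), 3 * se)
  }
})

test_that("coupled walk: parity alternates, steps are +-1, mean matches", {
  g0 <- random_genome(g = 29, telomeres = 2, f = 0, seed = 6)  # n = 30
  cy <- matrix(0L, 60, 41)
  bc <- cy
  for (r in 1:60) {
    tr <- simulate_dcj(g0, 40, seed = 200 + r, couple = TRUE)
    expect_true(all(abs(diff(tr$perm_cycles)) == 1L))
    expect_true(all(abs(diff(tr$real_cycles)) <= 1L))
    cy[r, ] <- tr$perm_cycles
    bc[r, ] <- tr$real_cycles
  }
  # permutation parity flips every transposition
  expect_true(all((cy[, 1] - cy[, 2]) %% 2 == 1))
  # expectation-level domination and O(k/n) gap (Theorem-2 scale)
  gap <- colMeans(cy) - colMeans(bc)
  se <- apply(cy - bc, 2, sd) / sqrt(60)
  expect_true(all(gap >= -3 * se))
  expect_true(all(gap[-1] <= 3 * (1:40) / 30 + 3 * se[-1]))
  # the coupled permutation is an honest uniform transposition walk
  eh <- eh_expected_cycles(30, 0:40)
  se_cy <- apply(cy, 2, sd) / sqrt(60)
  # absolute floor covers early steps where no run has yet seen the rare
  # same-cycle event (sample se = 0 while the true mean is slightly lower)
  expect_true(all(abs(colMeans(cy) - eh) <= 4 * se_cy + 0.05))
})

test_that("observed-graph cycles dominate real-graph cycles along runs", {
  for (s in 1:3) {
    g0 <- random_genome(g = 15, telomeres = 4, f = 2, seed = s)
    tr <- simulate_dcj(g0, 80, seed = 300 + s,
                       record = c("obs_cycles", "real_cycles"))
    expect_true(all(tr$obs_cycles >= tr$real_cycles))
  }
})

test_that("multigraph process: first edge always merges, counts non-increasing", {
  tr <- random_graph_trajectory(100, 200, seed = 8)
  expect_equal(tr$components[1], 100L)
  expect_equal(tr$components[2], 99L)
  expect_true(all(diff(tr$components) <= 0))
  expect_identical(tr, random_graph_trajectory(100, 200, seed = 8))
  # agreement with the independent igraph-based sampler
  ours <- vapply(1:150, function(s) {
    tail(random_graph_trajectory(200, 100, seed = s)$components, 1)
  }, 0L)
  mc <- montecarlo_components(200, 100, replicates = 1000, seed = 42)
  se <- sqrt(sd(ours)^2 / 150 + mc$se^2)
  expect_lt(abs(mean(ours) - mc$mean), 4 * se)
})
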