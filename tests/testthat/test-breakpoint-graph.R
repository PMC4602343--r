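# Observed and real breakpoint graphs, cycle counts and the DCJ distance.

test_that("worked three-gene example: observed graph has 2 cycles, distance 2", {
  bg <- observed_breakpoint_graph(fig_red(), fig_blue())
  expect_equal(bg$n, 4L)
  expect_equal(length(bg$cycle_lengths), 2L)
  expect_equal(dcj_distance(bg), 2L)
  expect_equal(sum(bg$cycle_lengths), bg$n)
})

test_that("real graph depends on the telomere correspondence", {
  red <- augment_genome(fig_red())
  blue <- augment_genome(fig_blue())
  # identity correspondence: red's tail-of-g1 telomeric vertex is blue's
  # head-of-g1 one -- a single 4-cycle, so three DCJs are needed
  real_b <- real_breakpoint_graph(red, blue)
  expect_equal(length(real_b$cycle_lengths), 1L)
  expect_equal(dcj_distance(real_b), 3L)
  # swapped correspondence reproduces the cycle-maximizing closure: 2 cycles
  swap <- data.frame(from = c(7L, 8L), to = c(8L, 7L))
  real_c <- real_breakpoint_graph(red, blue, correspondence = swap)
  expect_equal(length(real_c$cycle_lengths), 2L)
  expect_equal(dcj_distance(real_c), 2L)
  obs <- observed_breakpoint_graph(red, blue)
  expect_equal(cycle_count_gap(obs, real_b), 1L)
  expect_equal(cycle_count_gap(obs, real_c), 0L)
})

test_that("identical genomes give n trivial cycles and distance zero", {
  g <- augment_genome(build_genome(list(c(1, 2), c(3, 4)), circular = TRUE))
  obs <- observed_breakpoint_graph(g, g)
  expect_equal(length(obs$cycle_lengths), obs$n)
  expect_equal(dcj_distance(obs), 0L)
  real <- real_breakpoint_graph(g, g)
  expect_equal(length(real$cycle_lengths), real$n)
  expect_equal(cycle_count_gap(obs, real), 0L)
})

test_that("observed graph maximizes cycles over all telomere correspondences", {
  # exhaustive search over bijections of <= 4 non-observed vertices
  set.seed(7)
  for (case in 1:6) {
    g1 <- random_genome(g = 5, telomeres = 2, f = 2, augment = TRUE)
    g2 <- random_genome(g = 5, telomeres = 2, f = 2, augment = TRUE)
    obs <- observed_breakpoint_graph(g1, g2)
    best <- max(vapply(all_correspondences(g1, g2), function(corr) {
      length(real_breakpoint_graph(g1, g2, correspondence = corr)$cycle_lengths)
    }, 0L))
    expect_equal(length(obs$cycle_lengths), best)
    # gap bounds against the identity correspondence
    real <- real_breakpoint_graph(g1, g2)
    gap <- cycle_count_gap(obs, real)
    expect_gte(gap, 0L)
    expect_lte(gap, length(g1$mate) - 2L * g1$g)
    expect_lte(dcj_distance(obs), dcj_distance(real))
  }
})

test_that("cycle lengths always sum to the graph's adjacency count", {
  set.seed(11)
  for (case in 1:5) {
    g1 <- random_genome(g = 8, telomeres = 4, f = 0, augment = TRUE)
    g2 <- random_genome(g = 8, telomeres = 4, f = 0, augment = TRUE)
    obs <- observed_breakpoint_graph(g1, g2)
    expect_equal(sum(obs$cycle_lengths), obs$n)
    real <- real_breakpoint_graph(g1, g2)
    expect_equal(sum(real$cycle_lengths), real$n)
  }
})

test_that("one effective DCJ gives observed distance one", {
  g <- augment_genome(build_genome(c(1, 2, 3, 4)))
  # rewire two observed adjacencies (an inversion)
  g2 <- apply_dcj(g, c(2, 3), c(4, 5), choice = 2L)
  expect_gt(count_breakpoints(g, g2), 0)
  expect_equal(dcj_distance(observed_breakpoint_graph(g, g2)), 1L)
})

test_that("tidy and glance expose the cycle-type table", {
  bg <- observed_breakpoint_graph(fig_red(), fig_blue())
  td <- tidy(bg)
  expect_named(td, c("cycle_length", "multiplicity", "graph_kind"))
  expect_equal(sum(td$cycle_length * td$multiplicity), bg$n)
  gl <- glance(bg)
  expect_equal(gl$dcj_distance, 2L)
})
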