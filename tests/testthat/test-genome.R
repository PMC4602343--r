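# Genome construction, augmentation, DCJ application and breakpoint counting.

test_that("build_genome links consecutive extremities and leaves telomeres", {
  g <- build_genome(c(1, 2, 3))
  # adjacencies {head(1), tail(2)} and {head(2), tail(3)}
  expect_equal(g$mate[2], 3L)
  expect_equal(g$mate[4], 5L)
  # telomeres: tail(1) and head(3)
  expect_equal(g$mate[c(1, 6)], c(0L, 0L))
  expect_equal(genome_params(g)$a, 2L)

  circ <- build_genome(list(1), circular = TRUE)
  expect_equal(circ$mate, c(2L, 1L))  # single adjacency {head, tail}
  expect_equal(genome_params(circ)$t, 0L)

  two <- build_genome(list(1, 2))
  expect_equal(genome_params(two)$a, 0L)
  expect_equal(genome_params(two)$t, 4L)

  expect_error(build_genome(c(1, 2, 2)), "duplicate")
  expect_error(build_genome(c(1, 3)), "missing")
})

test_that("augmentation yields a perfect matching with n = 2g - a + f/2", {
  g <- augment_genome(fig_red())  # a = 2, g = 3, f = 0
  p <- genome_params(g)
  expect_equal(p$n, 4L)
  expect_equal(length(g$mate), 4L * p$g - 2L * p$a + p$f)  # 8 vertices
  expect_perfect_matching(g)

  circ <- augment_genome(build_genome(list(c(1, 2), c(3)), circular = TRUE),
                         f = 4L)
  expect_equal(genome_params(circ)$n, genome_params(circ)$g + 2L)
  # f = 4 fictional vertices matched pairwise: 2 fictional adjacencies
  expect_equal(sum(adjacencies(circ)$kind == "fictional"), 2L)

  one_f <- augment_genome(fig_red(), f = 2L)
  expect_equal(sum(adjacencies(one_f)$kind == "fictional"), 1L)
  expect_error(augment_genome(fig_red(), f = 3L), "even")
})

test_that("apply_dcj rewires exactly the two named adjacencies", {
  g <- augment_genome(fig_red())
  adj <- adjacencies(g)
  a1 <- c(adj$v1[1], adj$v2[1]); a2 <- c(adj$v1[2], adj$v2[2])
  g1 <- apply_dcj(g, a1, a2, choice = 1L)
  expect_perfect_matching(g1)
  expect_equal(g1$mate[a1[1]], a2[1])
  expect_equal(g1$mate[a1[2]], a2[2])
  # same move twice restores the genome (involution on those four vertices)
  back <- apply_dcj(g1, c(a1[1], a2[1]), c(a1[2], a2[2]), choice = 1L)
  expect_true(dcjmoments:::genomes_identical(back, g))
  expect_error(apply_dcj(g, a1, a1), "distinct")
  expect_error(apply_dcj(g, c(1, 5), a2), "not adjacencies")
})

test_that("two DCJs transform the red genome into the blue genome", {
  red <- augment_genome(fig_red())
  blue <- augment_genome(fig_blue())
  # the observed graph has two cycles of length 2; rewiring the red edges of
  # each cycle into the blue edges is one DCJ per cycle -- search all pairs
  moves <- dcj_moves(red)
  found <- FALSE
  for (i in seq_len(nrow(moves))) {
    m1 <- apply_dcj(red, c(moves$a1[i], moves$b1[i]),
                    c(moves$a2[i], moves$b2[i]), moves$choice[i])
    moves2 <- dcj_moves(m1)
    for (j in seq_len(nrow(moves2))) {
      m2 <- apply_dcj(m1, c(moves2$a1[j], moves2$b1[j]),
                      c(moves2$a2[j], moves2$b2[j]), moves2$choice[j])
      if (count_breakpoints(m2, blue) == 0 && count_breakpoints(blue, m2) == 0) {
        found <- TRUE
        break
      }
    }
    if (found) break
  }
  expect_true(found)
})

test_that("dcj_moves enumerates n(n-1) moves, each changing the matching", {
  for (case in list(list(ch = list(1), circ = TRUE, f = 2L, n = 2L),
                    list(ch = list(c(1, 2, 3)), circ = FALSE, f = 0L, n = 4L))) {
    g <- augment_genome(build_genome(case$ch, circular = case$circ), f = case$f)
    moves <- dcj_moves(g)
    expect_equal(nrow(moves), case$n * (case$n - 1L))
    changed <- vapply(seq_len(nrow(moves)), function(i) {
      gi <- apply_dcj(g, c(moves$a1[i], moves$b1[i]),
                      c(moves$a2[i], moves$b2[i]), moves$choice[i])
      !dcjmoments:::genomes_identical(gi, g)
    }, logical(1))
    expect_true(all(changed))
  }
  g10 <- random_genome(g = 6, telomeres = 4, f = 4, seed = 1)  # n = 10
  expect_equal(genome_params(g10)$n, 10L)
  expect_equal(nrow(dcj_moves(g10)), 90L)
})

test_that("breakpoint counting matches brute-force set difference", {
  expect_equal(count_breakpoints(fig_red(), fig_blue()), 2L)
  expect_equal(count_breakpoints(fig_red(), fig_red()), 0L)
  # small case by explicit adjacency sets: g1 g2 g3 vs g2 g1 g3
  g1 <- build_genome(c(1, 2, 3))
  g2 <- build_genome(c(2, 1, 3))
  adj_set <- function(g) {
    adj <- adjacencies(g)
    paste(adj$v1[adj$kind == "observed"], adj$v2[adj$kind == "observed"])
  }
  expect_equal(count_breakpoints(g1, g2),
               length(setdiff(adj_set(g1), adj_set(g2))))
  # symmetry when observed adjacency counts agree
  expect_equal(count_breakpoints(g1, g2), count_breakpoints(g2, g1))
})

test_that("random_genome hits requested counts and is seed-deterministic", {
  g <- random_genome(g = 980, telomeres = 40, f = 10, seed = 3)
  p <- genome_params(g)
  expect_equal(p$a, 960L)
  expect_equal(p$n, 2L * 980L - 960L + 5L)
  expect_perfect_matching(g)

  empty <- random_genome(g = 5, telomeres = 10, seed = 1)
  expect_equal(genome_params(empty)$a, 0L)

  expect_true(dcjmoments:::genomes_identical(
    random_genome(50, 6, 2, seed = 11), random_genome(50, 6, 2, seed = 11)))
  expect_error(random_genome(10, telomeres = 3), "even")
})

test_that("DCJ trajectories preserve the matching and the vertex budget", {
  g0 <- random_genome(g = 15, telomeres = 6, f = 2, seed = 4)
  nonobs0 <- sum(adjacencies(g0)$kind != "observed")
  g <- g0
  set.seed(42)
  for (step in 1:40) {
    adj <- adjacencies(g)
    pick <- sample(nrow(adj), 2)
    g <- apply_dcj(g, c(adj$v1[pick[1]], adj$v2[pick[1]]),
                   c(adj$v1[pick[2]], adj$v2[pick[2]]),
                   choice = sample(2, 1))
    expect_perfect_matching(g)
  }
  # telomeric + fictional vertex count never varies
  expect_equal(length(g$mate), length(g0$mate))
  expect_equal(sum(adjacencies(g)$kind != "observed") >= 0, TRUE)
  nonobs_vertices <- function(gen) length(gen$mate) - 2L * gen$g
  expect_equal(nonobs_vertices(g), nonobs_vertices(g0))
})
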