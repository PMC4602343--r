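# Shared fixtures: the three-gene worked example (one linear chromosome read
# g1 g2 g3 in the first genome and g3 g2 g1 in the second) and small helpers.

fig_red <- function() build_genome(c(1, 2, 3), name = "red")
fig_blue <- function() build_genome(c(3, 2, 1), name = "blue")

# all bijections between the non-observed vertices of two augmented genomes,
# as correspondence data frames (for exhaustive search over closures)
all_correspondences <- function(genome1, genome2) {
  nv <- length(genome1$mate)
  extra <- setdiff(seq_len(nv), seq_len(2L * genome1$g))
  if (length(extra) == 0) return(list(NULL))
  perms <- dcjmoments:::all_permutations(length(extra))
  lapply(perms, function(p) data.frame(from = extra, to = extra[p]))
}

# validity of an augmented genome's matching
expect_perfect_matching <- function(genome) {
  mate <- genome$mate
  expect_true(all(mate >= 1 & mate <= length(mate)))
  expect_true(all(mate[mate] == seq_along(mate)))
  expect_true(all(mate != seq_along(mate)))
}
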