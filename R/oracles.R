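# Brute-force oracles over small state spaces, in exact arithmetic.
#
# These are deliberately independent of the closed-form implementations they
# validate: the transposition walk is evolved exactly over integer-partition
# (cycle-type) states, cross-checked against literal enumeration of the
# symmetric group; the DCJ chain is evolved exactly over all perfect
# matchings.  All probability weights are big-integer numerators over the
# common denominator (moves per step)^k.

# ---- integer partitions ----------------------------------------------------

partitions_of <- function(n, max_part = n) {
  if (n == 0) return(list(integer()))
  out <- list()
  for (p in seq(min(n, max_part), 1)) {
    for (rest in partitions_of(n - p, p)) {
      out <- c(out, list(c(p, rest)))
    }
  }
  out
}

part_key <- function(p) paste(p, collapse = ",")

# Transition table of the random transposition walk on cycle types: from each
# partition, integer counts (out of choose(n, 2)) of moves to each successor.
# A transposition with its two elements in distinct cycles of sizes i and j
# merges them; with both elements in one cycle of size i it splits that cycle
# into sizes (s, i - s), where s is the cyclic distance between the elements.
transposition_partition_transitions <- function(n) {
  key <- paste0("tpt_", n)
  if (!is.null(the[[key]])) return(the[[key]])
  parts <- partitions_of(n)
  keys <- vapply(parts, part_key, "")
  index <- setNames(seq_along(parts), keys)
  trans <- vector("list", length(parts))
  for (si in seq_along(parts)) {
    p <- parts[[si]]
    sizes <- sort(unique(p))
    mult <- vapply(sizes, function(s) sum(p == s), 0L)
    to <- integer(); cnt <- numeric()
    emit <- function(newp, count) {
      k <- index[[part_key(sort(newp, decreasing = TRUE))]]
      to <<- c(to, k); cnt <<- c(cnt, count)
    }
    # merges across two distinct cycles
    for (ii in seq_along(sizes)) {
      i <- sizes[ii]
      if (mult[ii] >= 2) {
        newp <- p[-c(which(p == i)[1:2])]
        emit(c(newp, 2L * i), choose(mult[ii], 2) * i * i)
      }
      for (jj in seq_along(sizes)) {
        j <- sizes[jj]
        if (j <= i) next
        newp <- p[-c(which(p == i)[1], which(p == j)[1])]
        emit(c(newp, i + j), i * mult[ii] * j * mult[jj])
      }
    }
    # splits within one cycle
    for (ii in seq_along(sizes)) {
      i <- sizes[ii]
      if (i < 2) next
      base <- p[-which(p == i)[1]]
      for (s in seq_len(i %/% 2)) {
        count <- if (s < i - s) i else i / 2
        emit(c(base, s, i - s), count * mult[ii])
      }
    }
    agg <- tapply(cnt, to, sum)
    trans[[si]] <- list(to = as.integer(names(agg)), count = as.numeric(agg))
  }
  res <- list(parts = parts, index = index, trans = trans)
  the[[key]] <- res
  res
}

# Evolve the exact cycle-type distribution; returns per-step E(cycles) as
# exact rationals with denominator choose(n,2)^k.
transposition_cycle_curve_exact <- function(n, k_max) {
  stopifnot(n >= 2, n <= 10, k_max >= 0, k_max <= 60)
  tp <- transposition_partition_transitions(n)
  nparts <- length(tp$parts)
  npieces <- vapply(tp$parts, length, 0L)
  moves <- choose(n, 2)
  w <- vector("list", nparts)
  start <- tp$index[[part_key(rep(1L, n))]]
  w[[start]] <- bi(1)
  nums <- vector("list", k_max + 1)
  dens <- vector("list", k_max + 1)
  expectation_num <- function(w) {
    acc <- bi(0)
    for (si in seq_len(nparts)) {
      if (!is.null(w[[si]])) acc <- bi_add(acc, bi_mul_s(w[[si]], npieces[si]))
    }
    acc
  }
  conservation <- function(w, k) {
    tot <- bi(0)
    for (si in seq_len(nparts)) if (!is.null(w[[si]])) tot <- bi_add(tot, w[[si]])
    if (!bi_eq(tot, bi_pow_s(moves, k))) {
      stop("oracle probability weights do not sum to one at step ", k)
    }
  }
  nums[[1]] <- expectation_num(w); dens[[1]] <- bi(1)
  for (k in seq_len(k_max)) {
    w2 <- vector("list", nparts)
    for (si in seq_len(nparts)) {
      if (is.null(w[[si]])) next
      tr <- tp$trans[[si]]
      for (ti in seq_along(tr$to)) {
        contrib <- bi_mul_s(w[[si]], tr$count[ti])
        dst <- tr$to[ti]
        w2[[dst]] <- if (is.null(w2[[dst]])) contrib else bi_add(w2[[dst]], contrib)
      }
    }
    w <- w2
    conservation(w, k)
    nums[[k + 1]] <- expectation_num(w)
    dens[[k + 1]] <- bi_pow_s(moves, k)
  }
  list(num = nums, den = dens,
       value = mapply(bi_ratio, nums, dens))
}

#' Exact expected cycle count of the random transposition walk
#'
#' Evolves the exact probability distribution over cycle types (integer
#' partitions of `n`) of a permutation obtained from the identity by `k`
#' uniformly random transpositions, in exact big-integer arithmetic, and
#' returns the expected number of cycles.  This is the independent reference
#' against which the closed-form expected-cycles formula
#' ([eh_expected_cycles()]) is validated on small instances.
#'
#' @param n Permutation size, `2 <= n <= 10` (the partition state space must
#'   stay enumerable).
#' @param k Number of transpositions, `0 <= k <= 60`.
#' @return An exact rational object (fields `num`, `den` as big-integer limb
#'   vectors, `value` as double).
#' @examples
#' exact_transposition_cycle_expectation(3, 1)$value  # 2: any first move merges
#' @export
exact_transposition_cycle_expectation <- function(n, k) {
  curve <- transposition_cycle_curve_exact(n, k)
  new_exact_rational(curve$num[[k + 1]], curve$den[[k + 1]])
}

#' @rdname exact_transposition_cycle_expectation
#' @param k_max Largest step; the full curve `k = 0..k_max` is returned.
#' @return For `transposition_cycle_curve()`: a tibble with columns `k` and
#'   `expected_cycles` (doubles converted from the exact rationals).
#' @export
transposition_cycle_curve <- function(n, k_max) {
  curve <- transposition_cycle_curve_exact(n, k_max)
  tibble::tibble(k = 0:k_max, expected_cycles = curve$value)
}

# ---- literal symmetric-group enumeration (guards the partition chain) ------

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_permutations(n - 1)) {
    for (pos in 0:(n - 1)) {
      out <- c(out, list(append(p, n, after = pos)))
    }
  }
  out
}

perm_cycle_count <- function(p) {
  n <- length(p)
  seen <- logical(n)
  cycles <- 0L
  for (v in seq_len(n)) {
    if (seen[v]) next
    cycles <- cycles + 1L
    w <- v
    while (!seen[w]) {
      seen[w] <- TRUE
      w <- p[w]
    }
  }
  cycles
}

# Same expectation computed by evolving the exact distribution over all n!
# permutations; n <= 5.  Used to guard the partition-chain derivation.
transposition_cycle_curve_enumerated <- function(n, k_max) {
  stopifnot(n >= 2, n <= 5, k_max >= 0, k_max <= 25)
  perms <- all_permutations(n)
  keys <- vapply(perms, paste, "", collapse = ",")
  index <- setNames(seq_along(perms), keys)
  cycles <- vapply(perms, perm_cycle_count, 0L)
  pairs <- utils::combn(n, 2)
  succ <- lapply(perms, function(p) {
    vapply(seq_len(ncol(pairs)), function(j) {
      q <- p
      q[pairs[, j]] <- q[rev(pairs[, j])]
      index[[paste(q, collapse = ",")]]
    }, 0L)
  })
  moves <- ncol(pairs)
  w <- vector("list", length(perms))
  w[[index[[paste(seq_len(n), collapse = ",")]]]] <- bi(1)
  expectation <- function(w, k) {
    acc <- bi(0)
    for (si in seq_along(w)) {
      if (!is.null(w[[si]])) acc <- bi_add(acc, bi_mul_s(w[[si]], cycles[si]))
    }
    bi_ratio(acc, bi_pow_s(moves, k))
  }
  out <- numeric(k_max + 1)
  out[1] <- expectation(w, 0)
  for (k in seq_len(k_max)) {
    w2 <- vector("list", length(perms))
    for (si in seq_along(w)) {
      if (is.null(w[[si]])) next
      for (dst in succ[[si]]) {
        w2[[dst]] <- if (is.null(w2[[dst]])) w[[si]] else bi_add(w2[[dst]], w[[si]])
      }
    }
    w <- w2
    out[k + 1] <- expectation(w, k)
  }
  tibble::tibble(k = 0:k_max, expected_cycles = out)
}

# ---- exact DCJ chain over perfect matchings --------------------------------

all_matchings <- function(vertices) {
  if (length(vertices) == 0) return(list(integer(0)))
  v <- vertices[1]
  out <- list()
  for (w in vertices[-1]) {
    rest <- setdiff(vertices, c(v, w))
    for (m in all_matchings(rest)) {
      out <- c(out, list(rbind(c(v, w), m)))
    }
  }
  out
}

matching_key <- function(mat) {
  if (is.null(dim(mat))) mat <- matrix(mat, ncol = 2)
  ord <- order(mat[, 1])
  paste(t(mat[ord, , drop = FALSE]), collapse = ",")
}

#' Exact expected breakpoint count of the DCJ chain
#'
#' Builds the full transition structure of the uniform DCJ Markov chain over
#' all perfect matchings of `2n` vertices (a state space of `(2n-1)!!`
#' matchings) and evolves the exact distribution for `k` steps, starting from
#' the matching `{1,2}, {3,4}, ...` whose first `a` edges are designated
#' observed.  Returns the exact expected number of those observed start
#' adjacencies that are broken after `k` steps.
#'
#' @param n Total adjacency count, `2 <= n <= 4`.
#' @param a Number of observed adjacencies, `0 <= a <= n`.
#' @param k Step count, `0 <= k <= 20`.
#' @return An exact rational object (fields `num`, `den`, `value`).
#' @seealso [verify_breakpoint_closed_form()] for the exact comparison with
#'   the closed-form expectation.
#' @export
exact_breakpoint_expectation <- function(n, a, k) {
  curve <- breakpoint_curve_exact(n, a, k)
  new_exact_rational(curve$num[[k + 1]], curve$den[[k + 1]])
}

breakpoint_curve_exact <- function(n, a, k_max) {
  stopifnot(n >= 2, n <= 4, a >= 0, a <= n, k_max >= 0, k_max <= 20)
  mats <- all_matchings(seq_len(2L * n))
  keys <- vapply(mats, matching_key, "")
  index <- setNames(seq_along(mats), keys)
  # mate-vector form for fast breakpoint evaluation
  mate_of <- function(mat) {
    mate <- integer(2L * n)
    mate[mat[, 1]] <- mat[, 2]
    mate[mat[, 2]] <- mat[, 1]
    mate
  }
  mates <- lapply(mats, mate_of)
  start <- matrix(c(seq(1, 2 * n, by = 2), seq(2, 2 * n, by = 2)), ncol = 2)
  start_idx <- index[[matching_key(start)]]
  obs <- start[seq_len(a), , drop = FALSE]
  breakpoints <- vapply(mates, function(m) {
    sum(m[obs[, 1]] != obs[, 2])
  }, 0L)
  moves <- n * (n - 1)
  succ <- lapply(mats, function(mat) {
    dst <- integer(0)
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        A <- mat[i, 1]; B <- mat[i, 2]; C <- mat[j, 1]; D <- mat[j, 2]
        for (choice in 1:2) {
          new_i <- if (choice == 1) c(A, C) else c(A, D)
          new_j <- if (choice == 1) c(B, D) else c(B, C)
          m2 <- mat
          m2[i, ] <- new_i; m2[j, ] <- new_j
          m2 <- t(apply(m2, 1, sort))
          dst <- c(dst, index[[matching_key(m2)]])
        }
      }
    }
    agg <- table(dst)
    list(to = as.integer(names(agg)), count = as.numeric(agg))
  })
  w <- vector("list", length(mats))
  w[[start_idx]] <- bi(1)
  expectation_num <- function(w) {
    acc <- bi(0)
    for (si in seq_along(w)) {
      if (!is.null(w[[si]]) && breakpoints[si] > 0) {
        acc <- bi_add(acc, bi_mul_s(w[[si]], breakpoints[si]))
      }
    }
    acc
  }
  nums <- vector("list", k_max + 1); dens <- vector("list", k_max + 1)
  nums[[1]] <- expectation_num(w); dens[[1]] <- bi(1)
  for (k in seq_len(k_max)) {
    w2 <- vector("list", length(mats))
    for (si in seq_along(w)) {
      if (is.null(w[[si]])) next
      tr <- succ[[si]]
      for (ti in seq_along(tr$to)) {
        contrib <- bi_mul_s(w[[si]], tr$count[ti])
        dst <- tr$to[ti]
        w2[[dst]] <- if (is.null(w2[[dst]])) contrib else bi_add(w2[[dst]], contrib)
      }
    }
    w <- w2
    tot <- bi(0)
    for (si in seq_along(w)) if (!is.null(w[[si]])) tot <- bi_add(tot, w[[si]])
    if (!bi_eq(tot, bi_pow_s(moves, k))) {
      stop("oracle probability weights do not sum to one at step ", k)
    }
    nums[[k + 1]] <- expectation_num(w)
    dens[[k + 1]] <- bi_pow_s(moves, k)
  }
  list(num = nums, den = dens, value = mapply(bi_ratio, nums, dens))
}

#' Exact rational identity between the DCJ chain and the closed form
#'
#' Checks, in exact integer arithmetic, that the expected breakpoint count of
#' the exhaustive DCJ chain equals the closed-form expectation
#' `a (2n-2)/(2n-1) (1 - (1 - 1/(n-1) - 1/n)^k)` for every `k = 0..k_max`.
#' Both sides are cleared of denominators: with `D = n(n-1)` and
#' `m = n^2 - 3n + 1`, exact equality holds iff
#' `num_k (2n-1) == a (2n-2) (D^k - m^k)` where `num_k` is the chain
#' expectation's numerator over `D^k`.
#'
#' @inheritParams exact_breakpoint_expectation
#' @param k_max Largest step checked.
#' @return Logical vector of length `k_max + 1`, one exact comparison per `k`.
#' @export
verify_breakpoint_closed_form <- function(n, a, k_max) {
  curve <- breakpoint_curve_exact(n, a, k_max)
  D <- n * (n - 1)
  m <- n^2 - 3 * n + 1  # >= 0 for n >= 3
  vapply(0:k_max, function(k) {
    lhs <- bi_mul_s(curve$num[[k + 1]], 2 * n - 1)
    Dk <- bi_pow_s(D, k)
    rhs_core <- if (m >= 0) {
      bi_sub(Dk, bi_pow_s(m, k))
    } else if (k %% 2 == 0) {
      bi_sub(Dk, bi_pow_s(-m, k))   # m^k = |m|^k for even k
    } else {
      bi_add(Dk, bi_pow_s(-m, k))   # m^k = -|m|^k for odd k
    }
    bi_eq(lhs, bi_mul_s(rhs_core, a * (2 * n - 2)))
  }, logical(1))
}

# ---- Monte-Carlo component counts ------------------------------------------

#' Monte-Carlo component counts of the random multigraph
#'
#' Simulates the random multigraph process (starting from `n` isolated
#' vertices, each step adds one edge drawn uniformly over unordered pairs of
#' distinct vertices, parallel edges allowed) and reports the mean component
#' count after `k` edges with a normal-approximation confidence interval.
#' Graph construction and component counting go through igraph, keeping this
#' sampler independent of the package's own union-find process
#' ([random_graph_trajectory()]).
#'
#' @param n Vertex count.
#' @param k Number of edges added.
#' @param replicates Number of independent graphs (>= 100).
#' @param seed Optional integer seed.
#' @param conf_level Confidence level for the interval (default 0.99).
#' @return A one-row tibble: `n`, `k`, `replicates`, `mean`, `sd`, `se`,
#'   `conf_level`, `ci_lower`, `ci_upper`.
#' @export
montecarlo_components <- function(n, k, replicates = 1000, seed = NULL,
                                  conf_level = 0.99) {
  stopifnot(n >= 2, k >= 0, replicates >= 100)
  with_seed(seed, {
    comps <- vapply(seq_len(replicates), function(r) {
      if (k == 0) return(as.numeric(n))
      v1 <- sample.int(n, k, replace = TRUE)
      v2 <- sample.int(n - 1L, k, replace = TRUE)
      v2 <- v2 + (v2 >= v1)
      gr <- igraph::make_graph(rbind(v1, v2), n = n, directed = FALSE)
      igraph::components(gr)$no
    }, 0)
    z <- qnorm(1 - (1 - conf_level) / 2)
    m <- mean(comps); s <- sd(comps); se <- s / sqrt(replicates)
    tibble::tibble(n = n, k = k, replicates = replicates, mean = m, sd = s,
                   se = se, conf_level = conf_level,
                   ci_lower = m - z * se, ci_upper = m + z * se)
  })
}
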