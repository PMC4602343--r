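# The uniform DCJ Markov chain simulator, with the optional coupled random
# transposition walk and the random multigraph process.

#' Simulate the uniform DCJ Markov chain
#'
#' Starting from an augmented genome with `n` adjacencies, each step draws
#' one of the `n(n-1)` equiprobable DCJ operations (an unordered adjacency
#' pair, uniform over `choose(n,2)`, plus a fair rewiring choice) and applies
#' it.  Per-step statistics are recorded against the starting genome.
#'
#' When `couple = TRUE` the simulator also runs the coupled random
#' transposition walk: every adjacency carries a label in `1..n` (a bijection
#' at all times); when a DCJ cuts the adjacencies labelled `x` and `y`, the
#' transposition `(x y)` is applied to the permutation.  After a DCJ that
#' splits a real-breakpoint-graph cycle, the two new adjacencies inherit `x`
#' and `y` so as to respect the cycles — each goes to the label whose
#' permutation cycle contains the labels of the adjacencies sharing its
#' breakpoint-graph cycle; in the merge and leave-unchanged cases (where the
#' choice is arbitrary) the new adjacency with the smaller minimum vertex id
#' takes `min(x, y)`.  The walk uses the same draws as the DCJ chain, so the
#' coupling adds no randomness.
#'
#' @param genome An augmented `dcj_genome` (see [augment_genome()],
#'   [random_genome()]).
#' @param k_max Number of DCJ steps (`>= 0`).
#' @param seed Optional integer seed; same seed, same trajectory.
#' @param record Character vector of per-step statistics to record, from
#'   `"breakpoints"` (count against the start genome), `"real_cycles"`
#'   (cycles of the real breakpoint graph against the start, identity vertex
#'   correspondence), `"obs_cycles"` (cycles of the observed breakpoint
#'   graph, padded to `n` where the budget allows; recorded together with
#'   `obs_distance`, that graph's parsimony DCJ distance) and
#'   `"perm_cycles"` (the coupled walk).
#' @param couple If `TRUE`, adds `"perm_cycles"` (and `"real_cycles"`, which
#'   the label bookkeeping needs) to `record`.
#' @return A tibble of class `dcj_trajectory` with column `k = 0..k_max` and
#'   one column per recorded statistic; attributes `params` (the model
#'   parameter tibble), `seed`, and `final_genome`.
#' @examples
#' g0 <- random_genome(g = 20, telomeres = 4, seed = 1)
#' tr <- simulate_dcj(g0, k_max = 10, seed = 2, couple = TRUE)
#' tail(tr, 3)
#' @export
simulate_dcj <- function(genome, k_max, seed = NULL,
                         record = c("breakpoints", "real_cycles"),
                         couple = FALSE) {
  stopifnot(inherits(genome, "dcj_genome"))
  if (!genome$augmented) stop("simulate_dcj() requires an augmented genome")
  k_max <- as.integer(k_max)
  if (k_max < 0) stop("`k_max` must be non-negative")
  record <- match.arg(record, c("breakpoints", "real_cycles", "obs_cycles",
                                "perm_cycles"), several.ok = TRUE)
  if (couple) record <- union(record, c("real_cycles", "perm_cycles"))
  couple <- "perm_cycles" %in% record
  rec_b <- "breakpoints" %in% record
  rec_real <- "real_cycles" %in% record || couple
  rec_obs <- "obs_cycles" %in% record

  m0 <- genome$mate
  nv <- length(m0)
  n <- nv %/% 2L
  if (n < 2) stop("need n >= 2 adjacencies to perform DCJs")
  g2 <- 2L * genome$g

  with_seed(seed, {
    mate <- m0
    e1 <- which(m0 > seq_len(nv))
    edges <- cbind(e1, m0[e1])
    a <- sum(edges[, 1] <= g2 & edges[, 2] <= g2)
    shared <- a
    pi_ <- seq_len(n)
    labels <- seq_len(n)
    Cy <- n
    BCy <- n

    B_out <- if (rec_b) integer(k_max + 1)
    real_out <- if (rec_real) integer(k_max + 1)
    obs_out <- if (rec_obs) integer(k_max + 1)
    obsd_out <- if (rec_obs) integer(k_max + 1)
    perm_out <- if (couple) integer(k_max + 1)
    if (rec_b) B_out[1] <- 0L
    if (rec_real) real_out[1] <- n
    if (couple) perm_out[1] <- n
    if (rec_obs) {
      dec <- obs_graph_from_mates(m0, mate, genome$g, n)
      obs_out[1] <- length(dec$lengths)
      obsd_out[1] <- dec$n - length(dec$lengths)
    }

    for (k in seq_len(k_max)) {
      rows <- sample.int(n, 2L)
      i <- rows[1]; j <- rows[2]
      choice1 <- runif(1) < 0.5
      A <- edges[i, 1]; B <- edges[i, 2]
      C <- edges[j, 1]; D <- edges[j, 2]
      if (A <= g2 && B <= g2 && m0[A] == B) shared <- shared - 1L
      if (C <= g2 && D <= g2 && m0[C] == D) shared <- shared - 1L
      if (choice1) {
        p1 <- A; p2 <- C; q1 <- B; q2 <- D
      } else {
        p1 <- A; p2 <- D; q1 <- B; q2 <- C
      }
      edges[i, 1] <- p1; edges[i, 2] <- p2
      edges[j, 1] <- q1; edges[j, 2] <- q2
      mate[p1] <- p2; mate[p2] <- p1
      mate[q1] <- q2; mate[q2] <- q1
      if (p1 <= g2 && p2 <= g2 && m0[p1] == p2) shared <- shared + 1L
      if (q1 <= g2 && q2 <= g2 && m0[q1] == q2) shared <- shared + 1L

      delta <- 0L
      if (rec_real) {
        newBCy <- length(union_cycle_lengths_cpp(m0, mate))
        delta <- newBCy - BCy
        BCy <- newBCy
      }
      if (couple) {
        x <- labels[i]; y <- labels[j]
        same <- perm_same_cycle_cpp(pi_, x, y)
        tmp <- pi_[x]; pi_[x] <- pi_[y]; pi_[y] <- tmp
        Cy <- Cy + (if (same) 1L else -1L)
        if (delta == 1L) {
          # fission: respect the cycles when handing x and y to the two new
          # adjacencies
          comp <- union_cycle_membership_cpp(m0, mate)
          in_x_cycle <- perm_cycle_members_cpp(pi_, x)
          rows_i <- which(comp[edges[, 1]] == comp[p1])
          old_i <- labels[setdiff(rows_i, c(i, j))]
          decided <- FALSE
          if (length(old_i) > 0) {
            if (any(in_x_cycle[old_i])) {
              labels[i] <- x; labels[j] <- y
            } else {
              labels[i] <- y; labels[j] <- x
            }
            decided <- TRUE
          } else {
            rows_j <- which(comp[edges[, 1]] == comp[q1])
            old_j <- labels[setdiff(rows_j, c(i, j))]
            if (length(old_j) > 0) {
              if (any(in_x_cycle[old_j])) {
                labels[j] <- x; labels[i] <- y
              } else {
                labels[j] <- y; labels[i] <- x
              }
              decided <- TRUE
            }
          }
          if (!decided) {
            if (min(p1, p2) < min(q1, q2)) {
              labels[i] <- min(x, y); labels[j] <- max(x, y)
            } else {
              labels[i] <- max(x, y); labels[j] <- min(x, y)
            }
          }
        } else {
          # merge or leave-unchanged: assignment is arbitrary; fix it by ids
          if (min(p1, p2) < min(q1, q2)) {
            labels[i] <- min(x, y); labels[j] <- max(x, y)
          } else {
            labels[i] <- max(x, y); labels[j] <- min(x, y)
          }
        }
      }

      if (rec_b) B_out[k + 1] <- a - shared
      if (rec_real) real_out[k + 1] <- BCy
      if (couple) perm_out[k + 1] <- Cy
      if (rec_obs) {
        dec <- obs_graph_from_mates(m0, mate, genome$g, n)
        obs_out[k + 1] <- length(dec$lengths)
        obsd_out[k + 1] <- dec$n - length(dec$lengths)
      }
    }

    out <- tibble::tibble(k = 0:k_max)
    if (rec_b) out$breakpoints <- B_out
    if (rec_obs) {
      out$obs_cycles <- obs_out
      out$obs_distance <- obsd_out
    }
    if (rec_real) out$real_cycles <- real_out
    if (couple) out$perm_cycles <- perm_out
    final <- genome
    final$mate <- mate
    attr(out, "params") <- model_params(genome$g, a, genome$f)
    attr(out, "seed") <- seed
    attr(out, "final_genome") <- final
    class(out) <- c("dcj_trajectory", class(out))
    out
  })
}

#' Simulate the random multigraph component process
#'
#' Starting from `n` isolated vertices, each step adds one edge drawn
#' uniformly over the `choose(n,2)` unordered pairs of distinct vertices
#' (parallel edges allowed), and the number of connected components is
#' recorded.  This is the coagulation-only companion of the DCJ chain:
#' components play the role of breakpoint-graph cycles.  Implemented with a
#' union-find structure, independently of the igraph-based Monte-Carlo
#' sampler used as its oracle ([montecarlo_components()]).
#'
#' @param n Vertex count (`n >= 2`).
#' @param k_max Number of edges added.
#' @param seed Optional integer seed.
#' @return A tibble with columns `k = 0..k_max` and `components`
#'   (non-increasing, starting at `n`).
#' @export
random_graph_trajectory <- function(n, k_max, seed = NULL) {
  n <- as.integer(n); k_max <- as.integer(k_max)
  stopifnot(n >= 2, k_max >= 0)
  with_seed(seed, {
    parent <- seq_len(n)
    find <- function(v) {
      while (parent[v] != v) {
        parent[v] <<- parent[parent[v]]
        v <- parent[v]
      }
      v
    }
    comp <- n
    out <- integer(k_max + 1)
    out[1] <- n
    for (k in seq_len(k_max)) {
      v1 <- sample.int(n, 1L)
      v2 <- sample.int(n - 1L, 1L)
      if (v2 >= v1) v2 <- v2 + 1L
      r1 <- find(v1); r2 <- find(v2)
      if (r1 != r2) {
        parent[r1] <- r2
        comp <- comp - 1L
      }
      out[k + 1] <- comp
    }
    tibble::tibble(k = 0:k_max, components = out)
  })
}
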