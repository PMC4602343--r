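# Method-of-moments estimators of the number of DCJ operations separating
# two genomes: analytic inversion of the breakpoint expectation, grid
# inversion of the transposition-cycle and graph-component expectations, the
# sequence-coding route, and the parsimony baseline.

new_estimate <- function(estimator, statistic, observed, k_hat, saturated,
                         a = NA_real_, n = NA_real_, N = NA_real_,
                         k_max = NA_integer_, extra = NULL) {
  out <- tibble::tibble(
    estimator = estimator, statistic = statistic, observed = observed,
    k_hat = k_hat, saturated = saturated, a = a, n = n, N = N, k_max = k_max
  )
  if (!is.null(extra)) out <- dplyr::bind_cols(out, extra)
  class(out) <- c("dcj_estimate", class(out))
  out
}

#' Analytic DCJ-count estimator from breakpoints
#'
#' Inverts the closed-form breakpoint expectation: from an observed
#' breakpoint count `B` between two genomes with `a` observed adjacencies and
#' `n` total adjacencies,
#' \deqn{\hat{k} = \frac{\log\left(1 - \frac{B(2n-1)}{a(2n-2)}\right)}
#'   {\log\left(1 - \frac{1}{n-1} - \frac{1}{n}\right)}.}
#' When `B` reaches the asymptote `a(2n-2)/(2n-1)` the statistic carries no
#' signal (saturation, expected once `k` is of order `n log n`); the result
#' is then flagged rather than raised, so batch experiments run to
#' completion.
#'
#' @param B Observed breakpoint count, `0 <= B <= a`; non-integer values are
#'   accepted (for inverting replicate averages).
#' @param a Observed adjacency count of the first genome.
#' @param n Total adjacency count (requires a choice of the fictional-vertex
#'   parameter `f`; see [choose_f()]).
#' @return A one-row `dcj_estimate` tibble: `estimator`, `statistic`,
#'   `observed`, `k_hat` (`Inf` when saturated), `saturated`, `a`, `n`.
#' @examples
#' B <- expected_breakpoints(a = 980, n = 1020, k = 500)
#' dcj_tilde(B, a = 980, n = 1020)$k_hat  # 500 up to round-off
#' @export
dcj_tilde <- function(B, a, n) {
  if (n < 2) stop("`n` must be at least 2")
  if (length(B) != 1 || is.na(B) || B < 0 || B > a) {
    stop("`B` must be a single value in [0, a]")
  }
  ratio <- 1 - B * (2 * n - 1) / (a * (2 * n - 2))
  if (ratio <= 0) {
    return(new_estimate("dcj_tilde", "breakpoints", B, Inf, TRUE, a = a, n = n))
  }
  k_hat <- log(ratio) / log(1 - 1 / (n - 1) - 1 / n)
  new_estimate("dcj_tilde", "breakpoints", B, k_hat, FALSE, a = a, n = n)
}

#' Choose the fictional-vertex parameter f
#'
#' The fictional-vertex count `f` must let one genome be transformed into the
#' other: a DCJ never changes the number of telomeric plus fictional
#' vertices, so `f` has to absorb the telomere-count difference, giving the
#' lower bound `2 |a1 - a2|`.  The upper end of the bracket follows the
#' equilibrium telomere scale of uniform-on-genome models and is left
#' configurable (`upper`, capped at `2g`); the default returns the lower
#' bound, rounded up to even.
#'
#' @param a1,a2 Observed adjacency counts of the two genomes.
#' @param g Gene count (used only to cap `upper`).
#' @param upper Optional requested value; clamped into the bracket and
#'   rounded to even.
#' @return An even integer `f`.
#' @export
choose_f <- function(a1, a2, g = NULL, upper = NULL) {
  lower <- 2L * abs(as.integer(a1) - as.integer(a2))
  if (is.null(upper)) return(lower)
  f <- max(lower, as.integer(upper))
  if (!is.null(g)) f <- min(f, 2L * as.integer(g))
  f + f %% 2L
}

#' Grid inversion of an expectation curve
#'
#' Returns the integer `k` in `0..k_max` whose expected statistic is closest
#' to the observed value, ties broken toward the smallest `k`.  This is the
#' numerical inversion used for expectation curves without a closed-form
#' inverse (expected transposition cycles, expected graph components).
#'
#' @param observed Observed statistic (non-integer values accepted).
#' @param expectation Either a function of `k` or a numeric vector of
#'   expectations at `k = 0..k_max`.
#' @param k_max Largest `k` searched (unused when `expectation` is a vector).
#' @return A one-row `dcj_estimate` tibble with `estimator = "grid"`.
#' @export
grid_invert <- function(observed, expectation, k_max = NULL) {
  if (is.function(expectation)) {
    if (is.null(k_max) || k_max < 0) stop("`k_max` must be a non-negative integer")
    values <- expectation(0:k_max)
  } else {
    values <- as.numeric(expectation)
    k_max <- length(values) - 1L
  }
  gap <- abs(observed - values)
  k_hat <- which.min(gap) - 1L  # which.min takes the first (smallest k) tie
  new_estimate("grid", "statistic", observed, as.numeric(k_hat), FALSE,
               k_max = as.integer(k_max))
}

#' Transposition-cycle (EH) and graph-component (BD) estimators
#'
#' Both estimators read the observed breakpoint-graph cycle count (from the
#' observed graph, padded to `n`) and grid-invert an expectation curve:
#' `estimate_eh()` against the expected cycle count of a permutation after
#' `k` random transpositions ([eh_expected_cycles()]), `estimate_bd()`
#' against the expected component count of a random multigraph after `k`
#' edges ([bd_expected_components()]), the latter per the identification of
#' breakpoint-graph cycles with graph components.
#'
#' @param cycles Observed cycle count of the breakpoint graph (see
#'   [observed_breakpoint_graph()]).
#' @param n Total adjacency count.
#' @param k_max Largest `k` of the inversion grid.
#' @param table Optional precomputed expectation vector at `k = 0..k_max`
#'   (saves recomputation in sweeps).
#' @return A one-row `dcj_estimate` tibble.
#' @export
estimate_eh <- function(cycles, n, k_max, table = NULL) {
  if (is.null(table)) table <- eh_expected_cycles(n, 0:k_max)
  est <- grid_invert(cycles, table)
  est$estimator <- "eh"
  est$statistic <- "obs_cycles"
  est$n <- n
  est
}

#' @rdname estimate_eh
#' @export
estimate_bd <- function(cycles, n, k_max, table = NULL) {
  if (is.null(table)) table <- bd_expected_components(n, 0:k_max)
  est <- grid_invert(cycles, table)
  est$estimator <- "bd"
  est$statistic <- "obs_cycles"
  est$n <- n
  est
}

#' Sequence-coding estimator of the DCJ count
#'
#' Codes the genomes as aligned binary adjacency-presence sequences of length
#' `N`, so that the observed difference count is `D = 2B` (each breakpoint is
#' seen from both genomes), inverts the single-site substitution expectation
#' at `D`, and rescales substitution steps to DCJ steps through the exact
#' sequence-coding correspondence (see [proposition_mapping()]).  With the
#' exact length `N = 4a(2n-2)/(2n-1)` this reproduces [dcj_tilde()]; shorter
#' sequences (e.g. `N = 2n`, coding only adjacencies present in either
#' genome) overestimate the distance, longer ones (e.g. `N = n(2n-1)`, coding
#' all possible adjacencies) underestimate it.
#'
#' @inheritParams dcj_tilde
#' @param N Sequence length: one of `"exact"`, `"4a"`, `"2n"`, `"n(2n-1)"`,
#'   or a positive number.
#' @return A one-row `dcj_estimate` tibble with additional column `k_s` (the
#'   substitution-step estimate before rescaling).
#' @export
seq_coding_estimate <- function(B, a, n, N = "exact") {
  if (n < 2) stop("`n` must be at least 2")
  if (length(B) != 1 || is.na(B) || B < 0 || B > a) {
    stop("`B` must be a single value in [0, a]")
  }
  N_val <- if (is.numeric(N)) {
    as.numeric(N)
  } else {
    switch(match.arg(N, c("exact", "4a", "2n", "n(2n-1)")),
           "exact" = 4 * a * (2 * n - 2) / (2 * n - 1),
           "4a" = 4 * a,
           "2n" = 2 * n,
           "n(2n-1)" = n * (2 * n - 1))
  }
  if (N_val < 2) stop("`N` must be at least 2")
  D <- 2 * B
  if (D >= N_val / 2) {
    return(new_estimate("seq_coding", "breakpoints", B, Inf, TRUE,
                        a = a, n = n, N = N_val,
                        extra = tibble::tibble(k_s = Inf)))
  }
  k_s <- log(1 - 2 * D / N_val) / log(1 - 2 / N_val)
  k_hat <- k_s * log(1 - 2 / N_val) / log(1 - 1 / n - 1 / (n - 1))
  new_estimate("seq_coding", "breakpoints", B, k_hat, FALSE,
               a = a, n = n, N = N_val,
               extra = tibble::tibble(k_s = k_s))
}

#' Parsimony DCJ distance as an estimator
#'
#' The minimum number of DCJs between two genomes: `n - cycles` on the
#' observed breakpoint graph.  A good estimate of the true number of events
#' only while rearrangements rarely reuse breakpoint regions (roughly
#' `k < n/2`); beyond that it systematically underestimates.
#'
#' @param genome1,genome2 Two `dcj_genome`s on the same gene set.
#' @return A one-row `dcj_estimate` tibble.
#' @export
parsimony_distance <- function(genome1, genome2) {
  bg <- observed_breakpoint_graph(genome1, genome2)
  new_estimate("parsimony", "dcj_distance", dcj_distance(bg),
               as.numeric(dcj_distance(bg)), FALSE, n = bg$n)
}

#' @export
print.dcj_estimate <- function(x, ...) {
  cat(sprintf("<dcj_estimate: %s> observed %s = %.6g, k_hat = %.6g%s\n",
              x$estimator[1], x$statistic[1], x$observed[1], x$k_hat[1],
              if (any(x$saturated)) " (saturated)" else ""))
  invisible(x)
}

#' Tidy methods for estimate objects
#'
#' @param x A `dcj_estimate`.
#' @param ... Unused.
#' @return `tidy()` returns the estimate as a plain tibble; `glance()` a
#'   one-row summary (`estimator`, `k_hat`, `saturated`).
#' @export
tidy.dcj_estimate <- function(x, ...) {
  class(x) <- setdiff(class(x), "dcj_estimate")
  x
}

#' @rdname tidy.dcj_estimate
#' @export
glance.dcj_estimate <- function(x, ...) {
  tibble::tibble(estimator = x$estimator, k_hat = x$k_hat,
                 saturated = x$saturated)
}
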