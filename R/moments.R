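# Closed-form and recursive first-moment formulas for the uniform DCJ model
# and its companion processes (binary-sequence substitutions, random
# transpositions, random multigraphs).

#' Expected breakpoints after k random DCJ operations
#'
#' Exact closed form for the expected number of breakpoints between an
#' augmented genome `G` and the genome obtained from it by `k` uniformly
#' random DCJ operations:
#' \deqn{E(B_k) = a \frac{2n-2}{2n-1}\left(1 - \left(1 - \frac{1}{n-1} -
#'   \frac{1}{n}\right)^k\right),}
#' where `a` is the observed adjacency count and `n` the total adjacency
#' count.  The curve is strictly increasing and concave in `k` with asymptote
#' `a (2n-2)/(2n-1)`.
#'
#' @param a Observed adjacency count (`a >= 0`).
#' @param n Total adjacency count (`n >= 2`).
#' @param k Step count(s), non-negative; vectorized.
#' @return Numeric vector of expectations, one per `k`.
#' @examples
#' expected_breakpoints(a = 980, n = 1020, k = c(0, 50, 500))
#' @seealso [breakpoint_recurrence()] for the step-by-step recurrence,
#'   [dcj_tilde()] for the analytic inversion.
#' @export
expected_breakpoints <- function(a, n, k) {
  if (n < 2) stop("`n` must be at least 2")
  if (a < 0) stop("`a` must be non-negative")
  if (any(k < 0)) stop("`k` must be non-negative")
  a * (2 * n - 2) / (2 * n - 1) * (1 - (1 - 1 / (n - 1) - 1 / n)^k)
}

#' Breakpoint expectation by recurrence
#'
#' Iterates the per-adjacency survival recurrence
#' `P_k = P_{k-1} (q_u - p_s) + p_s` from `P_0 = 0`, with cut probability
#' `p_s = 2/n` and no-reform probability `q_u = 1 - 1/(n(n-1))`, and returns
#' `a P_k`.  Algebraically identical to [expected_breakpoints()] (since
#' `2/n + 1/(n(n-1)) = 1/n + 1/(n-1)`); kept as an independent computational
#' route.
#'
#' @inheritParams expected_breakpoints
#' @return Numeric vector of expectations, one per `k`.
#' @export
breakpoint_recurrence <- function(a, n, k) {
  if (n < 2) stop("`n` must be at least 2")
  if (any(k < 0)) stop("`k` must be non-negative")
  p_s <- 2 / n
  q_u <- 1 - 1 / (n * (n - 1))
  k_max <- max(k)
  P <- numeric(k_max + 1)
  for (i in seq_len(k_max)) {
    P[i + 1] <- P[i] * (q_u - p_s) + p_s
  }
  a * P[k + 1]
}

#' Expected site differences under binary substitution models
#'
#' For a binary sequence of length `N` evolving by uniform single-site
#' substitutions, the expected number of sites differing from the start after
#' `k_s` steps is `(N/2)(1 - (1 - 2/N)^{k_s})`.  Under the four-by-four model
#' (each event substitutes four sites simultaneously, mirroring a DCJ's two
#' cut and two rejoined adjacencies) the change probability per site is
#' `4/N`, giving `(N/2)(1 - (1 - 8/N)^{k_s})`.
#'
#' @param N Sequence length (`N >= 2`; `N >= 8` for the four-by-four model).
#' @param k_s Substitution step count(s); vectorized; real values allowed
#'   (the formula extends continuously).
#' @return Numeric vector of expected differences.
#' @export
seq_expected_differences <- function(N, k_s) {
  if (N < 2) stop("`N` must be at least 2")
  (N / 2) * (1 - (1 - 2 / N)^k_s)
}

#' @rdname seq_expected_differences
#' @export
seq4_expected_differences <- function(N, k_s) {
  if (N < 8) stop("`N` must be at least 8 for the four-by-four model")
  (N / 2) * (1 - (1 - 8 / N)^k_s)
}

#' Exact sequence-coding of the DCJ breakpoint expectation
#'
#' The DCJ breakpoint expectation coincides with half the expected number of
#' differing sites of a binary sequence of the right length: with
#' `N = 4a(2n-2)/(2n-1)` (approximately `4a`) and
#' `k_s = k log(1 - 1/n - 1/(n-1)) / log(1 - (2n-1)/(4a(n-1)))`
#' (approximately `4ka/n`), `seq_expected_differences(N, k_s) / 2` equals
#' `expected_breakpoints(a, n, k)` exactly.
#'
#' @inheritParams expected_breakpoints
#' @return A tibble with one row per `k`: columns `k`, `N_exact`, `ks_exact`,
#'   `N_approx` (`4a`), `ks_approx` (`4ka/n`).
#' @export
proposition_mapping <- function(a, n, k) {
  if (n < 2) stop("`n` must be at least 2")
  if (a <= 0) stop("`a` must be positive")
  N_exact <- 4 * a * (2 * n - 2) / (2 * n - 1)
  ks_exact <- k * log(1 - 1 / n - 1 / (n - 1)) / log(1 - 2 / N_exact)
  tibble::tibble(k = k, N_exact = N_exact, ks_exact = ks_exact,
                 N_approx = 4 * a, ks_approx = 4 * k * a / n)
}

# ---- expected cycles of the random transposition walk ----------------------

eh_frac_limbs <- function(n) {
  # working precision: ~n log2(n) bits beyond the target, per the numeric
  # policy for the alternating coefficient sum (cancellation ~ C(n, n/2))
  digits <- ceiling(n * log2(max(n, 2)) * log10(2)) + 36
  as.integer(ceiling(digits / 9))
}

eh_table_raw <- function(n, k_max, frac_limbs) {
  key <- sprintf("eh_%d_%d_%d", n, k_max, frac_limbs)
  if (is.null(the[[key]])) {
    the[[key]] <- eh_formula_table_cpp(as.integer(n), as.integer(k_max),
                                       as.integer(frac_limbs))
  }
  the[[key]]
}

#' Expected cycles after k random transpositions
#'
#' `eh_formula()` evaluates, verbatim, the published alternating series
#' \deqn{n - \sum_{i=1}^n 1/i + \sum_{p=1}^{n-1} \sum_{q=1}^{\min(p, n-p)}
#'   a_{pq} \left(\frac{\binom{p}{2} + \binom{q-1}{2} -
#'   \binom{n-p-q+2}{2}}{\binom{n}{2}}\right)^k}
#' with \eqn{a_{pq} = (-1)^{n-p-q+1} \frac{(p-q+1)^2}{(n-q+1)^2 (n-p)}
#' \binom{n-p-1}{q-1} \binom{n}{p}}.  Exact small-case evaluation (see
#' [exact_transposition_cycle_expectation()]) shows this printed expression
#' equals the expected transposition *distance* `n - E(cycles)`, not the
#' cycle count under which it is usually quoted; `eh_expected_cycles()`
#' therefore returns `n - eh_formula(n, k)`, the orientation confirmed
#' against the exact partition-chain reference for all `n <= 8`, `k <= 20`.
#'
#' The alternating coefficients are astronomically larger than the result
#' (order `C(n, n/2)`), so evaluation uses arbitrary-precision fixed-point
#' arithmetic with exact big-integer coefficient numerators.  Every call is
#' recomputed at doubled precision; a relative disagreement above `1e-9`
#' raises an error rather than returning silently cancelled garbage.
#'
#' @param n Permutation size (`n >= 2`).
#' @param k Transposition count(s), non-negative integers; vectorized.
#' @param frac_limbs Number of base-1e9 fractional limbs of working
#'   precision; defaults to the policy above (about `n log2 n` bits plus a
#'   guard margin).
#' @return Numeric vector, one value per `k`.
#' @examples
#' eh_expected_cycles(2, 0:3)  # 2, 1, 2, 1
#' @export
eh_formula <- function(n, k, frac_limbs = NULL) {
  if (n < 2) stop("`n` must be at least 2")
  if (any(k < 0) || any(k != floor(k))) stop("`k` must be non-negative integers")
  F1 <- if (is.null(frac_limbs)) eh_frac_limbs(n) else as.integer(frac_limbs)
  k_max <- max(k)
  v1 <- eh_table_raw(n, k_max, F1)
  v2 <- eh_table_raw(n, k_max, 2L * F1)
  bad <- abs(v1 - v2) > 1e-9 * pmax(1, abs(v2))
  if (any(bad)) {
    stop("insufficient working precision for n = ", n,
         " (cancellation detected); increase `frac_limbs`")
  }
  v2[k + 1]
}

#' @rdname eh_formula
#' @export
eh_expected_cycles <- function(n, k, frac_limbs = NULL) {
  n - eh_formula(n, k, frac_limbs = frac_limbs)
}

#' @rdname eh_formula
#' @param k_max Largest step of the tabulated curve.
#' @return For `eh_cycle_table()`: a tibble with columns `k` and
#'   `expected_cycles` for `k = 0..k_max`.
#' @export
eh_cycle_table <- function(n, k_max, frac_limbs = NULL) {
  tibble::tibble(k = 0:k_max,
                 expected_cycles = eh_expected_cycles(n, 0:k_max,
                                                      frac_limbs = frac_limbs))
}

# ---- expected components of the random multigraph --------------------------

#' Expected component count of the sparse random multigraph
#'
#' Tree-count approximation to the expected number of connected components of
#' a multigraph grown from `n` isolated vertices by `k` uniformly random
#' edges (parallel edges allowed):
#' \deqn{\frac{n^2}{2k} \sum_{i \ge 1} \frac{i^{i-2}}{i!}
#'   \left(\frac{2k}{n} e^{-2k/n}\right)^i.}
#' The sum's argument `c e^{-c}` with `c = 2k/n` never exceeds `1/e`, so the
#' series converges; it is truncated when a term falls below `tol` (hard cap
#' `10 n` terms).  The prefactor is fixed by the requirement that the
#' `k -> 0` limit equal `n` (the `i = 1` term is `n e^{-2k/n}`); `k = 0` is
#' returned as that limit.
#'
#' @param n Vertex count (`n >= 2`).
#' @param k Edge count(s), non-negative; vectorized.
#' @param tol Truncation tolerance for the series terms.
#' @return Numeric vector of expected component counts.
#' @export
bd_expected_components <- function(n, k, tol = 1e-12) {
  if (n < 2) stop("`n` must be at least 2")
  if (any(k < 0)) stop("`k` must be non-negative")
  one <- function(kk) {
    if (kk == 0) return(as.numeric(n))
    c_ <- 2 * kk / n
    log_x <- log(c_) - c_        # log of the series argument c e^{-c}
    total <- 0
    for (i in seq_len(10L * n)) {
      log_term <- (i - 2) * log(i) - lgamma(i + 1) + i * log_x
      term <- exp(log_term)
      total <- total + term
      if (term < tol) break
    }
    n^2 / (2 * kk) * total
  }
  vapply(k, one, 0)
}
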