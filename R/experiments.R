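# Scripted simulation experiments: the sequence-length sweep and the
# estimator comparison, at full study scale or a reduced desk scale.

#' Configure a simulation experiment
#'
#' The full-scale defaults evolve a random genome with `a = 980` observed
#' adjacencies and `n = 1020` total adjacencies (realized as `g = 1000`
#' genes, 40 telomeres, `f = 0`) for 4000 DCJ steps in a single run.  The
#' reduced scale (`scale = "reduced"`) scales the telomere-to-adjacency
#' proportion down to `n = 120` (`g = 118`, 4 telomeres, `f = 0`, so
#' `a = 116`) with 400 steps over five seeds — small enough for routine
#' testing while showing the same qualitative behavior.
#'
#' @param scale `"full"` or `"reduced"`; explicit arguments override the
#'   chosen preset.
#' @param g,telomeres,f Genome generator parameters (see [random_genome()]).
#' @param k_max Number of DCJ steps.
#' @param seeds Integer vector of seeds, one trajectory per seed.
#' @return A list of class `dcj_experiment_config` with fields `g`,
#'   `telomeres`, `f`, `a`, `n`, `k_max`, `seeds`.
#' @export
experiment_config <- function(scale = c("full", "reduced"), g = NULL,
                              telomeres = NULL, f = NULL, k_max = NULL,
                              seeds = NULL) {
  scale <- match.arg(scale)
  preset <- if (scale == "full") {
    list(g = 1000L, telomeres = 40L, f = 0L, k_max = 4000L, seeds = 1L)
  } else {
    list(g = 118L, telomeres = 4L, f = 0L, k_max = 400L, seeds = 1:5)
  }
  cfg <- list(
    g = if (is.null(g)) preset$g else as.integer(g),
    telomeres = if (is.null(telomeres)) preset$telomeres else as.integer(telomeres),
    f = if (is.null(f)) preset$f else as.integer(f),
    k_max = if (is.null(k_max)) preset$k_max else as.integer(k_max),
    seeds = if (is.null(seeds)) preset$seeds else as.integer(seeds)
  )
  if (cfg$telomeres %% 2L != 0L || cfg$f %% 2L != 0L) {
    stop("`telomeres` and `f` must be even")
  }
  cfg$a <- (2L * cfg$g - cfg$telomeres) %/% 2L
  cfg$n <- cfg$a + cfg$telomeres + cfg$f %/% 2L
  class(cfg) <- "dcj_experiment_config"
  cfg
}

#' @export
print.dcj_experiment_config <- function(x, ...) {
  cat(sprintf(
    "<dcj_experiment_config> g = %d, telomeres = %d, f = %d (a = %d, n = %d); k_max = %d, %d seed(s)\n",
    x$g, x$telomeres, x$f, x$a, x$n, x$k_max, length(x$seeds)))
  invisible(x)
}

# vectorized inversion helpers for the sweeps
dcj_tilde_vec <- function(B, a, n) {
  ratio <- 1 - B * (2 * n - 1) / (a * (2 * n - 2))
  out <- rep(Inf, length(B))
  ok <- ratio > 0
  out[ok] <- log(ratio[ok]) / log(1 - 1 / (n - 1) - 1 / n)
  out
}

seq_coding_vec <- function(B, a, n, N_val) {
  D <- 2 * B
  out <- rep(Inf, length(B))
  ok <- D < N_val / 2
  out[ok] <- log(1 - 2 * D[ok] / N_val) / log(1 - 1 / n - 1 / (n - 1))
  out
}

grid_invert_vec <- function(observed, table) {
  vapply(observed, function(o) which.min(abs(o - table)) - 1L, 0L)
}

# one simulated trajectory per seed; genome and chain seeds are derived from
# the experiment seed so the two draws use distinct streams
experiment_trajectory <- function(cfg, seed, record) {
  g0 <- random_genome(cfg$g, cfg$telomeres, cfg$f, seed = seed)
  simulate_dcj(g0, cfg$k_max, seed = seed + 500009L, record = record)
}

#' Sequence-length sweep of the coding estimator
#'
#' Simulates a DCJ trajectory, records the breakpoint count at every step,
#' and inverts it through the sequence-coding estimator for each sequence
#' length in the sweep — `N = 2n` (adjacencies present in either genome),
#' `N = 4a`, the exact coding length `4a(2n-2)/(2n-1)`, and `N = n(2n-1)`
#' (all possible adjacencies) — alongside the direct analytic inversion.
#' Too-short codings overestimate the distance, too-long ones underestimate
#' it; `N = 4a` tracks the analytic estimator closely.
#'
#' @param config A `dcj_experiment_config`.
#' @return A long tibble: `seed`, `k` (true step count), `method`, `k_hat`.
#' @export
run_seq_length_sweep <- function(config) {
  stopifnot(inherits(config, "dcj_experiment_config"))
  a <- config$a; n <- config$n
  N_choices <- c("seq N=2n" = 2 * n,
                 "seq N=4a" = 4 * a,
                 "seq N=exact" = 4 * a * (2 * n - 2) / (2 * n - 1),
                 "seq N=n(2n-1)" = n * (2 * n - 1))
  purrr::map_dfr(config$seeds, function(seed) {
    tr <- experiment_trajectory(config, seed, record = "breakpoints")
    base <- tibble::tibble(seed = seed, k = tr$k)
    out <- dplyr::mutate(base, method = "dcj_tilde",
                         k_hat = dcj_tilde_vec(tr$breakpoints, a, n))
    for (lab in names(N_choices)) {
      out <- dplyr::bind_rows(
        out,
        dplyr::mutate(base, method = lab,
                      k_hat = seq_coding_vec(tr$breakpoints, a, n,
                                             N_choices[[lab]]))
      )
    }
    out
  })
}

#' Compare all DCJ-count estimators along a trajectory
#'
#' Simulates a DCJ trajectory recording breakpoints and observed-graph
#' cycles, then evaluates at every step: the parsimony distance
#' (`n - cycles`), the analytic breakpoint inversion, and the grid inversions
#' of the expected transposition cycles (EH) and expected graph components
#' (BD), both precomputed once over `k = 0..k_max` as the grid method
#' requires.
#'
#' @param config A `dcj_experiment_config`.
#' @return A long tibble: `seed`, `k`, `estimator` (`"parsimony"`,
#'   `"dcj_tilde"`, `"eh"`, `"bd"`), `k_hat`.
#' @export
run_estimator_comparison <- function(config) {
  stopifnot(inherits(config, "dcj_experiment_config"))
  a <- config$a; n <- config$n
  eh_tab <- eh_expected_cycles(n, 0:config$k_max)
  bd_tab <- bd_expected_components(n, 0:config$k_max)
  purrr::map_dfr(config$seeds, function(seed) {
    tr <- experiment_trajectory(config, seed,
                                record = c("breakpoints", "obs_cycles"))
    base <- tibble::tibble(seed = seed, k = tr$k)
    dplyr::bind_rows(
      dplyr::mutate(base, estimator = "parsimony",
                    k_hat = as.numeric(tr$obs_distance)),
      dplyr::mutate(base, estimator = "dcj_tilde",
                    k_hat = dcj_tilde_vec(tr$breakpoints, a, n)),
      dplyr::mutate(base, estimator = "eh",
                    k_hat = as.numeric(grid_invert_vec(tr$obs_cycles, eh_tab))),
      dplyr::mutate(base, estimator = "bd",
                    k_hat = as.numeric(grid_invert_vec(tr$obs_cycles, bd_tab)))
    )
  })
}

#' Write an experiment table as TSV
#'
#' @param table A tibble from [run_seq_length_sweep()] or
#'   [run_estimator_comparison()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_experiment_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
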