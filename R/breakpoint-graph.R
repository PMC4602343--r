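# Breakpoint graphs: the union of two genomes' adjacency matchings,
# decomposed into cycles alternating between the genomes.
#
# The "real" graph uses the true correspondence of telomeric/fictional
# vertices between the genomes (known to a simulator, unobservable in data);
# the "observed" graph closes the paths of the observed-adjacency union in
# the cycle-maximizing way: even-edge paths by one shared telomeric vertex,
# odd-edge paths by two fictional vertices and a fictional adjacency,
# leftover telomeric/fictional budget by trivial cycles of parallel edges.

new_bp_graph <- function(cycle_lengths, kind, n) {
  structure(
    list(cycle_lengths = sort(as.integer(cycle_lengths), decreasing = TRUE),
         kind = kind, n = as.integer(n)),
    class = "dcj_bp_graph"
  )
}

# Observed-graph decomposition from raw mate vectors; n_target pads with
# trivial cycles (each consuming one adjacency per genome) up to a common
# adjacency total.
obs_graph_from_mates <- function(m1, m2, g, n_target = NULL, strict = FALSE) {
  V <- 2L * g
  v <- seq_len(V)
  w1 <- m1[v]; nb1 <- ifelse(w1 >= 1L & w1 <= V, w1, 0L)
  w2 <- m2[v]; nb2 <- ifelse(w2 >= 1L & w2 <= V, w2, 0L)
  visited <- logical(V)
  lengths <- integer()
  telomeric_used <- 0L; fictional_used <- 0L
  # adjacencies shared by both genomes: trivial cycles of two parallel edges
  sh <- which(nb1 == nb2 & nb1 > v)
  if (length(sh) > 0) {
    visited[sh] <- TRUE; visited[nb1[sh]] <- TRUE
    lengths <- c(lengths, rep(1L, length(sh)))
  }
  # telomeres in both genomes: 0-edge paths, closed by one telomeric vertex
  iso <- which(!visited & nb1 == 0L & nb2 == 0L)
  if (length(iso) > 0) {
    visited[iso] <- TRUE
    lengths <- c(lengths, rep(1L, length(iso)))
    telomeric_used <- telomeric_used + length(iso)
  }
  # paths: walk from each endpoint (a vertex missing one genome's adjacency)
  for (s in which(!visited & (nb1 == 0L | nb2 == 0L))) {
    if (visited[s]) next
    cur <- s
    use1 <- nb1[s] != 0L
    e1 <- 0L; e2 <- 0L
    repeat {
      visited[cur] <- TRUE
      nxt <- if (use1) nb1[cur] else nb2[cur]
      if (nxt == 0L) break
      if (use1) e1 <- e1 + 1L else e2 <- e2 + 1L
      cur <- nxt
      use1 <- !use1
    }
    if (e1 == e2) {
      # even path: one telomeric vertex closes it
      lengths <- c(lengths, e1 + 1L)
      telomeric_used <- telomeric_used + 1L
    } else {
      # odd path: two fictional vertices and one fictional adjacency
      lengths <- c(lengths, max(e1, e2) + 1L)
      fictional_used <- fictional_used + 2L
    }
  }
  # remaining components are cycles of observed adjacencies
  for (s in which(!visited)) {
    if (visited[s]) next
    cur <- s; len <- 0L
    repeat {
      visited[cur] <- TRUE
      u <- nb1[cur]
      visited[u] <- TRUE
      len <- len + 1L
      cur <- nb2[u]
      if (cur == s) break
    }
    lengths <- c(lengths, len)
  }
  n_intrinsic <- sum(lengths)
  pad <- 0L
  if (!is.null(n_target)) {
    pad <- as.integer(n_target) - n_intrinsic
    if (pad < 0) {
      # the closure may consume more telomeric/fictional vertices than the
      # genomes' own augmentation carries (each odd path takes a fictional
      # pair); the graph then simply has more adjacencies than n_target
      if (strict) {
        stop("adjacency budget n = ", n_target,
             " too small for the observed graph (needs ", n_intrinsic, ")")
      }
      pad <- 0L
    }
    lengths <- c(lengths, rep(1L, pad))
  }
  list(lengths = lengths, n = n_intrinsic + pad,
       telomeric_used = telomeric_used, fictional_used = fictional_used,
       padded = pad)
}

#' Observed breakpoint graph of two genomes
#'
#' Builds the breakpoint graph from observed adjacencies alone, closing the
#' paths of the union in the cycle-maximizing way: a path with an even number
#' of edges is closed by one shared telomeric vertex; a path with an odd
#' number of edges by two fictional vertices joined by a fictional adjacency;
#' any leftover telomeric/fictional adjacency budget (when `n` exceeds what
#' the closures consume) becomes trivial cycles of two parallel edges.  Among
#' all telomere correspondences this construction maximizes the cycle count,
#' so `n - cycles` on this graph is the parsimony DCJ distance.
#'
#' @param genome1,genome2 Two `dcj_genome`s on the same gene set.
#' @param n Total adjacency count per genome in the graph.  Defaults to the
#'   common augmented total when both genomes are augmented compatibly,
#'   otherwise to the minimum the closures require.  Padding with trivial
#'   cycles changes `n` and the cycle count by the same amount, so the DCJ
#'   distance is unaffected.  The closure may need more telomeric/fictional
#'   vertices than the genomes' augmentation carries (each odd path consumes
#'   a fictional pair); a default `n` below that need is silently replaced by
#'   the closure total, while an explicitly requested one raises an error.
#' @return A `dcj_bp_graph` with fields `cycle_lengths` (adjacencies of one
#'   genome per cycle; trivial cycle = 1), `kind = "observed"` and `n`.
#' @examples
#' red  <- build_genome(c(1, 2, 3))
#' blue <- build_genome(c(3, 2, 1))
#' bg <- observed_breakpoint_graph(red, blue)
#' dcj_distance(bg)  # 2
#' @export
observed_breakpoint_graph <- function(genome1, genome2, n = NULL) {
  stopifnot(inherits(genome1, "dcj_genome"), inherits(genome2, "dcj_genome"))
  if (genome1$g != genome2$g ||
      !identical(genome1$gene_ids, genome2$gene_ids)) {
    stop("genomes must share the same gene set")
  }
  strict <- !is.null(n)
  if (is.null(n) && genome1$augmented && genome2$augmented &&
      length(genome1$mate) == length(genome2$mate)) {
    n <- length(genome1$mate) %/% 2L
  }
  dec <- obs_graph_from_mates(genome1$mate, genome2$mate, genome1$g, n,
                              strict = strict)
  new_bp_graph(dec$lengths, "observed", dec$n)
}

#' Real breakpoint graph of two genomes
#'
#' The breakpoint graph under a known correspondence between the
#' telomeric/fictional vertices of the two genomes — the graph an observer
#' with access to the evolutionary history would draw.  When the two genomes
#' live on the same augmented vertex set (as along a simulated DCJ
#' trajectory) the identity correspondence is used by default.
#'
#' @param genome1,genome2 Augmented `dcj_genome`s on the same gene set with
#'   equal numbers of non-observed vertices.
#' @param correspondence `NULL` for the identity, or a data frame with
#'   columns `from` (telomeric/fictional vertex ids of `genome2`) and `to`
#'   (vertex ids of `genome1`), a bijection between the non-observed vertices.
#' @return A `dcj_bp_graph` with `kind = "real"` and `n` the augmented
#'   adjacency count.
#' @examples
#' red  <- augment_genome(build_genome(c(1, 2, 3)))
#' blue <- augment_genome(build_genome(c(3, 2, 1)))
#' dcj_distance(real_breakpoint_graph(red, blue))  # 3 under identity pairing
#' @export
real_breakpoint_graph <- function(genome1, genome2, correspondence = NULL) {
  stopifnot(inherits(genome1, "dcj_genome"), inherits(genome2, "dcj_genome"))
  if (!genome1$augmented || !genome2$augmented) {
    stop("real_breakpoint_graph() requires augmented genomes")
  }
  if (genome1$g != genome2$g ||
      length(genome1$mate) != length(genome2$mate)) {
    stop("genomes must share gene set and augmented vertex count")
  }
  nv <- length(genome1$mate)
  g <- genome1$g
  m2 <- genome2$mate
  if (!is.null(correspondence)) {
    from <- as.integer(correspondence$from)
    to <- as.integer(correspondence$to)
    extra <- setdiff(seq_len(nv), seq_len(2L * g))
    if (!setequal(from, extra) || !setequal(to, extra)) {
      stop("`correspondence` must be a bijection between the ",
           "telomeric/fictional vertices of the two genomes")
    }
    map <- seq_len(nv)
    map[from] <- to
    relabeled <- integer(nv)
    relabeled[map] <- map[m2]
    m2 <- relabeled
  }
  lengths <- union_cycle_lengths_cpp(genome1$mate, m2)
  new_bp_graph(lengths, "real", nv %/% 2L)
}

#' DCJ distance from a breakpoint graph
#'
#' The number of DCJ operations needed to sort one genome into the other,
#' given the breakpoint graph: `n - (number of cycles)`.  On the observed
#' graph this is the parsimony (minimum) DCJ distance; on a real graph it is
#' the number of DCJs a scenario respecting that telomere correspondence
#' needs, which is never smaller.
#'
#' @param bp_graph A `dcj_bp_graph`.
#' @return Integer distance.
#' @export
dcj_distance <- function(bp_graph) {
  stopifnot(inherits(bp_graph, "dcj_bp_graph"))
  bp_graph$n - length(bp_graph$cycle_lengths)
}

#' Cycle-count gap between observed and real breakpoint graphs
#'
#' The observed graph maximizes the cycle count given the observed
#' adjacencies, so the gap is non-negative and bounded by the number of
#' telomeric plus fictional vertices.
#'
#' @param observed,real `dcj_bp_graph`s of the same genome pair.
#' @return Integer `cycles(observed) - cycles(real)`, `>= 0`.
#' @export
cycle_count_gap <- function(observed, real) {
  stopifnot(inherits(observed, "dcj_bp_graph"), inherits(real, "dcj_bp_graph"))
  length(observed$cycle_lengths) - length(real$cycle_lengths)
}

#' @export
print.dcj_bp_graph <- function(x, ...) {
  cat(sprintf("<dcj_bp_graph: %s> n = %d, cycles = %d, DCJ distance = %d\n",
              x$kind, x$n, length(x$cycle_lengths), dcj_distance(x)))
  tab <- table(x$cycle_lengths)
  cat("  cycle lengths:",
      paste(sprintf("%s x%d", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Tidy a breakpoint graph into its cycle-type table
#'
#' @param x A `dcj_bp_graph`.
#' @param ... Unused.
#' @return A tibble with columns `cycle_length`, `multiplicity`,
#'   `graph_kind`.
#' @export
tidy.dcj_bp_graph <- function(x, ...) {
  tab <- table(x$cycle_lengths)
  tibble::tibble(
    cycle_length = as.integer(names(tab)),
    multiplicity = as.integer(tab),
    graph_kind = x$kind
  )
}

#' @rdname tidy.dcj_bp_graph
#' @return For `glance()`: a one-row tibble with `n`, `cycles`,
#'   `dcj_distance`, `graph_kind`.
#' @export
glance.dcj_bp_graph <- function(x, ...) {
  tibble::tibble(n = x$n, cycles = length(x$cycle_lengths),
                 dcj_distance = dcj_distance(x), graph_kind = x$kind)
}
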