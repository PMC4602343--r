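# Genomes as perfect matchings on gene extremities.
#
# A genome with g genes lives on 2g "observed" vertices, the gene extremities.
# Gene j owns the tail vertex 2j - 1 and the head vertex 2j.  Adjacencies are
# an (incomplete) matching of the extremities; extremities left unmatched are
# telomeres.  Augmentation adds one telomeric vertex per telomere plus an even
# number f of fictional vertices matched pairwise, so that the adjacency set
# becomes a perfect matching with n = 2g - a + f/2 edges.
#
# Internally a genome is a `mate` vector: mate[v] is the vertex matched to v,
# or 0 for a telomere of an unaugmented genome.  Telomeric vertices occupy ids
# 2g + 1 .. 2g + t, fictional vertices 2g + t + 1 .. 2g + t + f.

tail_vertex <- function(gene) 2L * gene - 1L
head_vertex <- function(gene) 2L * gene

new_genome <- function(g, mate, t = 0L, f = 0L, augmented = FALSE,
                       name = NULL, gene_ids = NULL) {
  structure(
    list(g = as.integer(g), mate = as.integer(mate), t = as.integer(t),
         f = as.integer(f), augmented = isTRUE(augmented), name = name,
         gene_ids = if (is.null(gene_ids)) seq_len(g) else as.integer(gene_ids)),
    class = "dcj_genome"
  )
}

#' Build a genome from signed gene orders
#'
#' Constructs a genome as two matchings on gene extremities: the genes
#' (arcs, implicit in the vertex encoding) and the adjacencies between
#' consecutive genes on each chromosome.  Gene `j` contributes a tail
#' extremity (vertex `2j - 1`) and a head extremity (vertex `2j`); a positive
#' entry means the gene is read tail-to-head, a negative one head-to-tail.
#'
#' @param chromosomes A list of integer vectors (one per chromosome) of signed
#'   gene identifiers, or a single integer vector for a one-chromosome genome.
#'   Across all chromosomes each gene identifier must appear exactly once, and
#'   identifiers must be `1..g` (use [read_genomes()] for files with arbitrary
#'   identifiers).
#' @param circular Logical, recycled over chromosomes: `TRUE` closes the
#'   chromosome (no telomeres), `FALSE` leaves the two end extremities as
#'   telomeres.
#' @param name Optional genome name (used by [write_genomes()]).
#' @return A `dcj_genome` object (not augmented; see [augment_genome()]).
#' @examples
#' red  <- build_genome(c(1, 2, 3), name = "red")
#' blue <- build_genome(c(3, 2, 1), name = "blue")
#' count_breakpoints(red, blue)
#' @seealso [augment_genome()], [random_genome()], [count_breakpoints()]
#' @export
build_genome <- function(chromosomes, circular = FALSE, name = NULL) {
  if (is.numeric(chromosomes)) chromosomes <- list(chromosomes)
  if (!is.list(chromosomes) || length(chromosomes) == 0) {
    stop("`chromosomes` must be a non-empty list of signed integer vectors")
  }
  circular <- rep_len(as.logical(circular), length(chromosomes))
  genes <- abs(unlist(chromosomes, use.names = FALSE))
  if (length(genes) == 0 || any(genes != floor(genes)) || any(genes < 1)) {
    stop("gene identifiers must be non-zero integers")
  }
  if (anyDuplicated(genes)) {
    stop("duplicate gene identifier: ", genes[duplicated(genes)][1])
  }
  g <- length(genes)
  if (!setequal(genes, seq_len(g))) {
    stop("gene identifiers must be exactly 1..", g, " (missing ids)")
  }
  mate <- integer(2L * g)
  for (ci in seq_along(chromosomes)) {
    chrom <- as.integer(chromosomes[[ci]])
    gid <- abs(chrom)
    left  <- ifelse(chrom > 0, tail_vertex(gid), head_vertex(gid))
    right <- ifelse(chrom > 0, head_vertex(gid), tail_vertex(gid))
    m <- length(chrom)
    if (m > 1) {
      for (i in seq_len(m - 1)) {
        mate[right[i]] <- left[i + 1]
        mate[left[i + 1]] <- right[i]
      }
    }
    if (circular[ci]) {
      mate[right[m]] <- left[1]
      mate[left[1]] <- right[m]
    }
  }
  new_genome(g, mate, name = name)
}

#' Augment a genome to a perfect matching
#'
#' Adds one telomeric vertex (and telomeric adjacency) per telomere, plus `f`
#' fictional vertices matched pairwise by fictional adjacencies, so that every
#' vertex is matched.  The augmented genome has `4g - 2a + f` vertices and
#' `n = 2g - a + f/2` adjacencies.
#'
#' @param genome A `dcj_genome` from [build_genome()].
#' @param f Even, non-negative number of fictional vertices.  Fresh fictional
#'   vertices are paired consecutively (first with second, and so on), a fixed
#'   deterministic convention.
#' @return An augmented `dcj_genome`.
#' @examples
#' g <- augment_genome(build_genome(c(1, 2, 3)))
#' genome_params(g)  # a = 2, n = 4
#' @export
augment_genome <- function(genome, f = 0L) {
  stopifnot(inherits(genome, "dcj_genome"))
  if (genome$augmented) stop("genome is already augmented")
  f <- as.integer(f)
  if (length(f) != 1 || is.na(f) || f < 0 || f %% 2L != 0L) {
    stop("`f` must be a single even non-negative integer")
  }
  g <- genome$g
  telomeres <- which(genome$mate[seq_len(2L * g)] == 0L)
  t <- length(telomeres)
  mate <- c(genome$mate[seq_len(2L * g)], integer(t + f))
  if (t > 0) {
    tv <- 2L * g + seq_len(t)
    mate[telomeres] <- tv
    mate[tv] <- telomeres
  }
  if (f > 0) {
    fv <- 2L * g + t + seq_len(f)
    odd <- fv[seq(1L, f, by = 2L)]
    mate[odd] <- odd + 1L
    mate[odd + 1L] <- odd
  }
  new_genome(g, mate, t = t, f = f, augmented = TRUE,
             name = genome$name, gene_ids = genome$gene_ids)
}

#' Model parameters (g, a, f, n)
#'
#' The parameter set of the uniform DCJ model: `g` genes, `a` observed
#' adjacencies, `f` fictional vertices (even) and `n = 2g - a + f/2` total
#' adjacencies of the augmented genome.
#'
#' @param g Gene count.
#' @param a Observed adjacency count, `0 <= a <= g`... at most `g` for genomes
#'   whose chromosomes are all paths or single cycles (the general matching
#'   bound is `a <= g` because each gene has two extremities and adjacencies
#'   pair them off with one spare per linear chromosome).
#' @param f Even fictional-vertex count.
#' @return A one-row tibble with columns `g`, `a`, `f`, `t` (telomere count
#'   `2g - 2a`) and `n`.
#' @export
model_params <- function(g, a, f = 0L) {
  g <- as.integer(g); a <- as.integer(a); f <- as.integer(f)
  if (f < 0 || f %% 2L != 0L) stop("`f` must be even and non-negative")
  if (a < 0 || a > g) stop("`a` must satisfy 0 <= a <= g")
  tibble::tibble(g = g, a = a, f = f, t = 2L * g - 2L * a,
                 n = 2L * g - a + f %/% 2L)
}

#' @rdname model_params
#' @param genome An augmented or plain `dcj_genome`.
#' @export
genome_params <- function(genome) {
  stopifnot(inherits(genome, "dcj_genome"))
  model_params(genome$g, genome_a(genome), genome$f)
}

# observed adjacency count
genome_a <- function(genome) {
  g <- genome$g
  v <- seq_len(2L * g)
  w <- genome$mate[v]
  sum(w > v & w <= 2L * g)
}

# total adjacency count of an augmented genome
genome_n <- function(genome) {
  if (!genome$augmented) stop("genome must be augmented")
  length(genome$mate) %/% 2L
}

#' Adjacencies of a genome
#'
#' @param genome A `dcj_genome`.
#' @return A tibble with columns `v1`, `v2` (vertex ids, `v1 < v2`) and
#'   `kind` (`"observed"`, `"telomeric"` or `"fictional"`): an adjacency is
#'   observed iff both endpoints are gene extremities, telomeric if it joins a
#'   gene extremity to a non-observed vertex, fictional otherwise.
#' @export
adjacencies <- function(genome) {
  stopifnot(inherits(genome, "dcj_genome"))
  mate <- genome$mate
  v <- which(mate > seq_along(mate))
  w <- mate[v]
  obs <- 2L * genome$g
  n_obs_end <- (v <= obs) + (w <= obs)
  tibble::tibble(
    v1 = v, v2 = w,
    kind = c("fictional", "telomeric", "observed")[n_obs_end + 1L]
  )
}

#' Apply one DCJ operation
#'
#' A Double Cut-and-Join replaces two distinct adjacencies `{A,B}` and `{C,D}`
#' of an augmented genome by `{A,C}` and `{B,D}` (`choice = 1`) or by `{A,D}`
#' and `{B,C}` (`choice = 2`).  The result is again a perfect matching on the
#' same vertex set.
#'
#' @param genome An augmented `dcj_genome`.
#' @param adj1,adj2 Length-2 integer vectors, each an adjacency of `genome`
#'   (`mate[adj1[1]] == adj1[2]`); the two must be distinct adjacencies.
#' @param choice 1 or 2, selecting the rewiring.
#' @return The rearranged `dcj_genome`.
#' @examples
#' g <- augment_genome(build_genome(c(1, 2, 3)))
#' g2 <- apply_dcj(g, c(2, 3), c(4, 5), choice = 2)
#' count_breakpoints(g, g2)
#' @export
apply_dcj <- function(genome, adj1, adj2, choice = 1L) {
  stopifnot(inherits(genome, "dcj_genome"))
  if (!genome$augmented) stop("apply_dcj() requires an augmented genome")
  adj1 <- as.integer(adj1); adj2 <- as.integer(adj2)
  choice <- as.integer(choice)
  if (length(adj1) != 2 || length(adj2) != 2) stop("adjacencies are vertex pairs")
  if (!choice %in% c(1L, 2L)) stop("`choice` must be 1 or 2")
  mate <- genome$mate
  ok1 <- adj1[1] >= 1 && adj1[1] <= length(mate) && mate[adj1[1]] == adj1[2]
  ok2 <- adj2[1] >= 1 && adj2[1] <= length(mate) && mate[adj2[1]] == adj2[2]
  if (!ok1 || !ok2) stop("`adj1`/`adj2` are not adjacencies of this genome")
  if (all(sort(adj1) == sort(adj2))) {
    stop("the two adjacencies of a DCJ must be distinct")
  }
  a <- adj1[1]; b <- adj1[2]; c <- adj2[1]; d <- adj2[2]
  if (choice == 1L) {
    mate[a] <- c; mate[c] <- a; mate[b] <- d; mate[d] <- b
  } else {
    mate[a] <- d; mate[d] <- a; mate[b] <- c; mate[c] <- b
  }
  out <- genome
  out$mate <- mate
  out
}

#' Enumerate all DCJ moves of a genome
#'
#' An augmented genome with `n` adjacencies admits exactly `n(n-1)` distinct
#' equiprobable DCJ moves: each of the `choose(n, 2)` unordered adjacency
#' pairs combined with the two rewiring choices.  This includes moves that
#' only touch telomeric/fictional adjacencies and therefore leave the
#' underlying gene order unchanged ("do nothing" moves), as the uniform model
#' requires.
#'
#' @param genome An augmented `dcj_genome` with `n >= 2`.
#' @return A tibble with columns `a1`, `b1`, `a2`, `b2` (the two adjacencies)
#'   and `choice`; `n(n-1)` rows.
#' @export
dcj_moves <- function(genome) {
  stopifnot(inherits(genome, "dcj_genome"))
  if (!genome$augmented) stop("dcj_moves() requires an augmented genome")
  adj <- adjacencies(genome)
  n <- nrow(adj)
  if (n < 2) {
    return(tibble::tibble(a1 = integer(), b1 = integer(),
                          a2 = integer(), b2 = integer(), choice = integer()))
  }
  pairs <- utils::combn(n, 2)
  tibble::tibble(
    a1 = rep(adj$v1[pairs[1, ]], 2),
    b1 = rep(adj$v2[pairs[1, ]], 2),
    a2 = rep(adj$v1[pairs[2, ]], 2),
    b2 = rep(adj$v2[pairs[2, ]], 2),
    choice = rep(c(1L, 2L), each = ncol(pairs))
  )
}

#' Count breakpoints between two genomes
#'
#' A breakpoint of `genome1` with respect to `genome2` is an observed
#' adjacency of `genome1` (both endpoints gene extremities) whose endpoints
#' are not adjacent in `genome2`.  Only observed adjacencies enter the count,
#' so the result depends on observable data alone.
#'
#' @param genome1,genome2 Two `dcj_genome`s on the same gene set (augmented or
#'   not).
#' @return Integer breakpoint count, between 0 and `a1`.
#' @examples
#' count_breakpoints(build_genome(c(1, 2, 3)), build_genome(c(3, 2, 1)))  # 2
#' @export
count_breakpoints <- function(genome1, genome2) {
  stopifnot(inherits(genome1, "dcj_genome"), inherits(genome2, "dcj_genome"))
  if (genome1$g != genome2$g ||
      !identical(genome1$gene_ids, genome2$gene_ids)) {
    stop("genomes must share the same gene set")
  }
  g <- genome1$g
  v <- seq_len(2L * g)
  w1 <- genome1$mate[v]
  keep <- w1 > v & w1 <= 2L * g
  sum(genome2$mate[v[keep]] != w1[keep])
}

#' Generate a random genome
#'
#' Draws a uniformly random matching of the `2g` gene extremities leaving
#' exactly `telomeres` extremities unmatched, then augments it (one telomeric
#' vertex per telomere, `f` fictional vertices).  The observed adjacency count
#' is `a = (2g - telomeres) / 2` and the total adjacency count is
#' `n = a + telomeres + f/2`.
#'
#' @param g Gene count.
#' @param telomeres Even number of unmatched extremities (0 for a fully
#'   matched genome).
#' @param f Even fictional-vertex count passed to [augment_genome()].
#' @param seed Optional integer seed; when given, the caller's RNG state is
#'   left untouched and the draw is reproducible.
#' @param augment If `FALSE`, return the raw (unaugmented) genome.
#' @return A `dcj_genome`.
#' @examples
#' g <- random_genome(g = 1000, telomeres = 40, seed = 1)
#' genome_params(g)  # a = 980, n = 1020
#' @export
random_genome <- function(g, telomeres = 0L, f = 0L, seed = NULL,
                          augment = TRUE) {
  g <- as.integer(g); telomeres <- as.integer(telomeres)
  if (g < 1) stop("`g` must be positive")
  if (telomeres < 0 || telomeres > 2L * g || telomeres %% 2L != 0L) {
    stop("`telomeres` must be even and between 0 and 2g")
  }
  with_seed(seed, {
    mate <- integer(2L * g)
    unmatched <- if (telomeres > 0) sample.int(2L * g, telomeres) else integer()
    pool <- setdiff(seq_len(2L * g), unmatched)
    pool <- sample(pool)
    if (length(pool) > 0) {
      v1 <- pool[seq(1L, length(pool), by = 2L)]
      v2 <- pool[seq(2L, length(pool), by = 2L)]
      mate[v1] <- v2
      mate[v2] <- v1
    }
    gen <- new_genome(g, mate)
    if (augment) augment_genome(gen, f = f) else gen
  })
}

# Recover chromosomes (signed gene orders) from the observed adjacencies.
genome_chromosomes <- function(genome) {
  g <- genome$g
  mate <- genome$mate
  obs_mate <- function(v) {
    w <- mate[v]
    if (w >= 1 && w <= 2L * g) w else 0L
  }
  other_end <- function(v) if (v %% 2L == 1L) v + 1L else v - 1L
  visited <- logical(2L * g)
  chroms <- list(); circ <- logical()
  # linear chromosomes start at telomeres
  for (v in seq_len(2L * g)) {
    if (visited[v] || obs_mate(v) != 0L) next
    order <- integer(); cur <- v
    repeat {
      gene <- (cur + 1L) %/% 2L
      order <- c(order, if (cur %% 2L == 1L) gene else -gene)
      visited[cur] <- TRUE
      nxt <- other_end(cur)
      visited[nxt] <- TRUE
      w <- obs_mate(nxt)
      if (w == 0L) break
      cur <- w
    }
    chroms <- c(chroms, list(order)); circ <- c(circ, FALSE)
  }
  # remaining genes are on circular chromosomes
  for (v in seq_len(2L * g)) {
    if (visited[v]) next
    order <- integer(); cur <- v
    repeat {
      gene <- (cur + 1L) %/% 2L
      order <- c(order, if (cur %% 2L == 1L) gene else -gene)
      visited[cur] <- TRUE
      nxt <- other_end(cur)
      visited[nxt] <- TRUE
      w <- obs_mate(nxt)
      if (w == v) break
      cur <- w
    }
    chroms <- c(chroms, list(order)); circ <- c(circ, TRUE)
  }
  list(chromosomes = chroms, circular = circ)
}

#' @export
print.dcj_genome <- function(x, ...) {
  p <- genome_params(x)
  cat(sprintf(
    "<dcj_genome%s> g = %d, a = %d, telomeres = %d%s\n",
    if (!is.null(x$name)) paste0(" '", x$name, "'") else "",
    p$g, p$a, p$t,
    if (x$augmented) sprintf(", f = %d, n = %d (augmented)", p$f, p$n) else ""
  ))
  ch <- genome_chromosomes(x)
  shown <- head(seq_along(ch$chromosomes), 10)
  for (i in shown) {
    ord <- ch$chromosomes[[i]]
    lab <- paste(ifelse(ord > 0, x$gene_ids[ord],
                        -x$gene_ids[-ord]), collapse = " ")
    if (length(ord) > 12) lab <- paste(substr(lab, 1, 50), "...")
    cat(" ", lab, if (ch$circular[i]) ")" else "$", "\n")
  }
  if (length(ch$chromosomes) > 10) {
    cat("  ... and", length(ch$chromosomes) - 10, "more chromosomes\n")
  }
  invisible(x)
}

# adjacency-set equality on the full matching (arc orientation is ignored
# in comparisons by construction: only `mate` is compared)
genomes_identical <- function(genome1, genome2) {
  identical(genome1$mate, genome2$mate)
}
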