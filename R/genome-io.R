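# Plain-text gene-order files (UniMoG/GRIMM dialect): a ">name" header per
# genome, then chromosomes as whitespace-separated signed integers, each
# terminated by "$" (linear) or ")" (circular).

#' Read genomes from a gene-order file
#'
#' Parses the UniMoG/GRIMM plain-text dialect: lines of the form `>name`
#' start a genome; the following tokens are signed gene identifiers, with
#' each chromosome terminated by `$` (linear) or `)` (circular).  Gene
#' identifiers may be arbitrary distinct positive integers; they are kept and
#' written back verbatim (internally genes are ranked `1..g`).
#'
#' @param path File path.
#' @return A named list of `dcj_genome`s (possibly empty).
#' @examples
#' path <- system.file("extdata", "three_gene_pair.txt", package = "dcjmoments")
#' genomes <- read_genomes(path)
#' count_breakpoints(genomes$red, genomes$blue)
#' @export
read_genomes <- function(path) {
  lines <- readLines(path)
  genomes <- list()
  name <- NULL
  chroms <- list(); circ <- logical(); current <- integer()
  first_line <- NA_integer_
  flush_genome <- function(line_no) {
    if (is.null(name)) return()
    if (length(current) > 0) {
      stop("unterminated chromosome in genome '", name,
           "' (before line ", line_no, "); chromosomes end with '$' or ')'")
    }
    if (length(chroms) == 0) {
      stop("genome '", name, "' (line ", first_line, ") has no chromosomes")
    }
    ids <- abs(unlist(chroms))
    if (anyDuplicated(ids)) {
      stop("duplicate gene id ", ids[duplicated(ids)][1], " in genome '",
           name, "' (line ", first_line, ")")
    }
    gene_ids <- sort(ids)
    remapped <- lapply(chroms, function(ch) sign(ch) * match(abs(ch), gene_ids))
    gen <- build_genome(remapped, circular = circ, name = name)
    gen$gene_ids <- as.integer(gene_ids)
    genomes[[name]] <<- gen
  }
  for (ln in seq_along(lines)) {
    line <- trimws(lines[ln])
    if (line == "" || startsWith(line, "#")) next
    if (startsWith(line, ">")) {
      flush_genome(ln)
      name <- trimws(substring(line, 2))
      if (name == "") stop("empty genome name at line ", ln)
      chroms <- list(); circ <- logical(); current <- integer()
      first_line <- ln
      next
    }
    if (is.null(name)) {
      stop("line ", ln, ": gene data before any '>' genome header")
    }
    for (tok in strsplit(line, "[[:space:]]+")[[1]]) {
      if (tok == "$" || tok == ")") {
        if (length(current) == 0) {
          stop("line ", ln, ": chromosome terminator '", tok,
               "' without genes")
        }
        chroms[[length(chroms) + 1]] <- current
        circ <- c(circ, tok == ")")
        current <- integer()
      } else {
        val <- suppressWarnings(as.integer(tok))
        if (is.na(val) || val == 0) {
          stop("line ", ln, ": '", tok,
               "' is not a signed gene id or terminator")
        }
        current <- c(current, val)
      }
    }
  }
  flush_genome(length(lines) + 1L)
  genomes
}

#' Write genomes to a gene-order file
#'
#' Inverse of [read_genomes()]: writes each genome's chromosomes (recovered
#' from its observed adjacencies) with the original gene identifiers, in the
#' UniMoG/GRIMM dialect.  Reading the result back yields identical genomes.
#'
#' @param genomes A `dcj_genome` or a list of them; list names are used when
#'   a genome carries no name of its own.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_genomes <- function(genomes, path) {
  if (inherits(genomes, "dcj_genome")) genomes <- list(genomes)
  lines <- character()
  for (gi in seq_along(genomes)) {
    gen <- genomes[[gi]]
    stopifnot(inherits(gen, "dcj_genome"))
    name <- gen$name
    if (is.null(name) && !is.null(names(genomes))) name <- names(genomes)[gi]
    if (is.null(name) || name == "") name <- paste0("genome", gi)
    lines <- c(lines, paste0(">", name))
    ch <- genome_chromosomes(gen)
    for (ci in seq_along(ch$chromosomes)) {
      ord <- ch$chromosomes[[ci]]
      ids <- sign(ord) * gen$gene_ids[abs(ord)]
      lines <- c(lines, paste(c(ids, if (ch$circular[ci]) ")" else "$"),
                              collapse = " "))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
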