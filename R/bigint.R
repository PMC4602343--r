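# Exact non-negative big-integer arithmetic on base-1e7 limb vectors.
#
# Internal support for the brute-force oracles, which must run in exact
# arithmetic: distribution numerators over a common denominator (a power of
# the per-step move count) grow far beyond 2^53.  Limbs are stored as doubles
# in little-endian order; every intermediate stays below 2^53 because limb
# products are bounded by 1e7 * 1e7 plus a carry.
#
# Only the operations the oracles need are provided: add, subtract (a >= b),
# multiply by a small integer (< 1e7), compare, integer power of a small
# base, and conversion of a ratio of two big integers to double.

BI_BASE <- 1e7

bi <- function(x) {
  stopifnot(length(x) == 1, x >= 0, x == floor(x), x < 2^53)
  if (x == 0) return(0)
  d <- numeric(0)
  while (x > 0) {
    d <- c(d, x %% BI_BASE)
    x <- x %/% BI_BASE
  }
  d
}

bi_norm <- function(d) {
  # propagate carries, strip leading (top) zeros
  while (any(d >= BI_BASE)) {
    carry <- d %/% BI_BASE
    d <- d - carry * BI_BASE
    d <- c(d, 0)[seq_len(length(d) + 1)]
    d[-1] <- d[-1] + carry
    while (length(d) > 1 && d[length(d)] == 0) d <- d[-length(d)]
  }
  while (length(d) > 1 && d[length(d)] == 0) d <- d[-length(d)]
  d
}

bi_add <- function(a, b) {
  l <- max(length(a), length(b))
  a <- c(a, numeric(l - length(a)))
  b <- c(b, numeric(l - length(b)))
  bi_norm(a + b)
}

bi_mul_s <- function(a, m) {
  stopifnot(m >= 0, m < BI_BASE)
  if (m == 0) return(0)
  bi_norm(a * m)
}

bi_cmp <- function(a, b) {
  l <- max(length(a), length(b))
  a <- c(a, numeric(l - length(a)))
  b <- c(b, numeric(l - length(b)))
  for (i in rev(seq_len(l))) {
    if (a[i] != b[i]) return(if (a[i] > b[i]) 1L else -1L)
  }
  0L
}

bi_eq <- function(a, b) bi_cmp(a, b) == 0L

bi_sub <- function(a, b) {
  if (bi_cmp(a, b) < 0) stop("bi_sub: negative result")
  l <- length(a)
  b <- c(b, numeric(l - length(b)))
  d <- a - b
  for (i in seq_len(l)) {
    if (d[i] < 0) {
      d[i] <- d[i] + BI_BASE
      d[i + 1] <- d[i + 1] - 1
    }
  }
  while (length(d) > 1 && d[length(d)] == 0) d <- d[-length(d)]
  d
}

bi_pow_s <- function(base, k) {
  out <- bi(1)
  for (i in seq_len(k)) out <- bi_mul_s(out, base)
  out
}

# a / b as a double, accurate to ~1e-15 relative (top 21 digits of each)
bi_ratio <- function(a, b) {
  top <- function(d) {
    l <- length(d)
    lo <- max(1L, l - 2L)
    v <- 0
    for (i in seq(l, lo)) v <- v * BI_BASE + d[i]  # highest limb first
    list(v = v, exp = lo - 1L)
  }
  ta <- top(a); tb <- top(b)
  (ta$v / tb$v) * BI_BASE^(ta$exp - tb$exp)
}

bi_to_num <- function(a) {
  v <- 0
  for (i in rev(seq_along(a))) v <- v * BI_BASE + a[i]
  v
}

# exact rational wrapper used by oracle return values
new_exact_rational <- function(num, den) {
  structure(list(num = num, den = den, value = bi_ratio(num, den)),
            class = "dcj_exact_rational")
}

#' @export
print.dcj_exact_rational <- function(x, ...) {
  cat(sprintf("<exact rational> ~ %.12g (numerator %d limbs / denominator %d limbs)\n",
              x$value, length(x$num), length(x$den)))
  invisible(x)
}

#' @export
format.dcj_exact_rational <- function(x, ...) {
  # serialized as "p/q" digit strings (lossless)
  digits <- function(d) {
    s <- sprintf("%07.0f", rev(d))
    s[1] <- sub("^0+(?=.)", "", s[1], perl = TRUE)
    paste(s, collapse = "")
  }
  paste0(digits(x$num), "/", digits(x$den))
}
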