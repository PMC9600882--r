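#' Exact rational numbers
#'
#' Stoichiometric coefficients and cofactor tallies in this package are exact
#' rationals: the balancer must return integer-exact coefficients and the
#' ledger invariants (redox closure, ATP totals such as 15/4) must hold with
#' no floating-point residue. `rational()` builds a vector of reduced
#' fractions; ordinary arithmetic (`+`, `-`, `*`, `/`, `==`, `<`, ...) works
#' through group generics and stays exact.
#'
#' Numerators and denominators are stored as whole-number doubles; all values
#' arising here are far below 2^53, so the representation is exact.
#'
#' @param num integer-valued numerators (or a `rational` to pass through).
#' @param den integer-valued denominators, recycled against `num`.
#' @return A `rational` vector.
#' @examples
#' rational(1, 3) + rational(1, 6)   # 1/2
#' sum(rational(c(2, 1), c(3, 6)) * rational(c(2, 1)))  # 3/2
#' @export
rational <- function(num, den = 1) {
  if (is.rational(num)) {
    if (!all(den == 1)) stop("cannot rescale an existing rational")
    return(num)
  }
  if (any(!is.finite(num)) || any(!is.finite(den))) {
    stop("rational parts must be finite")
  }
  if (any(num != round(num)) || any(den != round(den))) {
    stop("rational parts must be integer-valued")
  }
  if (any(den == 0)) stop("zero denominator")
  n <- length(num) ; d <- length(den)
  len <- if (n == 0L || d == 0L) 0L else max(n, d)
  num <- rep_len(num, len) ; den <- rep_len(den, len)
  rat_reduce(num, den)
}

rat_reduce <- function(num, den) {
  if (any(abs(num) > 2^53) || any(abs(den) > 2^53)) {
    stop("rational overflow: intermediate numerator/denominator exceeds ",
         "exact double-precision range")
  }
  sgn <- ifelse(den < 0, -1, 1)
  num <- num * sgn ; den <- den * sgn
  g <- rat_gcd(abs(num), den)
  g[g == 0] <- 1
  structure(list(num = num / g, den = den / g), class = "rational")
}

# vectorized Euclid on nonnegative whole doubles
rat_gcd <- function(a, b) {
  while (any(b > 0)) {
    t <- b
    b <- ifelse(b > 0, a %% b, 0)
    a <- ifelse(t > 0, t, a)
  }
  a
}

#' @rdname rational
#' @param x object to test or convert.
#' @export
is.rational <- function(x) inherits(x, "rational")

#' Convert to rational, approximating non-integers
#'
#' Doubles that are not integer-valued are converted by continued-fraction
#' expansion to the smallest-denominator fraction within `tol` (relative),
#' so `as_rational(1/3)` is exactly 1/3. This is also how noisy measured
#' spectra enter the exact balancer.
#'
#' @param x numeric or rational vector.
#' @param tol relative tolerance of the approximation.
#' @param max_den largest denominator considered.
#' @return A `rational` vector.
#' @export
as_rational <- function(x, tol = 1e-9, max_den = 1e9) {
  if (is.rational(x)) return(x)
  if (any(!is.finite(x))) stop("cannot convert non-finite values to rational")
  n <- d <- numeric(length(x))
  for (i in seq_along(x)) {
    if (x[i] == round(x[i])) {
      n[i] <- round(x[i]) ; d[i] <- 1
      next
    }
    nd <- rat_approx(x[i], tol, max_den)
    n[i] <- nd[1] ; d[i] <- nd[2]
  }
  rat_reduce(n, d)
}

# best rational approximation by continued fractions
rat_approx <- function(x, tol, max_den) {
  sgn <- sign(x) ; x <- abs(x)
  h0 <- 0 ; h1 <- 1 ; k0 <- 1 ; k1 <- 0
  z <- x
  repeat {
    a <- floor(z)
    h2 <- a * h1 + h0 ; k2 <- a * k1 + k0
    if (k2 > max_den) break
    h0 <- h1 ; h1 <- h2 ; k0 <- k1 ; k1 <- k2
    if (abs(h1 / k1 - x) <= tol * max(1, x)) break
    frac <- z - a
    if (frac < 1e-15) break
    z <- 1 / frac
  }
  c(sgn * h1, k1)
}

#' @rdname rational
#' @export
as.double.rational <- function(x, ...) x$num / x$den

#' @export
length.rational <- function(x) length(x$num)

#' @export
format.rational <- function(x, ...) {
  ifelse(x$den == 1, sprintf("%g", x$num), sprintf("%g/%g", x$num, x$den))
}

#' @export
print.rational <- function(x, ...) {
  print(format(x), quote = FALSE)
  invisible(x)
}

#' @export
`[.rational` <- function(x, i) {
  structure(list(num = x$num[i], den = x$den[i]), class = "rational")
}

#' @export
`[<-.rational` <- function(x, i, value) {
  value <- as_rational(value)
  x$num[i] <- value$num
  x$den[i] <- value$den
  x
}

#' @export
c.rational <- function(...) {
  parts <- lapply(list(...), as_rational)
  structure(list(num = unlist(lapply(parts, `[[`, "num")),
                 den = unlist(lapply(parts, `[[`, "den"))),
            class = "rational")
}

#' @export
rep.rational <- function(x, ...) {
  structure(list(num = rep(x$num, ...), den = rep(x$den, ...)),
            class = "rational")
}

#' @export
Ops.rational <- function(e1, e2) {
  if (missing(e2)) {
    e1 <- as_rational(e1)
    return(switch(.Generic,
      "-" = rat_reduce(-e1$num, e1$den),
      "+" = e1,
      stop("unary ", .Generic, " not defined for rationals")))
  }
  e1 <- as_rational(e1) ; e2 <- as_rational(e2)
  switch(.Generic,
    "+" = rat_reduce(e1$num * e2$den + e2$num * e1$den, e1$den * e2$den),
    "-" = rat_reduce(e1$num * e2$den - e2$num * e1$den, e1$den * e2$den),
    "*" = rat_reduce(e1$num * e2$num, e1$den * e2$den),
    "/" = {
      if (any(e2$num == 0)) stop("division of rational by zero")
      rat_reduce(e1$num * e2$den, e1$den * e2$num)
    },
    "==" = e1$num * e2$den == e2$num * e1$den,
    "!=" = e1$num * e2$den != e2$num * e1$den,
    "<"  = e1$num * e2$den <  e2$num * e1$den,
    "<=" = e1$num * e2$den <= e2$num * e1$den,
    ">"  = e1$num * e2$den >  e2$num * e1$den,
    ">=" = e1$num * e2$den >= e2$num * e1$den,
    stop(.Generic, " not defined for rationals"))
}

#' @export
sum.rational <- function(..., na.rm = FALSE) {
  x <- c.rational(...)
  acc <- rational(0)
  for (i in seq_len(length(x))) acc <- acc + x[i]
  acc
}

#' @export
abs.rational <- function(x) rat_reduce(abs(x$num), x$den)

#' Solve a linear system exactly over the rationals
#'
#' Gauss-Jordan elimination with exact rational pivoting. The system may be
#' square or overdetermined; an overdetermined system must be consistent.
#'
#' @param A rational (or integer-valued numeric) coefficient matrix given as a
#'   list with `num` and `den` matrices, or a plain numeric matrix.
#' @param b rational right-hand side.
#' @return A `rational` solution vector, or an error if the system is
#'   singular (underdetermined) or inconsistent. The error condition carries
#'   class `"caproscope_unbalanceable"` and, when identifiable, the row label
#'   of the offending constraint in field `offending`.
#' @keywords internal
rat_solve <- function(A, b) {
  if (is.matrix(A)) A <- list(num = A, den = array(1, dim(A)))
  m <- nrow(A$num) ; n <- ncol(A$num)
  b <- as_rational(b)
  stopifnot(length(b) == m)
  rows <- rownames(A$num)
  if (is.null(rows)) rows <- as.character(seq_len(m))
  # augmented system as flat rational vectors, row-major access helpers
  aug_n <- cbind(A$num, b$num)
  aug_d <- cbind(A$den, b$den)
  get <- function(i, j) rational(aug_n[i, j], aug_d[i, j])
  set <- function(i, j, v) {
    aug_n[i, j] <<- v$num ; aug_d[i, j] <<- v$den
  }
  piv_row <- integer(0)
  r <- 1L
  for (col in seq_len(n)) {
    if (r > m) break
    p <- which(aug_n[r:m, col] != 0)
    if (length(p) == 0) next
    p <- r + p[1L] - 1L
    if (p != r) {
      tmp <- aug_n[r, ] ; aug_n[r, ] <- aug_n[p, ] ; aug_n[p, ] <- tmp
      tmp <- aug_d[r, ] ; aug_d[r, ] <- aug_d[p, ] ; aug_d[p, ] <- tmp
      tmp <- rows[r] ; rows[r] <- rows[p] ; rows[p] <- tmp
    }
    piv <- get(r, col)
    for (j in seq_len(n + 1L)) set(r, j, get(r, j) / piv)
    for (i in seq_len(m)) {
      if (i == r) next
      f <- get(i, col)
      if (f$num == 0) next
      for (j in seq_len(n + 1L)) set(i, j, get(i, j) - f * get(r, j))
    }
    piv_row[col] <- r
    r <- r + 1L
  }
  rank <- r - 1L
  if (rank < n) {
    missing_cols <- setdiff(seq_len(n), which(!is.na(piv_row) & piv_row > 0))
    stop(errorCondition(
      paste0("singular system: no unique solution (free column ",
             paste(missing_cols, collapse = ", "), ")"),
      class = c("caproscope_unbalanceable", "error"),
      offending = NA_character_))
  }
  if (m > rank) {
    bad <- which(aug_n[(rank + 1L):m, n + 1L] != 0)
    if (length(bad)) {
      lbl <- rows[rank + bad[1L]]
      stop(errorCondition(
        paste0("inconsistent system: constraint '", lbl,
               "' cannot be satisfied (unbalanceable)"),
        class = c("caproscope_unbalanceable", "error"),
        offending = lbl))
    }
  }
  rational(aug_n[seq_len(n), n + 1L], aug_d[seq_len(n), n + 1L])
}
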