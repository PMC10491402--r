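# Truncated Taylor-series arithmetic.
#
# A `tser` holds the first L Taylor coefficients (in t) of a quantity along the
# system flow, for D independent evaluation points at once: coefficients are a
# D x L matrix, row = evaluation point/draw, column k = coefficient of t^(k-1).
# Arithmetic is either in double precision or exactly in the prime field Z_p
# (coefficients stored as doubles in [0, p); p^2 < 2^53 so products are exact).
#
# This is the engine behind generic-rank evaluation: the k-th Lie derivative of
# an output g along f equals k! times the k-th Taylor coefficient of g(x(t)),
# so OI-matrix entries are obtained exactly from series of the states and of
# their first-order sensitivities, with no nested symbolic differentiation.

MODP_PRIME <- 67108859  # largest prime below 2^26; (p-1)^2 < 2^53

newTser <- function(m, p = NULL) {
  structure(list(m = m, p = p), class = "tser")
}

# Constant series (value in column 1). `x` is a length-D vector or scalar.
tserConst <- function(x, D, L, p = NULL) {
  m <- matrix(0, D, L)
  m[, 1L] <- if (is.null(p)) x else x %% p
  newTser(m, p)
}

tserCoeff <- function(s, k) s$m[, k + 1L]  # coefficient of t^k

modReduce <- function(x, p) x %% p

# Vectorized modular inverse via Fermat (p prime).
modInv <- function(x, p) {
  if (any(x == 0)) stop(singularPointError("division by zero in the prime field"))
  modPow(x, p - 2, p)
}

modPow <- function(x, e, p) {
  r <- rep(1, length(x))
  b <- x %% p
  while (e > 0) {
    if (e %% 2 == 1) r <- (r * b) %% p
    b <- (b * b) %% p
    e <- e %/% 2
  }
  r
}

singularPointError <- function(msg) {
  structure(class = c("motifid_singular_point", "error", "condition"),
            list(message = msg, call = NULL))
}

asTser <- function(x, proto) {
  if (inherits(x, "tser")) return(x)
  tserConst(x, nrow(proto$m), ncol(proto$m), proto$p)
}

tserMul <- function(a, b) {
  p <- a$p
  L <- ncol(a$m)
  res <- matrix(0, nrow(a$m), L)
  for (k in seq_len(L)) {
    sub <- a$m[, seq_len(k), drop = FALSE] * b$m[, rev(seq_len(k)), drop = FALSE]
    if (!is.null(p)) sub <- sub %% p
    v <- rowSums(sub)
    res[, k] <- if (is.null(p)) v else v %% p
  }
  newTser(res, p)
}

tserDiv <- function(a, b) {
  p <- a$p
  L <- ncol(a$m)
  b0 <- b$m[, 1L]
  if (is.null(p)) {
    if (any(b0 == 0)) stop(singularPointError("division by a series with zero constant term"))
    inv0 <- 1 / b0
  } else {
    inv0 <- modInv(b0, p)
  }
  res <- matrix(0, nrow(a$m), L)
  for (k in seq_len(L)) {
    acc <- a$m[, k]
    if (k > 1L) {
      sub <- b$m[, 2:k, drop = FALSE] * res[, (k - 1L):1L, drop = FALSE]
      if (!is.null(p)) sub <- sub %% p
      acc <- acc - rowSums(sub)
    }
    if (!is.null(p)) acc <- acc %% p  # reduce before scaling (stay < 2^53)
    v <- acc * inv0
    res[, k] <- if (is.null(p)) v else v %% p
  }
  newTser(res, p)
}

tserPow <- function(a, n) {
  if (!is.numeric(n) || length(n) != 1L || n != round(n))
    stop("series powers must have integer exponents", call. = FALSE)
  if (n < 0) return(tserDiv(tserConst(1, nrow(a$m), ncol(a$m), a$p), tserPow(a, -n)))
  res <- tserConst(1, nrow(a$m), ncol(a$m), a$p)
  b <- a
  while (n > 0) {
    if (n %% 2 == 1) res <- tserMul(res, b)
    b <- if (n > 1) tserMul(b, b) else b
    n <- n %/% 2
  }
  res
}

#' @export
Ops.tser <- function(e1, e2) {
  if (missing(e2)) {  # unary + / -
    if (.Generic == "+") return(e1)
    if (.Generic == "-") {
      m <- -e1$m
      if (!is.null(e1$p)) m <- m %% e1$p
      return(newTser(m, e1$p))
    }
    stop("unsupported unary operator '", .Generic, "' for series", call. = FALSE)
  }
  proto <- if (inherits(e1, "tser")) e1 else e2
  a <- asTser(e1, proto)
  # `^` keeps a numeric exponent
  if (.Generic == "^" && !inherits(e2, "tser")) return(tserPow(a, e2))
  b <- asTser(e2, proto)
  switch(.Generic,
    "+" = {
      m <- a$m + b$m
      if (!is.null(a$p)) m <- m %% a$p
      newTser(m, a$p)
    },
    "-" = {
      m <- a$m - b$m
      if (!is.null(a$p)) m <- m %% a$p
      newTser(m, a$p)
    },
    "*" = tserMul(a, b),
    "/" = tserDiv(a, b),
    "^" = stop("series-valued exponents are not supported", call. = FALSE),
    stop("unsupported operator '", .Generic, "' for series", call. = FALSE)
  )
}

#' @export
Math.tser <- function(x, ...) {
  stop("non-rational function '", .Generic, "' is not supported in model expressions",
       call. = FALSE)
}

#' @export
print.tser <- function(x, ...) {
  cat("<taylor series: ", nrow(x$m), " draw(s) x order ", ncol(x$m) - 1L,
      if (!is.null(x$p)) paste0(", mod ", x$p), ">\n", sep = "")
  invisible(x)
}

# Evaluate an expression tree on series bindings. `bindings` is a named list of
# tser objects; numeric literals are promoted automatically by Ops.tser.
evalSeries <- function(e, bindings, proto) {
  if (is.numeric(e)) return(tserConst(e, nrow(proto$m), ncol(proto$m), proto$p))
  v <- eval(e, envir = bindings, enclos = baseenv())
  if (!inherits(v, "tser")) v <- tserConst(v, nrow(proto$m), ncol(proto$m), proto$p)
  v
}

# Exact rank of a D-free numeric matrix over Z_p by Gaussian elimination.
rankModP <- function(M, p) {
  M <- M %% p
  nr <- nrow(M); nc <- ncol(M)
  r <- 0L
  row <- 1L
  for (col in seq_len(nc)) {
    piv <- which(M[row:nr, col] != 0)
    if (length(piv) == 0L) next
    piv <- piv[1L] + row - 1L
    if (piv != row) M[c(piv, row), ] <- M[c(row, piv), ]
    inv <- modPow(M[row, col], p - 2, p)
    M[row, ] <- (M[row, ] * inv) %% p
    others <- setdiff(seq(row, nr), row)
    if (length(others)) {
      fac <- M[others, col]
      nz <- others[fac != 0]
      if (length(nz)) {
        M[nz, ] <- (M[nz, , drop = FALSE] -
                      outer(M[nz, col], M[row, ])) %% p
      }
    }
    r <- r + 1L
    row <- row + 1L
    if (row > nr) break
  }
  r
}

# Numeric rank with the singular-value threshold sigma_max * max(dim) * tol.
rankNumeric <- function(M, tol = 1e-10) {
  if (nrow(M) == 0L || ncol(M) == 0L) return(0L)
  d <- svd(M, nu = 0, nv = 0)$d
  if (!all(is.finite(d))) stop(singularPointError("non-finite matrix entries"))
  if (d[1L] == 0) return(0L)
  sum(d > d[1L] * max(dim(M)) * tol)
}
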