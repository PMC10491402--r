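# Small helpers for working with R expressions (calls) as symbolic objects.
# Models are rational expressions over states/parameters, so only the
# arithmetic operators +, -, *, /, ^ (integer powers) and parentheses occur.

#' @keywords internal
mkCall <- function(op, a, b) call(op, a, b)

# Build a sum / product of a list of expressions, dropping neutral elements.
exprSum <- function(terms) {
  terms <- terms[!vapply(terms, isZeroExpr, logical(1))]
  if (length(terms) == 0L) return(0)
  Reduce(function(a, b) call("+", a, b), terms)
}

exprProd <- function(factors) {
  factors <- factors[!vapply(factors, function(e) identical(e, 1) || identical(e, 1L), logical(1))]
  if (length(factors) == 0L) return(1)
  Reduce(function(a, b) call("*", a, b), factors)
}

isZeroExpr <- function(e) is.numeric(e) && length(e) == 1L && e == 0

#' Differentiate an expression with respect to one variable
#'
#' Thin wrapper around [stats::D()] restricted to the rational-function
#' grammar used throughout the package.
#' @keywords internal
exprDeriv <- function(e, var) {
  if (is.numeric(e)) return(0)
  stats::D(e, var)
}

# Substitute symbols in an expression; `subs` is a named list mapping
# symbol names to replacement expressions or numbers.
substituteExpr <- function(e, subs) {
  do.call(substitute, list(e, subs))
}

# Replace every occurrence of a subexpression (matched by identical()) with
# a replacement expression. Used when a flow expression is promoted to a state.
replaceSubexpr <- function(e, target, replacement) {
  if (identical(e, target)) return(replacement)
  if (is.call(e)) {
    for (i in seq_along(e)[-1L]) e[[i]] <- replaceSubexpr(e[[i]], target, replacement)
  }
  e
}

exprSymbols <- function(e) if (is.numeric(e)) character(0) else all.vars(e)

exprText <- function(e) {
  paste(deparse(e, width.cutoff = 500L), collapse = " ")
}

# Evaluate an expression at a named numeric point.
evalAtPoint <- function(e, point) {
  eval(e, envir = as.list(point))
}

# Validate that an expression only uses the supported rational grammar.
checkRationalExpr <- function(e, where = "expression") {
  if (is.numeric(e) || is.name(e)) return(invisible(TRUE))
  if (is.call(e)) {
    op <- as.character(e[[1L]])
    if (op == "(") return(checkRationalExpr(e[[2L]], where))
    if (op %in% c("+", "-", "*", "/") || (op == "^" && is.numeric(e[[3L]]))) {
      for (i in seq_along(e)[-1L]) checkRationalExpr(e[[i]], where)
      return(invisible(TRUE))
    }
    stop("unsupported operator '", op, "' in ", where,
         ": only +, -, *, /, ^<integer> are allowed", call. = FALSE)
  }
  stop("unsupported term in ", where, call. = FALSE)
}

# Numeric spot-check that two expressions agree as functions of their symbols.
# Used by tests and by the augmentation identity check; points are positive
# to stay clear of poles.
exprEquivalent <- function(e1, e2, npoints = 25L, tol = 1e-9, seed = NULL) {
  vars <- union(exprSymbols(e1), exprSymbols(e2))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  for (i in seq_len(npoints)) {
    point <- stats::runif(length(vars), 0.25, 2)
    names(point) <- vars
    v1 <- evalAtPoint(e1, point)
    v2 <- evalAtPoint(e2, point)
    scale <- max(1, abs(v1), abs(v2))
    if (!is.finite(v1) || !is.finite(v2) || abs(v1 - v2) > tol * scale) return(FALSE)
  }
  TRUE
}
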