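# Observability-identifiability core.
#
# Structural identifiability is decided as augmented observability: parameters
# are treated as states without dynamics, successive Lie derivatives of the
# outputs are stacked, and the model is (locally) identifiable and observable
# iff the Jacobian of the stack with respect to the augmented state x~ — the
# OI matrix — has generic rank N = n + q.
#
# Two evaluation routes exist:
#  * a symbolic route (lieStack / oiMatrix) built by repeated differentiation,
#    kept un-simplified; practical for small models and used for display and
#    cross-checks;
#  * the series engine (used by assess()), which computes OI rows at a point
#    without nested differentiation: the k-th Lie derivative equals k! times
#    the k-th Taylor coefficient of the output along the flow, and its gradient
#    w.r.t. x~ follows from first-order sensitivity series. Entries are exact
#    (Taylor coefficients of rational functions), so the rank at a random point
#    is the generic rank.
#
# Rank modes: "symbolic" evaluates rows exactly over the prime field Z_p at
# random integer points and returns the exact generic rank (maximum over
# points); "numeric" follows the randomized protocol with draws from
# U(0.5, 1.5) and an SVD rank, maximum over draws.

withSeed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  code
}

#' Successive Lie derivatives of the outputs
#'
#' Order 0 is the output vector itself; order j+1 is the directional
#' derivative of order j along the dynamics (parameters contribute no
#' dynamics). Expressions are kept un-simplified.
#'
#' @param om An `outputModel`.
#' @param k Maximum derivative order (>= 0).
#' @return A `lieStack`: list with `orders` (list of length k+1, each a list
#'   of m expressions).
#' @export
lieStack <- function(om, k) {
  stopifnot(k >= 0)
  dyn <- om$model$dynamics
  states <- om$model$states
  orders <- vector("list", k + 1L)
  orders[[1L]] <- om$outputs
  if (k > 0) for (j in seq_len(k)) {
    orders[[j + 1L]] <- lapply(orders[[j]], function(e) {
      exprSum(lapply(states, function(s) {
        d <- exprDeriv(e, s)
        if (isZeroExpr(d)) 0 else exprProd(list(d, dyn[[s]]))
      }))
    })
  }
  structure(list(orders = orders, om = om, k = k), class = "lieStack")
}

#' Symbolic observability-identifiability matrix
#'
#' Jacobian of the stacked Lie derivatives with respect to the augmented state
#' vector x~. Row blocks are ordered by derivative order; columns follow the
#' x~ order of the output model.
#'
#' @param om An `outputModel`.
#' @param k Highest Lie-derivative order to include. Orders beyond `N - 1`
#'   cannot raise the rank but are permitted (e.g. for display).
#' @return An `oiMatrix` with an `entries` list-matrix of dimension
#'   `m*(k+1) x N`.
#' @export
oiMatrix <- function(om, k) {
  ls <- lieStack(om, k)
  xt <- om$xt
  rows <- list()
  for (ord in ls$orders) {
    for (e in ord) rows[[length(rows) + 1L]] <- lapply(xt, exprDeriv, e = e)
  }
  entries <- matrix(do.call(c, rows), nrow = length(rows), byrow = TRUE)
  structure(list(entries = entries, k = k, om = om,
                 nrow = length(rows), ncol = length(xt)),
            class = "oiMatrix")
}

#' @export
print.oiMatrix <- function(x, ...) {
  cat("<OI matrix: ", x$nrow, " x ", x$ncol, " (orders 0..", x$k, ")>\n", sep = "")
  invisible(x)
}

# Scalar evaluation of an expression over Z_p at a named integer point.
evalModP <- function(e, point, p) {
  bind <- lapply(point, function(v) tserConst(v, 1L, 1L, p))
  s <- evalSeries(e, bind, bind[[1L]])
  s$m[1L, 1L]
}

#' Generic rank of a symbolic OI matrix
#'
#' Evaluates the matrix at random generic points and returns the maximum rank:
#' exactly over the prime field (`mode = "symbolic"`) or in double precision
#' at draws from U(low, high) (`mode = "numeric"`, the randomized protocol
#' with 10 repetitions).
#'
#' @param M An `oiMatrix`.
#' @param mode `"symbolic"` or `"numeric"`.
#' @param draws Number of random draws in numeric mode.
#' @param low,high Range of the uniform numeric draws.
#' @param points Number of random field points in symbolic mode.
#' @param seed Optional RNG seed (restored afterwards).
#' @param tol Relative singular-value tolerance for the numeric rank.
#' @return Integer rank, with attribute `perDraw` (rank at every draw/point).
#' @export
genericRank <- function(M, mode = c("symbolic", "numeric"), draws = 10L,
                        low = 0.5, high = 1.5, points = 3L, seed = NULL,
                        tol = 1e-10) {
  mode <- match.arg(mode)
  xt <- M$om$xt
  entryVars <- unique(unlist(lapply(M$entries, exprSymbols)))
  if (!all(entryVars %in% xt))
    stop("OI entries contain symbols outside x~", call. = FALSE)
  withSeed(seed, {
    nrep <- if (mode == "numeric") draws else points
    per <- integer(nrep)
    for (r in seq_len(nrep)) {
      per[r] <- withRetries(function() {
        if (mode == "numeric") {
          point <- stats::setNames(stats::runif(length(xt), low, high), xt)
          vals <- vapply(M$entries, function(e)
            if (is.numeric(e)) as.numeric(e) else evalAtPoint(e, point), numeric(1))
          rankNumeric(matrix(vals, M$nrow, M$ncol), tol)
        } else {
          p <- MODP_PRIME
          point <- stats::setNames(as.list(sample(p - 1L, length(xt), replace = TRUE)), xt)
          vals <- vapply(M$entries, function(e)
            if (is.numeric(e)) as.numeric(e) %% p else evalModP(e, point, p), numeric(1))
          rankModP(matrix(vals, M$nrow, M$ncol), p)
        }
      })
    }
    structure(max(per), perDraw = per)
  })
}

withRetries <- function(f, max = 20L) {
  for (i in seq_len(max)) {
    v <- tryCatch(f(), motifid_singular_point = function(e) e)
    if (!inherits(v, "condition")) return(v)
  }
  stop("evaluation failed: repeated singular evaluation points", call. = FALSE)
}

# ---------------------------------------------------------------------------
# Series engine

makeEngine <- function(om) {
  xt <- om$xt
  dyn <- om$model$states
  f <- om$model$dynamics[dyn]
  fJ <- lapply(f, function(e) lapply(xt, exprDeriv, e = e))
  gJ <- lapply(om$outputs, function(e) lapply(xt, exprDeriv, e = e))
  list(xt = xt, N = length(xt), dyn = dyn, n = length(dyn),
       dynIdx = match(dyn, xt), f = f, fJ = fJ, g = om$outputs, gJ = gJ,
       m = length(om$outputs))
}

# Coefficient of t^k of the product of two coefficient matrices (D x >=k+1).
convCoeff <- function(a, b, k, p) {
  sub <- a[, seq_len(k + 1L), drop = FALSE] * b[, (k + 1L):1L, drop = FALSE]
  if (!is.null(p)) sub <- sub %% p
  v <- rowSums(sub)
  if (is.null(p)) v else v %% p
}

# Run the series engine on a D x N matrix of evaluation points. `onBlock` is
# called with (k, block) for each derivative order, `block` a D x m x N array
# of OI-row entries; it returns TRUE to continue to the next order.
runEngine <- function(eng, P, prime, maxOrder, onBlock) {
  D <- nrow(P)
  xt <- eng$xt; N <- eng$N
  dynIdx <- eng$dynIdx; n <- eng$n
  vals <- P
  if (!is.null(prime)) vals <- vals %% prime
  Xc <- lapply(seq_len(N), function(j) matrix(vals[, j], D, 1L))
  names(Xc) <- xt
  Sc <- lapply(seq_len(n), function(i)
    lapply(seq_len(N), function(j) matrix(as.numeric(dynIdx[i] == j), D, 1L)))
  fact <- 1

  for (k in 0:maxOrder) {
    bind <- lapply(Xc, newTser, p = prime)
    proto <- bind[[1L]]
    evalG <- function(e) {
      if (isZeroExpr(e)) return(NULL)
      evalSeries(e, bind, proto)$m
    }
    # output sensitivity rows
    block <- array(0, dim = c(D, eng$m, N))
    for (o in seq_len(eng$m)) {
      G <- lapply(eng$gJ[[o]], evalG)
      for (j in seq_len(N)) {
        acc <- numeric(D)
        for (i in seq_len(n)) {
          Gi <- G[[dynIdx[i]]]
          if (is.null(Gi)) next
          acc <- acc + convCoeff(Gi, Sc[[i]][[j]], k, prime)
        }
        if (!(j %in% dynIdx) && !is.null(G[[j]]))
          acc <- acc + tserCoeffMat(G[[j]], k)
        if (!is.null(prime)) acc <- acc %% prime
        block[, o, j] <- if (is.null(prime)) fact * acc else (fact * acc) %% prime
      }
    }
    if (!onBlock(k, block) || k == maxOrder) return(invisible(NULL))

    # extend state and sensitivity series by one coefficient
    invk <- if (is.null(prime)) 1 / (k + 1) else modPow(k + 1, prime - 2, prime)
    Fc <- lapply(eng$f, function(e)
      if (isZeroExpr(e)) NULL else evalSeries(e, bind, proto)$m)
    Jc <- lapply(eng$fJ, function(row) lapply(row, evalG))
    newS <- Sc
    for (i in seq_len(n)) {
      fi <- Fc[[i]]
      co <- if (is.null(fi)) numeric(D) else tserCoeffMat(fi, k)
      co <- co * invk
      if (!is.null(prime)) co <- co %% prime
      Xc[[dynIdx[i]]] <- cbind(Xc[[dynIdx[i]]], co)
      for (j in seq_len(N)) {
        acc <- numeric(D)
        for (l in seq_len(n)) {
          Jl <- Jc[[i]][[dynIdx[l]]]
          if (is.null(Jl)) next
          acc <- acc + convCoeff(Jl, Sc[[l]][[j]], k, prime)
        }
        if (!(j %in% dynIdx) && !is.null(Jc[[i]][[j]]))
          acc <- acc + tserCoeffMat(Jc[[i]][[j]], k)
        # reduce before scaling so the product stays below 2^53
        if (!is.null(prime)) acc <- acc %% prime
        acc <- acc * invk
        if (!is.null(prime)) acc <- acc %% prime
        newS[[i]][[j]] <- cbind(Sc[[i]][[j]], acc)
      }
    }
    Sc <- newS
    for (j in setdiff(seq_len(N), dynIdx))
      Xc[[j]] <- cbind(Xc[[j]], 0)
    fact <- fact * (k + 1)
    if (!is.null(prime)) fact <- fact %% prime
  }
  invisible(NULL)
}

# k-th coefficient of a coefficient matrix, 0 if not yet present.
tserCoeffMat <- function(m, k) {
  if (ncol(m) >= k + 1L) m[, k + 1L] else numeric(nrow(m))
}

samplePoints <- function(mode, nrep, N, xt, low, high) {
  if (mode == "numeric") {
    P <- matrix(stats::runif(nrep * N, low, high), nrep, N)
  } else {
    P <- matrix(as.numeric(sample(MODP_PRIME - 1L, nrep * N, replace = TRUE)),
                nrep, N)
  }
  colnames(P) <- xt
  P
}

#' Assess structural identifiability of an output model
#'
#' Builds OI rows order by order, re-evaluating the generic rank after each
#' Lie-derivative order, and stops at the first of: full rank (identifiable),
#' a rank plateau (one more order left the rank unchanged; further orders
#' cannot raise it), or the maximum order N - 1.
#'
#' @param om An `outputModel` (see [buildOutputModel()]).
#' @param mode `"auto"` (symbolic up to `symbolicCeiling` unknowns, numeric
#'   above), `"symbolic"` (exact rank over a prime field at random points) or
#'   `"numeric"` (uniform random draws in `[low, high]`, SVD rank, maximum
#'   over draws).
#' @param draws Numeric-mode draw count (default 10).
#' @param points Symbolic-mode evaluation-point count.
#' @param low,high Numeric draw range.
#' @param seed Optional seed; the global RNG state is restored afterwards.
#' @param tol Relative singular-value tolerance (numeric mode).
#' @param symbolicCeiling Largest N for which `"auto"` picks symbolic mode.
#' @param maxOrder Cap on the Lie-derivative order (default N - 1).
#' @param minOrder Suppress the plateau stop below this order (used to verify
#'   that a plateau really is final).
#' @param keepRows Keep the per-draw row stacks (needed for column diagnosis).
#' @return A `rankResult` with fields `rank`, `N`, `identifiable`, `k_used`,
#'   `stop_condition`, `mode`, `ranksByOrder`, `perDrawRanks`, `seed`.
#' @examples
#' om <- buildOutputModel(buildModel("basic", 3, "B8"), c("A", "E"))
#' assess(om, mode = "symbolic", seed = 1)
#' @export
assess <- function(om, mode = c("auto", "symbolic", "numeric"), draws = 10L,
                   points = 3L, low = 0.5, high = 1.5, seed = NULL,
                   tol = 1e-10, symbolicCeiling = 8L, maxOrder = NULL,
                   minOrder = 0L, keepRows = FALSE) {
  mode <- match.arg(mode)
  if (mode == "auto") mode <- if (om$N <= symbolicCeiling) "symbolic" else "numeric"
  eng <- makeEngine(om)
  N <- eng$N
  if (is.null(maxOrder)) maxOrder <- N - 1L
  maxOrder <- min(maxOrder, N - 1L)
  prime <- if (mode == "symbolic") MODP_PRIME else NULL
  nrep <- if (mode == "numeric") draws else points
  rankFun <- if (mode == "numeric") function(M) rankNumeric(M, tol)
             else function(M) rankModP(M, prime)

  withSeed(seed, withRetries(function() {
    P <- samplePoints(mode, nrep, N, eng$xt, low, high)
    rowsList <- rep(list(matrix(0, 0L, N)), nrep)
    ranks <- integer(0)
    perDraw <- integer(nrep)
    stopCond <- "max_order"
    onBlock <- function(k, block) {
      for (d in seq_len(nrep))
        rowsList[[d]] <<- rbind(rowsList[[d]], matrix(block[d, , ], ncol = N))
      perDraw <<- vapply(rowsList, rankFun, numeric(1))
      r <- max(perDraw)
      ranks <<- c(ranks, r)
      if (r >= N) { stopCond <<- "full_rank"; return(FALSE) }
      if (k >= max(1L, minOrder) && r == ranks[[k]]) {
        stopCond <<- "rank_plateau"; return(FALSE)
      }
      TRUE
    }
    runEngine(eng, P, prime, maxOrder, onBlock)
    res <- list(
      rank = as.integer(max(perDraw)), N = N,
      identifiable = max(perDraw) >= N,
      k_used = length(ranks) - 1L, stop_condition = stopCond,
      mode = mode, seed = seed,
      draws = nrep, ranksByOrder = as.integer(ranks),
      perDrawRanks = as.integer(perDraw),
      drawsAgree = length(unique(perDraw)) == 1L,
      om = om
    )
    if (keepRows) { res$rows <- rowsList; res$points <- P; res$prime <- prime }
    structure(res, class = "rankResult")
  }))
}

#' @export
print.rankResult <- function(x, ...) {
  cat("<rank result: ", x$om$model$meta$label, ", y = {",
      comboKey(x$om$combo), "}, method ", x$om$method, ">\n", sep = "")
  cat(sprintf("  rank %d of N = %d -> %s\n", x$rank, x$N,
              if (x$identifiable) "structurally identifiable and observable"
              else "structurally unidentifiable/unobservable"))
  cat(sprintf("  mode %s, Lie orders 0..%d, stop: %s\n",
              x$mode, x$k_used, x$stop_condition))
  if (!x$drawsAgree)
    cat("  note: per-draw ranks disagreed; generic rank is the maximum:",
        paste(x$perDrawRanks, collapse = " "), "\n")
  invisible(x)
}

#' Per-element identifiability diagnosis
#'
#' Classifies each element of x~ by column analysis of the OI matrix built to
#' the stopping order: an element is identifiable (parameter) or observable
#' (state) iff deleting its column lowers the generic rank.
#'
#' @inheritParams assess
#' @param ... Passed to [assess()].
#' @return An `elementDiagnosis` data frame (element, role, identifiable) with
#'   the partition stored in attributes `identifiableParams`,
#'   `unidentifiableParams`, `observableStates`, `unobservableStates`.
#' @export
elementIdentifiability <- function(om, mode = c("auto", "symbolic", "numeric"),
                                   ...) {
  res <- assess(om, mode = match.arg(mode), keepRows = TRUE, ...)
  rankFun <- if (res$mode == "numeric") rankNumeric
             else function(M) rankModP(M, res$prime)
  N <- res$N
  flags <- logical(N)
  for (j in seq_len(N)) {
    rj <- max(vapply(res$rows, function(M) rankFun(M[, -j, drop = FALSE]),
                     numeric(1)))
    flags[j] <- (rj == res$rank - 1L)
  }
  xt <- om$xt
  isState <- xt %in% om$model$states
  role <- ifelse(isState, "state", "parameter")
  out <- data.frame(element = xt, role = role, identifiable = flags,
                    stringsAsFactors = FALSE)
  structure(out, class = c("elementDiagnosis", "data.frame"),
            rank = res$rank, N = N,
            identifiableParams = xt[!isState & flags],
            unidentifiableParams = xt[!isState & !flags],
            observableStates = xt[isState & flags],
            unobservableStates = xt[isState & !flags])
}

#' @export
print.elementDiagnosis <- function(x, ...) {
  cat("<element diagnosis: rank ", attr(x, "rank"), " of ", attr(x, "N"), ">\n",
      sep = "")
  cat("  identifiable parameters:  ",
      paste(attr(x, "identifiableParams"), collapse = ", "), "\n")
  cat("  unidentifiable parameters:",
      paste(attr(x, "unidentifiableParams"), collapse = ", "), "\n")
  cat("  observable states:        ",
      paste(attr(x, "observableStates"), collapse = ", "), "\n")
  cat("  unobservable states:      ",
      paste(attr(x, "unobservableStates"), collapse = ", "), "\n")
  invisible(x)
}

#' Verify a Lie symmetry generator
#'
#' Checks whether an infinitesimal generator v lies in the null space of the
#' OI matrix built to the stopping order, i.e. OI(x~) v = 0: existence of such
#' a symmetry certifies structural unidentifiability.
#'
#' @param om An `outputModel`.
#' @param generator Named list mapping x~ element names to component
#'   expressions (or numbers); omitted elements are zero.
#' @inheritParams assess
#' @param ... Passed to [assess()].
#' @return `TRUE` iff the generator annihilates the OI rows (exactly in
#'   symbolic mode; within tolerance at every draw in numeric mode), with
#'   attribute `rank` carrying the underlying rank result.
#' @export
checkSymmetry <- function(om, generator, mode = c("auto", "symbolic", "numeric"),
                          tol = 1e-8, ...) {
  xt <- om$xt
  if (is.null(names(generator)) || !all(nzchar(names(generator))))
    stop("generator components must be named after x~ elements", call. = FALSE)
  bad <- setdiff(names(generator), xt)
  if (length(bad))
    stop("generator dimension mismatch: unknown element(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  res <- assess(om, mode = match.arg(mode), keepRows = TRUE, ...)
  prime <- res$prime
  anyNonZero <- FALSE
  ok <- TRUE
  for (d in seq_along(res$rows)) {
    point <- res$points[d, ]
    w <- numeric(res$N)
    names(w) <- xt
    for (nm in names(generator)) {
      g <- generator[[nm]]
      w[nm] <- if (is.numeric(g)) {
        if (is.null(prime)) g else g %% prime
      } else if (is.null(prime)) {
        evalAtPoint(g, point)
      } else {
        evalModP(g, as.list(point), prime)
      }
    }
    if (any(w != 0)) anyNonZero <- TRUE
    if (is.null(prime)) {
      resid <- res$rows[[d]] %*% w
      scale <- max(1, max(abs(res$rows[[d]])) * max(abs(w)))
      if (max(abs(resid)) > tol * scale) ok <- FALSE
    } else {
      # accumulate the modular matrix-vector product column-wise so every
      # intermediate stays well below 2^53
      M <- res$rows[[d]]
      resid <- numeric(nrow(M))
      for (j in seq_len(ncol(M)))
        resid <- (resid + (M[, j] * w[j]) %% prime) %% prime
      if (any(resid != 0)) ok <- FALSE
    }
  }
  if (!anyNonZero)
    stop("generator is identically zero at the evaluation points", call. = FALSE)
  structure(ok, rank = res, class = "symmetryCheck")
}

#' @export
print.symmetryCheck <- function(x, ...) {
  res <- attr(x, "rank")
  if (isTRUE(x)) {
    cat(sprintf("symmetry confirmed: OI(x~) v = 0 (rank %d of %d)\n",
                res$rank, res$N))
  } else {
    cat("no symmetry: the generator is not annihilated by the OI matrix\n")
  }
  invisible(x)
}
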