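# The controller-motif model library.
#
# Basic motifs: two species, the controlled species A and the controller E,
#   dA/dt = di - do +/- jc,   dE/dt = js - jd.
# Antithetic motifs: A plus two controller species E1, E2 that annihilate each
# other (ja = ka*E1*E2), implementing integral feedback:
#   dA/dt = di - do +/- jc,  dE1/dt = js1 - ja,  dE2/dt = js2 - ja.
# Eight wirings per family (inflow/outflow compensation x activating/inhibiting
# actuation x sensing channel), and per-wiring "cases" that grade model
# complexity: one or both disturbances, first-order vs saturable activation
# kinetics, and (basic only) zero-order / first-order / Michaelis-Menten
# degradation of E.

PARAM_ORDER <- c("ki", "ko", "kc", "ks", "kd", "ks1", "ks2", "ka",
                 "KaA", "KaE", "KiA", "KiE", "KME")

FLOW_ORDER <- c("di", "do", "jc", "js", "jd", "js1", "js2", "ja")

# Leading rate constant of each flow (the one eliminated when the flow is
# promoted to a state).
FLOW_RATE_CONSTANT <- c(di = "ki", do = "ko", jc = "kc", js = "ks", jd = "kd",
                        js1 = "ks1", js2 = "ks2", ja = "ka")

# Wiring of the 8 basic motifs: compensation direction, sign of the E -> jc
# actuation link, and the channel/sign with which A is sensed by the controller.
basicWiring <- function() {
  data.frame(
    index = 1:8,
    type = rep(c("inflow", "outflow"), each = 4L),
    actuation = rep(c("activating", "inhibiting"), 4L),
    senseChannel = c("jd", "js", "js", "jd", "js", "jd", "jd", "js"),
    senseSign = c("activating", "activating", "inhibiting", "inhibiting",
                  "activating", "activating", "inhibiting", "inhibiting"),
    stringsAsFactors = FALSE
  )
}

# Antithetic wiring mirrors the basic set one-to-one: actuation through E1,
# sensing of A through the synthesis of E1 (direct channel, analogue of js) or
# of E2 (indirect, sign-inverting through the annihilation reaction, analogue
# of jd); the sensing sign pattern is copied from the basic motifs so each
# closed loop is negative.
antitheticWiring <- function() {
  data.frame(
    index = 1:8,
    type = rep(c("inflow", "outflow"), each = 4L),
    actuation = rep(c("activating", "inhibiting"), 4L),
    senseChannel = c("js2", "js1", "js1", "js2", "js1", "js2", "js2", "js1"),
    senseSign = c("activating", "activating", "inhibiting", "inhibiting",
                  "activating", "activating", "inhibiting", "inhibiting"),
    stringsAsFactors = FALSE
  )
}

#' Case identifiers of the motif library
#'
#' Basic cases `B1`-`B12` grade complexity along three axes: disturbances
#' (`B1`-`B6` keep only the motif's main disturbance, `B7`-`B12` carry both
#' `di` and `do`), activation kinetics (`B1`-`B3`/`B7`-`B9` first order,
#' `B4`-`B6`/`B10`-`B12` saturable) and degradation of E (each triplet runs
#' zero order, first order, Michaelis-Menten). Antithetic cases `A1`-`A4`
#' cross disturbances with activation kinetics only; degradation of the
#' controller species is always the annihilation flow.
#'
#' @param family `"basic"` or `"antithetic"`.
#' @return A data frame with columns `case`, `disturbances`
#'   (`"one"`/`"both"`), `activation` (`"first_order"`/`"saturable"`) and,
#'   for the basic family, `eDegradation`
#'   (`"zero"`/`"first"`/`"michaelis_menten"`).
#' @export
listCases <- function(family = c("basic", "antithetic")) {
  family <- match.arg(family)
  if (family == "basic") {
    data.frame(
      case = paste0("B", 1:12),
      disturbances = rep(c("one", "both"), each = 6L),
      activation = rep(rep(c("first_order", "saturable"), each = 3L), 2L),
      eDegradation = rep(c("zero", "first", "michaelis_menten"), 4L),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(
      case = paste0("A", 1:4),
      disturbances = rep(c("one", "both"), each = 2L),
      activation = rep(c("first_order", "saturable"), 2L),
      stringsAsFactors = FALSE
    )
  }
}

# Activation/inhibition kinetics factor for a regulating species.
regulatorExpr <- function(species, sign, activation, Ka, Ki) {
  s <- as.name(species)
  if (sign == "activating") {
    if (activation == "first_order") s
    else call("/", s, call("+", as.name(Ka), s))
  } else {
    call("/", as.name(Ki), call("+", as.name(Ki), s))
  }
}

# Ordered signed sum of expressions: list of list(sign = +/-1, expr).
signedSum <- function(terms) {
  acc <- NULL
  for (t in terms) {
    if (is.null(t)) next
    if (is.null(acc)) {
      acc <- if (t$sign > 0) t$expr else call("-", t$expr)
    } else {
      acc <- call(if (t$sign > 0) "+" else "-", acc, t$expr)
    }
  }
  if (is.null(acc)) 0 else acc
}

orderedParams <- function(flows, dynamics, states) {
  vars <- unique(unlist(c(lapply(flows, exprSymbols),
                          lapply(dynamics, exprSymbols))))
  vars <- setdiff(vars, states)
  c(PARAM_ORDER[PARAM_ORDER %in% vars],
    sort(setdiff(vars, PARAM_ORDER)))
}

newModel <- function(states, dynamics, flows, relations, meta) {
  params <- orderedParams(flows, dynamics, states)
  structure(
    list(states = states, params = params, dynamics = dynamics,
         flows = flows, relations = relations, meta = meta),
    class = "ctrlModel"
  )
}

#' Construct one controller-motif model
#'
#' Assembles the symbolic ODE model for a motif/case selection: state symbols,
#' parameter symbols (in a fixed canonical order), dynamics, named flow
#' expressions and species-relation metadata.
#'
#' @param family `"basic"` or `"antithetic"`.
#' @param index Motif index 1-8 (1-4 inflow controllers, 5-8 outflow).
#' @param case Case identifier, `"B1"`-`"B12"` or `"A1"`-`"A4"` (see
#'   [listCases()]).
#' @return A `ctrlModel` object.
#' @examples
#' m <- buildModel("basic", 2, "B7")
#' m$dynamics$A   # ki - ko*A + kc*KiE/(KiE + E)
#' @export
buildModel <- function(family = c("basic", "antithetic"), index, case) {
  family <- match.arg(family)
  if (!(is.numeric(index) && length(index) == 1L && index %in% 1:8))
    stop("invalid motif selection: index must be 1..8", call. = FALSE)
  index <- as.integer(index)
  cases <- listCases(family)
  ci <- match(case, cases$case)
  if (is.na(ci))
    stop("invalid motif selection: unknown case '", case, "' for family '",
         family, "'", call. = FALSE)
  cs <- cases[ci, ]
  wiring <- if (family == "basic") basicWiring() else antitheticWiring()
  w <- wiring[index, ]

  hasDi <- cs$disturbances == "both" || w$type == "outflow"
  hasDo <- cs$disturbances == "both" || w$type == "inflow"

  flows <- list()
  if (hasDi) flows$di <- quote(ki)
  if (hasDo) flows$do <- quote(ko * A)

  if (family == "basic") {
    jcReg <- regulatorExpr("E", w$actuation, cs$activation, "KaE", "KiE")
    flows$jc <- if (w$type == "inflow") call("*", quote(kc), jcReg)
                else call("*", call("*", quote(kc), jcReg), quote(A))
    senseReg <- regulatorExpr("A", w$senseSign, cs$activation, "KaA", "KiA")
    flows$js <- if (w$senseChannel == "js") call("*", quote(ks), senseReg)
                else quote(ks)
    eFactor <- switch(cs$eDegradation,
                      zero = NULL,
                      first = quote(E),
                      michaelis_menten = quote(E / (KME + E)))
    jd <- quote(kd)
    if (w$senseChannel == "jd") jd <- call("*", jd, senseReg)
    if (!is.null(eFactor)) jd <- call("*", jd, eFactor)
    flows$jd <- jd

    dynamics <- list(
      A = signedSum(list(
        if (hasDi) list(sign = 1, expr = flows$di),
        if (hasDo) list(sign = -1, expr = flows$do),
        list(sign = if (w$type == "inflow") 1 else -1, expr = flows$jc)
      )),
      E = signedSum(list(list(sign = 1, expr = flows$js),
                         list(sign = -1, expr = flows$jd)))
    )
    states <- c("A", "E")
    relations <- list(A = "A", E = "E")
    for (f in names(flows)) relations[[f]] <- if (f %in% c("di", "do", "jc")) "A" else "E"
  } else {
    jcReg <- regulatorExpr("E1", w$actuation, cs$activation, "KaE", "KiE")
    flows$jc <- if (w$type == "inflow") call("*", quote(kc), jcReg)
                else call("*", call("*", quote(kc), jcReg), quote(A))
    senseReg <- regulatorExpr("A", w$senseSign, cs$activation, "KaA", "KiA")
    flows$js1 <- if (w$senseChannel == "js1") call("*", quote(ks1), senseReg)
                 else quote(ks1)
    flows$js2 <- if (w$senseChannel == "js2") call("*", quote(ks2), senseReg)
                 else quote(ks2)
    flows$ja <- quote(ka * E1 * E2)

    dynamics <- list(
      A = signedSum(list(
        if (hasDi) list(sign = 1, expr = flows$di),
        if (hasDo) list(sign = -1, expr = flows$do),
        list(sign = if (w$type == "inflow") 1 else -1, expr = flows$jc)
      )),
      E1 = signedSum(list(list(sign = 1, expr = flows$js1),
                          list(sign = -1, expr = flows$ja))),
      E2 = signedSum(list(list(sign = 1, expr = flows$js2),
                          list(sign = -1, expr = flows$ja)))
    )
    states <- c("A", "E1", "E2")
    relations <- list(A = "A", E1 = "E1", E2 = "E2")
    for (f in names(flows)) {
      relations[[f]] <- switch(f, di = "A", do = "A", jc = "A",
                               js1 = "E1", js2 = "E2", ja = c("E1", "E2"))
    }
  }

  meta <- list(
    family = family, index = index, case = cs$case,
    controllerType = w$type, actuationSign = w$actuation,
    sensingChannel = w$senseChannel, sensingSign = w$senseSign,
    disturbances = cs$disturbances, activation = cs$activation,
    eDegradation = if (family == "basic") cs$eDegradation else NA_character_,
    label = paste(family, "motif", index, "case", cs$case)
  )
  newModel(states, dynamics, flows, relations, meta)
}

#' Enumerate the full motif library
#'
#' @param family Families to include; default both.
#' @return List of all `ctrlModel`s in stable order: basic motifs 1-8 each
#'   with cases B1-B12 (96 models), then antithetic motifs 1-8 each with
#'   A1-A4 (32 models); 128 in total. Structurally duplicated entries (motifs
#'   whose links are all inhibiting, so first-order and saturable cases
#'   coincide) are retained as distinct entries.
#' @export
enumerateModels <- function(family = c("basic", "antithetic")) {
  family <- match.arg(family, several.ok = TRUE)
  out <- list()
  for (fam in family) {
    cases <- listCases(fam)$case
    for (i in 1:8) for (cs in cases) out[[length(out) + 1L]] <- buildModel(fam, i, cs)
  }
  out
}

#' Number of states / parameters of a model
#' @param model A `ctrlModel`.
#' @export
modelSize <- function(model) length(model$states) + length(model$params)

#' @export
print.ctrlModel <- function(x, ...) {
  cat("<", x$meta$label, ">\n", sep = "")
  cat("  states:", paste(x$states, collapse = ", "), "\n")
  cat("  params:", paste(x$params, collapse = ", "),
      sprintf(" (n + q = %d)\n", modelSize(x)))
  for (s in x$states) cat("  d", s, "/dt = ", exprText(x$dynamics[[s]]), "\n", sep = "")
  if (length(x$flows)) {
    cat("  flows:\n")
    for (f in names(x$flows)) cat("    ", f, " = ", exprText(x$flows[[f]]), "\n", sep = "")
  }
  invisible(x)
}

#' Sign of the feedback loop gain at a point
#'
#' Evaluates the product of the partial derivatives along the closed
#' A -> controller -> A signalling loop at a strictly positive point. All
#' library motifs are negative-feedback circuits, so the sign must be negative;
#' this is a wiring self-check.
#'
#' @param model A `ctrlModel` from the library (basic or antithetic states).
#' @param point Named strictly positive numeric vector covering states and
#'   parameters.
#' @return `-1` or `+1`.
#' @export
loopGainSign <- function(model, point) {
  vars <- c(model$states, model$params)
  if (!all(vars %in% names(point)))
    stop("point must assign values to all states and parameters", call. = FALSE)
  if (any(point[vars] <= 0))
    stop("point must be strictly positive", call. = FALSE)
  d <- model$dynamics
  if (setequal(model$states, c("A", "E"))) {
    parts <- c(evalAtPoint(exprDeriv(d$E, "A"), point),
               evalAtPoint(exprDeriv(d$A, "E"), point))
  } else if (setequal(model$states, c("A", "E1", "E2"))) {
    viaE1 <- evalAtPoint(exprDeriv(d$E1, "A"), point)
    if (viaE1 != 0) {
      parts <- c(viaE1, evalAtPoint(exprDeriv(d$A, "E1"), point))
    } else {
      parts <- c(evalAtPoint(exprDeriv(d$E2, "A"), point),
                 evalAtPoint(exprDeriv(d$E1, "E2"), point),
                 evalAtPoint(exprDeriv(d$A, "E1"), point))
    }
  } else {
    stop("loop gain is defined for library motif models only", call. = FALSE)
  }
  if (any(parts == 0))
    stop("degenerate point: a loop partial derivative vanishes", call. = FALSE)
  if (prod(sign(parts)) < 0) -1 else 1
}

#' Toy fixture models with known identifiability verdicts
#'
#' @return A list of three `ctrlModel`s: `decay` (x' = -k x, identifiable from
#'   y = x), `decay_scaled` (x' = -k x observed through y = c x, structurally
#'   unidentifiable by the scaling symmetry x -> lambda x, c -> c/lambda) and
#'   `chain` (a two-state linear chain observed at the end).
#' @export
toyModels <- function() {
  decay <- newModel(
    states = "x",
    dynamics = list(x = quote(-(k * x))),
    flows = list(),
    relations = list(x = "x"),
    meta = list(family = "toy", index = NA_integer_, case = "decay",
                label = "toy decay model")
  )
  scaled <- newModel(
    states = "x",
    dynamics = list(x = quote(-(k * x))),
    flows = list(yobs = quote(c * x)),
    relations = list(x = "x", yobs = "x"),
    meta = list(family = "toy", index = NA_integer_, case = "decay_scaled",
                label = "toy scaled-output decay model")
  )
  chain <- newModel(
    states = c("x1", "x2"),
    dynamics = list(x1 = quote(-(k1 * x1)), x2 = quote(k1 * x1 - k2 * x2)),
    flows = list(j1 = quote(k1 * x1), j2 = quote(k2 * x2)),
    relations = list(x1 = "x1", x2 = "x2", j1 = "x1", j2 = "x2"),
    meta = list(family = "toy", index = NA_integer_, case = "chain",
                label = "toy two-state chain")
  )
  list(decay = decay, decay_scaled = scaled, chain = chain)
}
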