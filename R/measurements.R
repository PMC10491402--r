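# Measurement combinations and output models.
#
# A measurement is either a species concentration (a state symbol) or a named
# flow. Flow measurements enter the output vector y in one of two ways:
# method 1 promotes the flow to a new state (its state equation is the total
# time derivative of the flow expression, with the flow's leading rate
# constant eliminated by substitution so the number of unknowns is unchanged);
# method 2 places the flow expression directly in y.

#' Species relation of a measurement
#'
#' Maps a measurement to the chemical species it is related to: a
#' concentration to its own species, a flow to the species whose balance
#' equation it appears in (the annihilation flow `ja` relates to both
#' controller species).
#'
#' @param measurement Measurement token (state name or flow name).
#' @param model A `ctrlModel`.
#' @return Character vector of species names.
#' @export
speciesRelation <- function(measurement, model) {
  rel <- model$relations[[measurement]]
  if (is.null(rel))
    stop("measurement '", measurement, "' is not available in this model",
         call. = FALSE)
  rel
}

# Measurements available in a model: concentrations (original species, in
# state order), then flows in canonical flow-table order.
availableMeasurements <- function(model) {
  species <- intersect(model$states, names(model$relations))
  flows <- c(FLOW_ORDER[FLOW_ORDER %in% names(model$flows)],
             setdiff(names(model$flows), FLOW_ORDER))
  # flows already promoted to states (method 1 intermediates) are not re-offered
  flows <- setdiff(flows, model$states)
  list(concentrations = species, flows = flows)
}

comboKey <- function(members) paste(members, collapse = ",")

#' Enumerate measurement combinations
#'
#' All one- and two-element subsets of the available concentration and flow
#' measurements, ordered the way the result grids are laid out: concentration
#' combos first, then single flows, then concentration + flow pairs (grouped
#' by the species relation of the flow, and within a group by concentration),
#' then flow pairs in flow-table order.
#'
#' @param model A `ctrlModel`.
#' @return List of character vectors (measurement tokens, canonical order:
#'   concentrations before flows).
#' @export
enumerateCombos <- function(model) {
  av <- availableMeasurements(model)
  concs <- av$concentrations
  flows <- av$flows
  combos <- list()
  add <- function(x) combos[[length(combos) + 1L]] <<- x

  for (s in concs) add(s)
  if (length(concs) >= 2L)
    for (i in seq_len(length(concs) - 1L))
      for (j in (i + 1L):length(concs)) add(c(concs[i], concs[j]))
  for (f in flows) add(f)
  # concentration + flow, grouped by the flow's species relation
  relKey <- vapply(flows, function(f) paste(speciesRelation(f, model), collapse = "+"),
                   character(1))
  for (grp in unique(relKey))
    for (s in concs)
      for (f in flows[relKey == grp]) add(c(s, f))
  if (length(flows) >= 2L)
    for (i in seq_len(length(flows) - 1L))
      for (j in (i + 1L):length(flows)) add(c(flows[i], flows[j]))
  combos
}

#' Promote a flow to a model state (method 1 augmentation)
#'
#' Replaces every occurrence of the flow expression in the dynamics by a new
#' state named after the flow, removes the flow's leading rate constant from
#' the parameter list (it is recovered algebraically from the new state), and
#' derives the new state equation as the total time derivative of the flow
#' expression with the rate constant substituted out.
#'
#' @param model A `ctrlModel`.
#' @param flow Flow name present in `model$flows`.
#' @return The augmented `ctrlModel`; trajectories of the original model are
#'   preserved when the new state starts at the flow's initial value.
#' @export
augmentFlowState <- function(model, flow) {
  expr <- model$flows[[flow]]
  if (is.null(expr))
    stop("invalid selection: flow '", flow, "' is not part of this model",
         call. = FALSE)
  if (identical(expr, as.name(flow)) || flow %in% model$states)
    stop("flow '", flow, "' is already a state", call. = FALSE)
  k <- unname(FLOW_RATE_CONSTANT[flow])
  if (is.na(k)) {
    # user-defined flow: take the first parameter appearing in the expression
    cand <- intersect(model$params, exprSymbols(expr))
    k <- if (length(cand)) cand[1L] else NA_character_
  }
  if (is.na(k) || !(k %in% exprSymbols(expr)))
    stop("unsupported flow: no eliminable multiplicative rate constant in '",
         flow, "'", call. = FALSE)
  phi <- substituteExpr(expr, stats::setNames(list(1), k))
  # the eliminated constant must factor out multiplicatively: j = k * phi
  if (k %in% exprSymbols(phi) ||
      !exprEquivalent(expr, call("*", as.name(k), call("(", phi)), seed = 421L))
    stop("unsupported flow: rate constant '", k,
         "' does not factor out of '", flow, "'", call. = FALSE)

  J <- as.name(flow)
  dyn <- lapply(model$dynamics, replaceSubexpr, target = expr, replacement = J)

  # dJ/dt = J * (d phi / dt) / phi, with the replaced dynamics
  phiStates <- intersect(model$states, exprSymbols(phi))
  dphi <- exprSum(lapply(phiStates, function(s)
    exprProd(list(exprDeriv(phi, s), dyn[[s]]))))
  dyn[[flow]] <- if (isZeroExpr(dphi)) 0
                 else call("/", call("*", J, call("(", dphi)), call("(", phi))

  flows <- model$flows
  flows[[flow]] <- J
  newStates <- c(model$states, flow)
  meta <- model$meta
  meta$augmented <- c(meta$augmented, stats::setNames(k, flow))
  m <- newModel(newStates, dyn, flows, model$relations, meta)
  if (k %in% m$params)
    stop("internal error: eliminated constant still present")  # nocov
  m
}

#' Attach outputs to a model
#'
#' Builds the output model for a measurement combination under either flow
#' method. The augmented state vector (states followed by parameters; under
#' method 1 each flow-state occupies the slot of its eliminated rate constant)
#' has the same length N under both methods.
#'
#' @param model A `ctrlModel`.
#' @param combo Character vector of 1-2 measurement tokens.
#' @param method 1 (flows as states) or 2 (flow expressions in the output).
#' @return An `outputModel`: the (possibly augmented) model, output
#'   expressions, and the ordered augmented state vector `xt` of length `N`.
#' @export
buildOutputModel <- function(model, combo, method = 2L) {
  method <- as.integer(method)
  if (!method %in% c(1L, 2L)) stop("method must be 1 or 2", call. = FALSE)
  combo <- as.character(combo)
  if (length(combo) < 1L || length(combo) > 2L || anyDuplicated(combo))
    stop("a measurement combination has 1 or 2 distinct members", call. = FALSE)
  av <- availableMeasurements(model)
  bad <- setdiff(combo, c(av$concentrations, av$flows))
  if (length(bad))
    stop("invalid selection: measurement(s) ", paste(bad, collapse = ", "),
         " not available in this model", call. = FALSE)
  # canonical member order: concentrations first, then flow-table order
  combo <- c(intersect(av$concentrations, combo),
             intersect(av$flows, combo))

  flowsMeasured <- intersect(av$flows, combo)
  baseParams <- model$params
  m <- model
  if (method == 1L) {
    for (f in flowsMeasured) m <- augmentFlowState(m, f)
    outputs <- lapply(combo, as.name)
  } else {
    outputs <- lapply(combo, function(tok) {
      if (tok %in% av$concentrations) as.name(tok) else m$flows[[tok]]
    })
  }

  # augmented state vector: original states, then the original parameter order
  # with eliminated rate constants replaced in-slot by their flow-states
  xt <- c(model$states, baseParams)
  if (method == 1L) {
    elim <- m$meta$augmented
    for (f in names(elim)) xt[xt == elim[[f]]] <- f
  }
  structure(
    list(model = m, outputs = outputs, combo = combo, method = method,
         xt = xt, N = length(xt), m = length(outputs)),
    class = "outputModel"
  )
}

#' @export
print.outputModel <- function(x, ...) {
  cat("<output model: ", x$model$meta$label, ">\n", sep = "")
  cat("  measurements:", comboKey(x$combo), " (method ", x$method, ")\n", sep = "")
  for (i in seq_along(x$outputs))
    cat("  y", i, " = ", exprText(x$outputs[[i]]), "\n", sep = "")
  cat("  x~ = (", paste(x$xt, collapse = ", "), "), N = ", x$N, "\n", sep = "")
  invisible(x)
}
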