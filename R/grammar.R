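# Plain-text model grammar and JSON serialization.
#
# Format (one item per line, `#` comments allowed):
#   params: ki, ko, kc, ks, kd, KiE
#   flows:
#     di = ki
#     jc = kc*KiE/(KiE + E)
#   relations:
#     jc = A
#   dA/dt = di - do + jc
#   dE/dt = js - jd
# Dynamics may reference flow names; `*` must be explicit and `^` is the
# power operator. Only rational expressions are accepted.

parseExprText <- function(s, where) {
  e <- tryCatch(str2lang(s), error = function(err)
    stop("cannot parse ", where, ": ", s, call. = FALSE))
  checkRationalExpr(e, where)
  e
}

#' Read a model from the plain-text grammar
#'
#' @param path File path, or a character vector of lines via `text`.
#' @param text Optional character vector of lines (overrides `path`).
#' @return A `ctrlModel` with metadata family `"user"`.
#' @export
readModelText <- function(path = NULL, text = NULL) {
  lines <- if (!is.null(text)) text else readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]

  section <- "top"
  paramsDecl <- NULL
  flows <- list()
  relations <- list()
  dynamics <- list()
  states <- character(0)

  for (ln in lines) {
    if (grepl("^params\\s*:", ln)) {
      paramsDecl <- trimws(strsplit(sub("^params\\s*:", "", ln), ",")[[1]])
      paramsDecl <- paramsDecl[nzchar(paramsDecl)]
      section <- "top"
    } else if (grepl("^flows\\s*:\\s*$", ln)) {
      section <- "flows"
    } else if (grepl("^relations\\s*:\\s*$", ln)) {
      section <- "relations"
    } else if (grepl("^d[[:alnum:]_]+/dt\\s*=", ln)) {
      nm <- sub("^d([[:alnum:]_]+)/dt.*$", "\\1", ln)
      rhs <- trimws(sub("^[^=]*=", "", ln))
      dynamics[[nm]] <- parseExprText(rhs, paste0("d", nm, "/dt"))
      states <- c(states, nm)
      section <- "top"
    } else if (grepl("=", ln) && section %in% c("flows", "relations")) {
      nm <- trimws(sub("=.*$", "", ln))
      rhs <- trimws(sub("^[^=]*=", "", ln))
      if (section == "flows") flows[[nm]] <- parseExprText(rhs, paste0("flow ", nm))
      else relations[[nm]] <- trimws(strsplit(rhs, ",")[[1]])
    } else {
      stop("unrecognized line in model text: ", ln, call. = FALSE)
    }
  }
  if (length(dynamics) == 0L) stop("model text declares no state equations",
                                   call. = FALSE)
  # expand flow names inside dynamics
  if (length(flows))
    dynamics <- lapply(dynamics, substituteExpr, subs = flows)

  rel <- list()
  for (s in states) rel[[s]] <- s
  for (f in names(flows)) {
    rel[[f]] <- if (!is.null(relations[[f]]))
      relations[[f]] else intersect(states, exprSymbols(flows[[f]]))
  }
  for (nm in names(relations)) rel[[nm]] <- relations[[nm]]

  model <- newModel(states, dynamics, flows, rel,
                    meta = list(family = "user", index = NA_integer_,
                                case = NA_character_, label = "user model"))
  if (!is.null(paramsDecl)) {
    missing <- setdiff(paramsDecl, model$params)
    if (length(missing))
      stop("declared parameter(s) not present in the model: ",
           paste(missing, collapse = ", "), call. = FALSE)
    model$params <- c(paramsDecl, setdiff(model$params, paramsDecl))
  }
  model
}

#' Serialize a model to the plain-text grammar
#'
#' Dynamics are written in terms of flow names where a flow expression occurs
#' verbatim in a state equation; [readModelText()] inverts this.
#'
#' @param model A `ctrlModel`.
#' @param path Optional file path; if `NULL` the lines are returned.
#' @export
writeModelText <- function(model, path = NULL) {
  out <- c(paste0("# ", model$meta$label),
           paste0("params: ", paste(model$params, collapse = ", ")))
  if (length(model$flows)) {
    out <- c(out, "flows:")
    for (f in names(model$flows))
      out <- c(out, paste0("  ", f, " = ", exprText(model$flows[[f]])))
    out <- c(out, "relations:")
    for (f in names(model$relations))
      out <- c(out, paste0("  ", f, " = ",
                           paste(model$relations[[f]], collapse = ", ")))
  }
  for (s in model$states) {
    e <- model$dynamics[[s]]
    for (f in names(model$flows))
      if (!is.name(model$flows[[f]]))
        e <- replaceSubexpr(e, model$flows[[f]], as.name(f))
    out <- c(out, paste0("d", s, "/dt = ", exprText(e)))
  }
  if (is.null(path)) return(out)
  writeLines(out, path)
  invisible(path)
}

#' JSON serialization of models
#'
#' @param model A `ctrlModel`.
#' @return A JSON string with expression strings for dynamics and flows.
#' @export
modelToJSON <- function(model) {
  jsonlite::toJSON(list(
    states = model$states,
    params = model$params,
    dynamics = lapply(model$dynamics, exprText),
    flows = lapply(model$flows, exprText),
    relations = model$relations,
    meta = model$meta[!vapply(model$meta, is.null, logical(1))]
  ), auto_unbox = TRUE, pretty = TRUE)
}

#' @rdname modelToJSON
#' @param json JSON string produced by [modelToJSON()].
#' @export
modelFromJSON <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  dynamics <- lapply(x$dynamics, parseExprText, where = "dynamics")
  flows <- lapply(x$flows, parseExprText, where = "flow")
  meta <- as.list(x$meta)
  model <- newModel(as.character(x$states), dynamics, flows,
                    lapply(x$relations, as.character), meta)
  if (!is.null(x$params)) model$params <- as.character(x$params)
  model
}
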