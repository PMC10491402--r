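# Sweep driver: enumerate (motif, case, measurement-combination) instances,
# assess each, classify combination patterns and aggregate identifiability
# scores.

# Species-relation signature of a combo, transferable across motifs:
# e.g. "conc[A]+flow[E]" or "flow[A]+flow[E1+E2]".
comboPattern <- function(model, combo) {
  av <- availableMeasurements(model)
  sig <- vapply(combo, function(tok) {
    kind <- if (tok %in% av$concentrations) "conc" else "flow"
    paste0(kind, "[", paste(speciesRelation(tok, model), collapse = "+"), "]")
  }, character(1))
  paste(sort(sig), collapse = "+")
}

# One A-related member paired with one controller-species-related member.
isCrossSpecies <- function(model, combo) {
  if (length(combo) != 2L) return(FALSE)
  rels <- lapply(combo, speciesRelation, model = model)
  aRel <- vapply(rels, function(r) identical(r, "A"), logical(1))
  sum(aRel) == 1L
}

# Membership in the display block from which the per-case and per-motif
# scores are aggregated. Basic family: the case-and-motif-dependent
# combinations, i.e. cross-species pairs without the (always sufficient)
# concentration pair {A, E}. Antithetic family: all pairs whose two members
# have different species-relation sets (everything except the always
# insufficient single measurements and strictly same-species pairs).
isDependentBlock <- function(model, combo) {
  if (length(combo) != 2L) return(FALSE)
  if (model$meta$family == "antithetic") {
    rels <- lapply(combo, speciesRelation, model = model)
    return(!identical(sort(rels[[1L]]), sort(rels[[2L]])))
  }
  if (!isCrossSpecies(model, combo)) return(FALSE)
  av <- availableMeasurements(model)
  length(intersect(combo, av$concentrations)) < 2L
}

instanceSeed <- function(baseSeed, idx) {
  (as.numeric(baseSeed) * 1000003 + as.numeric(idx) * 7919) %% 2147483629
}

# Full canonical instance grid; the global index is stable across filters so a
# single instance can be recomputed in isolation with the same derived seed.
instanceGrid <- function() {
  rows <- list()
  idx <- 0L
  for (fam in c("basic", "antithetic")) {
    cases <- listCases(fam)$case
    for (motif in 1:8) for (cs in cases) {
      model <- buildModel(fam, motif, cs)
      combos <- enumerateCombos(model)
      for (cb in combos) {
        idx <- idx + 1L
        rows[[idx]] <- data.frame(
          globalIdx = idx, family = fam, motif = motif, case = cs,
          measurements = comboKey(cb),
          size = length(cb),
          pattern = comboPattern(model, cb),
          cross = isCrossSpecies(model, cb),
          dependent = isDependentBlock(model, cb),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, rows)
}

gridCache <- new.env(parent = emptyenv())

cachedGrid <- function() {
  if (is.null(gridCache$grid)) gridCache$grid <- instanceGrid()
  gridCache$grid
}

#' Run an identifiability sweep
#'
#' Assesses every (motif, case, measurement-combination) instance in the
#' requested scope and returns one record per instance. Deterministic given
#' `seed`: each instance derives its own seed from its position in the full
#' canonical grid, so any row can be recomputed in isolation.
#'
#' @param family Families to sweep (`"basic"`, `"antithetic"` or both).
#' @param motifs Motif indices (subset of 1:8).
#' @param cases Case identifiers; default all cases of the family.
#' @param combos `"all"`, `"cross"` (cross-species pairs only) or
#'   `"dependent"` (the case-and-motif-dependent display block), or a
#'   character vector of exact combo strings such as `"E,do"`.
#' @param method Flow-measurement method, 1 or 2.
#' @param mode Rank mode passed to [assess()].
#' @param seed Master seed.
#' @param compute If `FALSE`, return the instance grid without running any
#'   rank computation (counting / planning).
#' @param out Optional CSV path; records are streamed there and, with
#'   `resume = TRUE`, existing completed rows are reused on rerun.
#' @param resume Reuse rows already present in `out`.
#' @param progress Print a progress line every `progress` instances (0 = off).
#' @param ... Passed to [assess()] (`draws`, `points`, `tol`, ...).
#' @return Data frame of sweep records with columns family, motif, case,
#'   method, mode, measurements, n, q, N, rank, identifiable, k_used,
#'   stop_condition, seed, pattern, cross, dependent.
#' @export
runSweep <- function(family = c("basic", "antithetic"), motifs = 1:8,
                     cases = NULL, combos = "all", method = 2L,
                     mode = c("auto", "symbolic", "numeric"), seed = 1L,
                     compute = TRUE, out = NULL, resume = TRUE,
                     progress = 0L, ...) {
  family <- match.arg(family, several.ok = TRUE)
  mode <- match.arg(mode)
  grid <- cachedGrid()
  keep <- grid$family %in% family & grid$motif %in% motifs
  if (!is.null(cases)) keep <- keep & grid$case %in% cases
  if (length(combos) == 1L && combos %in% c("all", "cross", "dependent")) {
    if (combos == "cross") keep <- keep & grid$cross
    if (combos == "dependent") keep <- keep & grid$dependent
  } else {
    keep <- keep & grid$measurements %in% combos
  }
  grid <- grid[keep, , drop = FALSE]
  if (!compute) return(grid)

  done <- NULL
  if (!is.null(out) && resume && file.exists(out)) {
    done <- readSweepCSV(out)
    done <- done[done$method == method, , drop = FALSE]
  }
  key <- function(df) paste(df$family, df$motif, df$case, df$measurements, sep = "|")

  records <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    if (!is.null(done)) {
      hit <- which(key(done) == key(g))
      if (length(hit)) { records[[i]] <- done[hit[1L], ]; next }
    }
    model <- buildModel(g$family, g$motif, g$case)
    iseed <- instanceSeed(seed, g$globalIdx)
    rec <- tryCatch({
      om <- buildOutputModel(model, strsplit(g$measurements, ",")[[1L]], method)
      res <- assess(om, mode = mode, seed = iseed, ...)
      data.frame(
        family = g$family, motif = g$motif, case = g$case,
        method = method, mode = res$mode, measurements = g$measurements,
        n = length(model$states), q = length(model$params),
        N = res$N, rank = res$rank, identifiable = res$identifiable,
        k_used = res$k_used, stop_condition = res$stop_condition,
        seed = iseed, pattern = g$pattern, cross = g$cross,
        dependent = g$dependent, stringsAsFactors = FALSE
      )
    }, error = function(e) {
      warning("instance ", key(g), " failed: ", conditionMessage(e),
              call. = FALSE)
      data.frame(
        family = g$family, motif = g$motif, case = g$case,
        method = method, mode = mode, measurements = g$measurements,
        n = length(model$states), q = length(model$params),
        N = NA_integer_, rank = NA_integer_, identifiable = NA,
        k_used = NA_integer_, stop_condition = "error",
        seed = iseed, pattern = g$pattern, cross = g$cross,
        dependent = g$dependent, stringsAsFactors = FALSE
      )
    })
    records[[i]] <- rec
    if (progress > 0L && i %% progress == 0L)
      message(sprintf("sweep: %d/%d instances", i, nrow(grid)))
  }
  res <- do.call(rbind, records)
  rownames(res) <- NULL
  if (!is.null(out)) writeSweepCSV(res, out, seed = seed, method = method,
                                   mode = mode)
  res
}

#' Write / read sweep records as CSV
#'
#' The file carries the effective configuration in `#`-prefixed header lines,
#' sufficient to reproduce any row in isolation.
#'
#' @param records Sweep record data frame.
#' @param path CSV path.
#' @param seed,method,mode Configuration recorded in the header.
#' @export
writeSweepCSV <- function(records, path, seed = NA, method = NA, mode = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# motifid sweep records (%d instances)", nrow(records)),
    sprintf("# seed=%s method=%s mode=%s", seed, method, mode)
  ), con)
  utils::write.csv(records, con, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSweepCSV
#' @export
readSweepCSV <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Identifiability score of a set of instances
#'
#' Fraction of instances that are structurally identifiable.
#'
#' @param records Sweep records.
#' @return The raw fraction, with attributes `n`, `identifiable` and
#'   `rounded` (two decimals, the convention of the summary tables).
#' @export
identifiabilityScore <- function(records) {
  if (is.null(records) || nrow(records) == 0L)
    stop("identifiability score is undefined for an empty record set",
         call. = FALSE)
  ok <- !is.na(records$identifiable)
  if (!all(ok)) warning(sum(!ok), " failed instance(s) excluded from the score")
  records <- records[ok, , drop = FALSE]
  s <- mean(records$identifiable)
  structure(s, n = nrow(records), identifiable = sum(records$identifiable),
            rounded = round(s, 2))
}

#' Cross-species measurement subset
#'
#' Keeps the two-measurement instances that pair one measurement related to
#' the controlled species A with one related to a controller species; this is
#' the necessary condition for structural identifiability of the motifs.
#'
#' @param records Sweep records.
#' @export
crossSpeciesSubset <- function(records) {
  records[records$cross, , drop = FALSE]
}

#' Classify combination patterns
#'
#' Groups records by species-relation pattern and classifies each pattern over
#' the evaluated scope as always sufficient (every instance full rank), always
#' insufficient (no instance full rank) or case and motif dependent.
#'
#' @param records Sweep records covering the scope of interest.
#' @return Data frame: pattern, n, identifiable, class.
#' @export
classifyCombos <- function(records) {
  records <- records[!is.na(records$identifiable), , drop = FALSE]
  pats <- split(records, records$pattern)
  out <- do.call(rbind, lapply(pats, function(df) {
    k <- sum(df$identifiable)
    data.frame(pattern = df$pattern[1L], n = nrow(df), identifiable = k,
               class = if (k == nrow(df)) "always_sufficient"
                       else if (k == 0L) "always_insufficient"
                       else "case_and_motif_dependent",
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$pattern), , drop = FALSE]
}

#' Aggregate identifiability scores
#'
#' Computes the standard summary tables from sweep records: per-case scores
#' (dependent-block combinations only), per-motif scores split by disturbance
#' count, controller type and degradation kinetics, and per-family comparison
#' scores over all cross-species combinations.
#'
#' @param records Sweep records.
#' @return List with data frames `caseScores`, `motifScores`,
#'   `controllerTypeScores`, `familyComparison`. Every score carries its
#'   denominator (`n`).
#' @export
aggregateTables <- function(records) {
  records <- records[!is.na(records$identifiable), , drop = FALSE]
  dep <- records[records$dependent, , drop = FALSE]
  scoreDf <- function(df, keys) {
    sp <- split(df, df[keys], drop = TRUE)
    out <- do.call(rbind, lapply(sp, function(d) {
      cbind(d[1L, keys, drop = FALSE],
            data.frame(n = nrow(d), identifiable = sum(d$identifiable),
                       score = round(mean(d$identifiable), 2)))
    }))
    rownames(out) <- NULL
    out
  }
  caseScores <- if (nrow(dep)) scoreDf(dep, c("family", "case")) else NULL
  motifScores <- if (nrow(dep)) {
    dep$distGroup <- ifelse(dep$case %in% c(paste0("B", 1:6), "A1", "A2"),
                            "one", "both")
    scoreDf(dep, c("family", "motif", "distGroup"))
  } else NULL
  ctrl <- if (nrow(dep)) {
    dep$controllerType <- ifelse(dep$motif <= 4, "inflow", "outflow")
    dep$distGroup <- ifelse(dep$case %in% c(paste0("B", 1:6), "A1", "A2"),
                            "one", "both")
    scoreDf(dep, c("family", "controllerType", "distGroup"))
  } else NULL
  cross <- records[records$cross, , drop = FALSE]
  familyComparison <- if (nrow(cross)) scoreDf(cross, "family") else NULL
  list(caseScores = caseScores, motifScores = motifScores,
       controllerTypeScores = ctrl, familyComparison = familyComparison)
}
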