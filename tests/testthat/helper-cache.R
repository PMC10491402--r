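# Shared fixtures: expensive sweeps are computed once per test run and reused
# across test files.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- expr
  .cache[[key]]
}

# Full-library sweep (3648 instances, exact rank mode); ~2 minutes.
fullSweep <- function() cached("full", runSweep(mode = "symbolic", seed = 1))

basicSweep <- function() {
  rec <- fullSweep()
  rec[rec$family == "basic", , drop = FALSE]
}

# A strictly positive random point over all library symbols.
randomLibraryPoint <- function() {
  vars <- c("A", "E", "E1", "E2", motifid:::PARAM_ORDER)
  stats::setNames(stats::runif(length(vars), 0.2, 3), vars)
}

# Independent route: evaluate the symbolically differentiated OI matrix at a
# numeric point (no series engine involved).
symbolicOIAt <- function(om, k, point) {
  M <- oiMatrix(om, k)
  vals <- vapply(M$entries, function(e) {
    if (is.numeric(e)) as.numeric(e) else eval(e, as.list(point))
  }, numeric(1))
  matrix(vals, M$nrow, M$ncol)
}

# Engine route: OI rows at the same point via Taylor/sensitivity propagation.
engineOIAt <- function(om, k, point) {
  eng <- motifid:::makeEngine(om)
  P <- matrix(point[om$xt], 1L, om$N, dimnames = list(NULL, om$xt))
  rows <- NULL
  motifid:::runEngine(eng, P, NULL, k, function(kk, block) {
    rows <<- rbind(rows, matrix(block[1L, , ], ncol = om$N))
    TRUE
  })
  rows
}
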