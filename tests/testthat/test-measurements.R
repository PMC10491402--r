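test_that("species relations group measurements by balance equation", {
  m <- buildModel("basic", 3, "B8")
  expect_identical(speciesRelation("jc", m), "A")
  expect_identical(speciesRelation("di", m), "A")
  expect_identical(speciesRelation("js", m), "E")
  expect_identical(speciesRelation("E", m), "E")
  a <- buildModel("antithetic", 1, "A3")
  expect_identical(speciesRelation("ja", a), c("E1", "E2"))
  expect_identical(speciesRelation("js2", a), "E2")
  # di is absent from a one-disturbance inflow model
  m1 <- buildModel("basic", 2, "B1")
  expect_error(speciesRelation("di", m1), "not available")
})

test_that("combination counts are 21/28 for basic and 36/45 for antithetic models", {
  expect_length(enumerateCombos(buildModel("basic", 2, "B1")), 21L)
  expect_length(enumerateCombos(buildModel("basic", 2, "B7")), 28L)
  expect_length(enumerateCombos(buildModel("antithetic", 5, "A1")), 36L)
  expect_length(enumerateCombos(buildModel("antithetic", 5, "A3")), 45L)
})

test_that("combinations follow the result-grid section layout", {
  combos <- enumerateCombos(buildModel("basic", 3, "B8"))
  keys <- vapply(combos, paste, character(1), collapse = ",")
  # concentrations, single flows, concentration+flow, flow pairs
  expect_identical(keys[1:3], c("A", "E", "A,E"))
  expect_identical(keys[4:8], c("di", "do", "jc", "js", "jd"))
  # lines 12-16: the cross-species concentration+flow block
  expect_identical(keys[12:16], c("E,di", "E,do", "E,jc", "A,js", "A,jd"))
  expect_identical(keys[17:18], c("E,js", "E,jd"))
  expect_identical(keys[28], "js,jd")
})

test_that("flow-state augmentation reproduces the motif 2 worked example", {
  m <- buildModel("basic", 2, "B7")
  aug <- augmentFlowState(m, "jc")
  expect_true("jc" %in% aug$states)
  expect_false("kc" %in% aug$params)
  # dJc/dt = jc * (kd - ks*A) / (KiE + E)
  expect_true(motifid:::exprEquivalent(
    aug$dynamics$jc, quote(jc * (kd - ks * A) / (KiE + E)), seed = 5))
  # the flow symbol replaces the expression in dA/dt
  expect_true(motifid:::exprEquivalent(
    aug$dynamics$A, quote(ki - ko * A + jc), seed = 5))
})

test_that("augmenting a constant disturbance gives zero dynamics and replaces its constant", {
  m <- buildModel("basic", 3, "B8")
  aug <- augmentFlowState(m, "di")
  expect_identical(aug$dynamics$di, 0)
  expect_false("ki" %in% aug$params)
  expect_true(motifid:::exprEquivalent(
    aug$dynamics$A, quote(di - ko * A + kc * E), seed = 5))
})

test_that("augmenting a first-order degradation matches the symbolic total derivative", {
  m <- buildModel("basic", 2, "B8")   # jd = kd * E
  aug <- augmentFlowState(m, "jd")
  # after substituting kd = jd/E: dJd/dt = jd * (js - jd) / E
  js <- m$flows$js
  expect_true(motifid:::exprEquivalent(
    aug$dynamics$jd, call("/", call("*", quote(jd), call("(", call("-", js, quote(jd)))), quote(E)),
    seed = 5))
})

test_that("augmentation errors on unsupported or absent flows", {
  m <- buildModel("basic", 2, "B1")
  expect_error(augmentFlowState(m, "di"), "invalid selection")
  toy <- toyModels()$decay
  toy$flows$bad <- quote(x + 1)     # no multiplicative rate constant
  expect_error(augmentFlowState(toy, "bad"), "unsupported flow")
})

test_that("augmented systems preserve the measured flow trajectory (ODE oracle)", {
  set.seed(42)
  checkFlow <- function(model, flow) {
    aug <- augmentFlowState(model, flow)
    p0 <- as.list(stats::setNames(stats::runif(length(model$params), 0.5, 1.5),
                                  model$params))
    x0 <- stats::setNames(stats::runif(length(model$states), 0.5, 1.5),
                          model$states)
    rhs <- function(model) function(t, y, parms)
      list(vapply(model$states, function(s)
        eval(model$dynamics[[s]], c(as.list(y), p0)), numeric(1)))
    J0 <- eval(model$flows[[flow]], c(as.list(x0), p0))
    tt <- seq(0, 2, by = 0.1)
    o1 <- deSolve::ode(x0, tt, rhs(model), NULL)
    o2 <- deSolve::ode(c(x0, stats::setNames(J0, flow)), tt, rhs(aug), NULL)
    jtraj <- apply(o1, 1, function(row)
      eval(model$flows[[flow]], c(as.list(row[-1]), p0)))
    max(abs(jtraj - o2[, flow]))
  }
  expect_lt(checkFlow(buildModel("basic", 2, "B7"), "jc"), 1e-4)
  expect_lt(checkFlow(buildModel("antithetic", 1, "A3"), "ja"), 1e-4)
  expect_lt(checkFlow(buildModel("basic", 5, "B7"), "do"), 1e-4)
})

test_that("output models have equal N under both flow methods", {
  m2 <- buildModel("basic", 2, "B7")
  om2 <- buildOutputModel(m2, "jc", 2)
  om1 <- buildOutputModel(m2, "jc", 1)
  expect_identical(om1$N, om2$N)
  expect_identical(om2$xt, c("A", "E", "ki", "ko", "kc", "ks", "kd", "KiE"))
  expect_identical(om1$xt, c("A", "E", "ki", "ko", "jc", "ks", "kd", "KiE"))
  expect_true(motifid:::exprEquivalent(om2$outputs[[1]],
                                       quote(kc * KiE / (KiE + E)), seed = 5))
  expect_identical(om1$outputs[[1]], as.name("jc"))
  # N equality across a spread of instances, including two-flow combos
  for (sel in list(list("basic", 3, "B8", c("jc", "js")),
                   list("basic", 5, "B12", c("di", "jd")),
                   list("antithetic", 4, "A4", c("jc", "ja")),
                   list("antithetic", 7, "A2", c("di", "js2")))) {
    model <- buildModel(sel[[1]], sel[[2]], sel[[3]])
    expect_identical(buildOutputModel(model, sel[[4]], 1)$N,
                     buildOutputModel(model, sel[[4]], 2)$N)
  }
})

test_that("concentration-only combinations are identical under both methods", {
  m <- buildModel("antithetic", 2, "A1")
  om1 <- buildOutputModel(m, c("A", "E1"), 1)
  om2 <- buildOutputModel(m, c("A", "E1"), 2)
  expect_identical(om1$outputs, om2$outputs)
  expect_identical(om1$model$dynamics, om2$model$dynamics)
  expect_identical(om1$xt, om2$xt)
})

test_that("malformed combinations are rejected", {
  m <- buildModel("basic", 1, "B1")
  expect_error(buildOutputModel(m, c("A", "E", "jc")), "1 or 2")
  expect_error(buildOutputModel(m, c("A", "A")), "distinct")
  expect_error(buildOutputModel(m, "di"), "not available")
  expect_error(buildOutputModel(m, "A", method = 3), "method")
})
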