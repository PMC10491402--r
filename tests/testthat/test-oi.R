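test_that("Lie stacks match hand-computed derivatives on the decay model", {
  om <- buildOutputModel(toyModels()$decay, "x", 2)
  ls <- lieStack(om, 2)
  eq <- motifid:::exprEquivalent
  expect_identical(ls$orders[[1]][[1]], as.name("x"))          # order 0 is g
  expect_true(eq(ls$orders[[2]][[1]], quote(-(k * x)), seed = 1))
  expect_true(eq(ls$orders[[3]][[1]], quote(k^2 * x), seed = 1))
})

test_that("the first Lie derivative of a concentration output is its state equation", {
  m <- buildModel("basic", 3, "B8")
  om <- buildOutputModel(m, "A", 2)
  ls <- lieStack(om, 1)
  expect_true(motifid:::exprEquivalent(ls$orders[[2]][[1]], m$dynamics$A, seed = 2))
})

test_that("the OI matrix of the decay model matches the hand computation", {
  om <- buildOutputModel(toyModels()$decay, "x", 2)
  M <- oiMatrix(om, 2)
  pt <- c(x = 0.7, k = 1.3)
  vals <- matrix(vapply(M$entries, function(e)
    if (is.numeric(e)) as.numeric(e) else eval(e, as.list(pt)), numeric(1)), 3, 2)
  expected <- rbind(c(1, 0),
                    c(-pt["k"], -pt["x"]),
                    c(pt["k"]^2, 2 * pt["k"] * pt["x"]))
  expect_equal(vals, expected, ignore_attr = TRUE, tolerance = 1e-12)
  expect_identical(genericRank(M, "symbolic", seed = 1), structure(2L, perDraw = c(2L, 2L, 2L)),
                   ignore_attr = TRUE)
})

test_that("OI matrix dimensions are m*(k+1) rows by N columns", {
  om <- buildOutputModel(buildModel("basic", 2, "B7"), c("A", "E"), 2)
  M <- oiMatrix(om, 1)
  expect_identical(c(M$nrow, M$ncol), c(4L, 8L))
  expect_identical(oiMatrix(om, 3)$nrow, 8L)
})

test_that("series engine rows equal the symbolically differentiated OI matrix", {
  set.seed(31)
  cases <- list(
    buildOutputModel(toyModels()$chain, "x2", 2),
    buildOutputModel(buildModel("basic", 3, "B8"), "jc", 2),
    buildOutputModel(buildModel("basic", 2, "B7"), c("A", "E"), 2),
    buildOutputModel(buildModel("basic", 2, "B7"), "jc", 1),
    buildOutputModel(buildModel("antithetic", 1, "A1"), c("A", "ja"), 2)
  )
  for (om in cases) {
    k <- min(4L, om$N - 1L)
    pt <- stats::setNames(stats::runif(om$N, 0.5, 1.5), om$xt)
    expect_equal(engineOIAt(om, k, pt), symbolicOIAt(om, k, pt),
                 tolerance = 1e-8)
  }
})

test_that("the scaled-output toy model has a rank deficiency of one", {
  om <- buildOutputModel(toyModels()$decay_scaled, "yobs", 2)
  res <- assess(om, mode = "symbolic", seed = 1)
  expect_identical(res$rank, 2L)
  expect_identical(res$N, 3L)
  expect_false(res$identifiable)
  resn <- assess(om, mode = "numeric", seed = 1)
  expect_identical(resn$rank, 2L)
})

test_that("assess reproduces the motif 3 case B8 rank table", {
  m <- buildModel("basic", 3, "B8")
  expected <- list(
    list("di", 1L), list("jc", 6L), list("E", 6L), list("A", 7L),
    list(c("E", "di"), 7L), list(c("A", "E"), 8L), list(c("js", "jd"), 6L),
    list(c("E", "jc"), 7L), list(c("di", "jd"), 7L)
  )
  for (ex in expected) {
    res <- assess(buildOutputModel(m, ex[[1]], 2), mode = "symbolic", seed = 3)
    expect_identical(res$rank, ex[[2]],
                     info = paste(ex[[1]], collapse = ","))
    expect_identical(res$identifiable, res$rank == res$N)
  }
})

test_that("stopping conditions are reported correctly", {
  m <- buildModel("basic", 3, "B8")
  full <- assess(buildOutputModel(m, c("A", "E"), 2), mode = "symbolic", seed = 1)
  expect_identical(full$stop_condition, "full_rank")
  plat <- assess(buildOutputModel(m, "di", 2), mode = "symbolic", seed = 1)
  expect_identical(plat$stop_condition, "rank_plateau")
  expect_identical(plat$k_used, 1L)
  capped <- assess(buildOutputModel(m, "jc", 2), mode = "symbolic", seed = 1,
                   maxOrder = 2L)
  expect_identical(capped$stop_condition, "max_order")
  expect_lte(full$k_used, full$N - 1L)
})

test_that("ranks are monotone in derivative order and in measurement inclusion", {
  set.seed(17)
  mods <- enumerateModels()
  for (rep in 1:12) {
    m <- mods[[sample.int(128, 1)]]
    combos <- enumerateCombos(m)
    cb <- combos[[sample.int(length(combos), 1)]]
    res <- assess(buildOutputModel(m, cb, 2), mode = "symbolic", seed = rep)
    expect_true(all(diff(res$ranksByOrder) >= 0))
    expect_lte(res$rank, res$N)
    if (length(cb) == 1L) {
      av <- availableMeasurements(m)
      other <- setdiff(c(av$concentrations, av$flows), cb)
      sup <- c(cb, sample(other, 1))
      res2 <- assess(buildOutputModel(m, sup, 2), mode = "symbolic", seed = rep)
      expect_gte(res2$rank, res$rank)
    }
  }
})

test_that("a rank plateau really is final: one extra order never raises the rank", {
  set.seed(23)
  mods <- enumerateModels("basic")
  tested <- 0L
  while (tested < 8L) {
    m <- mods[[sample.int(96, 1)]]
    combos <- enumerateCombos(m)
    cb <- combos[[sample.int(length(combos), 1)]]
    om <- buildOutputModel(m, cb, 2)
    res <- assess(om, mode = "symbolic", seed = tested + 1L)
    if (res$stop_condition != "rank_plateau" || res$k_used + 1L > om$N - 1L) next
    forced <- assess(om, mode = "symbolic", seed = tested + 1L,
                     maxOrder = res$k_used + 1L, minOrder = res$k_used + 1L)
    expect_gte(forced$k_used, res$k_used + 1L)
    expect_identical(forced$rank, res$rank)
    tested <- tested + 1L
  }
})

test_that("numeric and exact ranks agree across modest-size instances", {
  set.seed(5)
  mods <- enumerateModels()
  small <- Filter(function(m) modelSize(m) <= 8, mods)
  for (rep in 1:15) {
    m <- small[[sample.int(length(small), 1)]]
    combos <- enumerateCombos(m)
    cb <- combos[[sample.int(length(combos), 1)]]
    om <- buildOutputModel(m, cb, 2)
    rs <- assess(om, mode = "symbolic", seed = rep)
    rn <- assess(om, mode = "numeric", seed = rep)
    expect_identical(rs$rank, rn$rank,
                     info = paste(m$meta$label, paste(cb, collapse = ",")))
  }
})

test_that("per-element diagnosis reproduces the published motif 3 case B8 partitions", {
  m <- buildModel("basic", 3, "B8")
  d1 <- elementIdentifiability(buildOutputModel(m, "jc", 2), mode = "symbolic", seed = 2)
  expect_setequal(attr(d1, "identifiableParams"), c("ko", "kd"))
  expect_setequal(attr(d1, "unidentifiableParams"), c("ki", "kc", "ks", "KiA"))
  expect_setequal(attr(d1, "unobservableStates"), c("A", "E"))

  d2 <- elementIdentifiability(buildOutputModel(m, c("E", "di"), 2), mode = "symbolic", seed = 2)
  expect_setequal(attr(d2, "identifiableParams"), c("ki", "ko", "kd"))
  expect_setequal(attr(d2, "observableStates"), "E")
  expect_setequal(attr(d2, "unobservableStates"), "A")

  d3 <- elementIdentifiability(buildOutputModel(m, "di", 2), mode = "symbolic", seed = 2)
  expect_setequal(attr(d3, "identifiableParams"), "ki")

  # full-rank instances have every element identifiable/observable
  d4 <- elementIdentifiability(buildOutputModel(m, c("A", "E"), 2), mode = "symbolic", seed = 2)
  expect_true(all(d4$identifiable))
})

test_that("the translational symmetry generator is confirmed for B7 and broken for B8", {
  gen <- list(E = -1, ki = quote(kc))
  om7 <- buildOutputModel(buildModel("basic", 3, "B7"), c("A", "js"), 2)
  om8 <- buildOutputModel(buildModel("basic", 3, "B8"), c("A", "js"), 2)
  s7 <- checkSymmetry(om7, gen, mode = "symbolic", seed = 1)
  expect_true(isTRUE(s7))
  expect_false(isTRUE(checkSymmetry(om8, gen, mode = "symbolic", seed = 1)))
  # numeric route agrees
  expect_true(isTRUE(checkSymmetry(om7, gen, mode = "numeric", seed = 1)))
  # a valid generator implies rank deficiency
  expect_lt(attr(s7, "rank")$rank, om7$N)
  # dimension/naming errors
  expect_error(checkSymmetry(om7, list(zz = 1)), "dimension mismatch")
  expect_error(checkSymmetry(om7, list(E = 0)), "identically zero")
})
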