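branchModel <- function() {
  # 5 balanced metabolites, two branches re-converging, 2 dof
  stoichiometricModel(list(
    up = list(stoich = c(A = 1)),
    b1 = list(stoich = c(A = -1, B = 1)),
    b2 = list(stoich = c(A = -1, C = 1)),
    j1 = list(stoich = c(B = -1, D = 1)),
    j2 = list(stoich = c(C = -1, D = 1)),
    sink = list(stoich = c(D = -1, E = 1)),
    out = list(stoich = c(E = -1))))
}

test_that("a linear chain with measured uptake carries the flux through", {
  m <- stoichiometricModel(list(
    up = list(stoich = c(A = 1)),
    r1 = list(stoich = c(A = -1, B = 1)),
    r2 = list(stoich = c(B = -1, C = 1)),
    out = list(stoich = c(C = -1))))
  sol <- solveNetFluxes(m, fluxConstraints(
    data.frame(reaction = "up", value = 1, sd = 0.1)))
  expect_equal(unname(fluxes(sol)), rep(1, 4), tolerance = 1e-10)
})

test_that("a closed cycle with zero exchange returns the zero flux vector", {
  m <- stoichiometricModel(list(
    ex = list(stoich = c(A = 1), reversible = TRUE),
    f  = list(stoich = c(A = -1, B = 1), reversible = TRUE),
    g  = list(stoich = c(B = -1, A = 1), reversible = TRUE)))
  cons <- fluxConstraints(data.frame(reaction = "ex", value = 0, sd = 0.1))
  expect_error(solveNetFluxes(m, cons), "underdetermined")
  sol <- solveNetFluxes(m, cons, onRankDeficient = "minnorm")
  expect_equal(unname(fluxes(sol)), c(0, 0, 0))
})

test_that("branch model with a ratio constraint matches the null-space grid oracle", {
  m <- branchModel()
  measured <- data.frame(reaction = c("up", "out"), value = c(1, 0.97),
                         sd = c(0.05, 0.05))
  # branch split b1 = 0.3 of uptake, as a soft ratio equation
  cons <- fluxConstraints(measured, ratios = list(
    list(coef = c(b1 = 1, up = -0.3), sd = 0.02)))
  sol <- solveNetFluxes(m, cons)
  # oracle: grid search with the ratio held exactly; the solver's soft
  # optimum can only be at least as good on the common objective
  v0 <- oracleNullspaceGrid(m, measured, ranges = list(
    list(coef = c(b1 = 1, up = -0.3), lower = -1e-9, upper = 1e-9)))
  obj <- function(v) sum(((v[measured$reaction] - measured$value) /
                            measured$sd)^2) +
    ((v[["b1"]] - 0.3 * v[["up"]]) / 0.02)^2
  expect_lte(obj(fluxes(sol)), obj(v0) + 1e-6)
  expect_equal(fluxes(sol)[["b1"]] / fluxes(sol)[["up"]], 0.3,
               tolerance = 1e-3)
})

test_that("solutions with active bounds match the refined grid oracle within 1e-4", {
  m <- branchModel()
  # measurements that pull b2 negative; bound b2 >= 0 becomes active
  measured <- data.frame(reaction = c("up", "j1"), value = c(1, 1.3),
                         sd = c(0.1, 0.1))
  sol <- solveNetFluxes(m, fluxConstraints(measured))
  v0 <- oracleNullspaceGrid(m, measured)
  expect_equal(fluxes(sol), v0, tolerance = 1e-4)
  expect_gte(min(fluxes(sol)), -1e-9)
  # and with a two-sided range constraint on the split
  measured2 <- data.frame(reaction = c("up", "j1"), value = c(1, 0.9),
                          sd = c(0.1, 0.1))
  ranges <- list(list(coef = c(b2 = 1, up = -0.4), lower = 0, upper = Inf),
                 list(coef = c(b2 = 1, up = -0.5), lower = -Inf, upper = 0))
  sol2 <- solveNetFluxes(m, fluxConstraints(measured2, ranges = ranges))
  v02 <- oracleNullspaceGrid(m, measured2, ranges = list(
    list(coef = c(b2 = 1, up = -0.4), lower = 0, upper = Inf),
    list(coef = c(b2 = 1, up = -0.5), lower = -Inf, upper = 0)))
  expect_equal(fluxes(sol2), v02, tolerance = 1e-4)
  ratio <- fluxes(sol2)[["b2"]] / fluxes(sol2)[["up"]]
  expect_gte(ratio, 0.4 - 1e-9)
  expect_lte(ratio, 0.5 + 1e-9)
})

test_that("mass balance holds to 1e-8 and homogeneity under rate scaling", {
  m <- yeastCentralModel()
  S <- stoichiometryMatrix(m)
  v <- cascadeGlucoseFluxes(tca = 0.8)
  sol <- solveNetFluxes(m, cascadeConstraints(v))
  expect_lt(max(abs(S %*% fluxes(sol))), 1e-8)
  # scaling all measured rates by c scales v by c ...
  c3 <- cascadeConstraints(v)
  c3$measured$value <- 3 * c3$measured$value
  c3$measured$sd <- 3 * c3$measured$sd
  sol3 <- solveNetFluxes(m, c3)
  expect_equal(fluxes(sol3), 3 * fluxes(sol), tolerance = 1e-6)
  # ... and leaves normalized fluxes and the degree of respiration unchanged
  n1 <- normalizeFluxes(sol, "uptake", scale = 100)
  n3 <- normalizeFluxes(sol3, "uptake", scale = 100)
  expect_equal(normalizedFluxes(n1), normalizedFluxes(n3), tolerance = 1e-6)
  expect_equal(degreeOfRespiration(n1), degreeOfRespiration(n3),
               tolerance = 1e-6)
})

test_that("rates generated from a feasible truth are recovered (round trip)", {
  m <- yeastCentralModel()
  set.seed(9)
  for (rep in 1:5) {
    v <- cascadeGlucoseFluxes(uptake = runif(1, 5, 20), mu = runif(1, 0.1, 0.4),
                              ppp = runif(1, 1, 3), glycerol = runif(1, 0.2, 1.5),
                              acetate = runif(1, 0.2, 1), tca = runif(1, 0, 1.2))
    expect_lt(max(abs(stoichiometryMatrix(m) %*% v)), 1e-9)  # truth feasible
    sol <- solveNetFluxes(m, cascadeConstraints(v))
    expect_equal(fluxes(sol)[names(v)], v, tolerance = 1e-6)
  }
})

test_that("degree of respiration reads the normalized mal_mit -> oaa_mit flux", {
  m <- yeastCentralModel()
  v <- cascadeGlucoseFluxes(uptake = 10, tca = 2)
  sol <- normalizeFluxes(solveNetFluxes(m, cascadeConstraints(v)), "uptake")
  expect_equal(degreeOfRespiration(sol), 0.2, tolerance = 1e-6)
  # fermentative truth: zero TCA flux -> degree 0.00
  v0 <- cascadeGlucoseFluxes(tca = 0)
  sol0 <- normalizeFluxes(solveNetFluxes(m, cascadeConstraints(v0)), "uptake")
  expect_equal(degreeOfRespiration(sol0), 0, tolerance = 1e-8)
  expect_error(degreeOfRespiration(sol, reaction = "nope"), "lacks")
  expect_error(degreeOfRespiration(solveNetFluxes(m, cascadeConstraints(v))),
               "normalize")
})

test_that("the solver reports infeasible constraint sets and zero uptake", {
  m <- branchModel()
  measured <- data.frame(reaction = c("up", "j1"), value = c(1, 0.5),
                         sd = c(0.1, 0.1))
  ranges <- list(list(coef = c(b1 = 1), lower = 0.8, upper = Inf),
                 list(coef = c(b2 = 1), lower = 0.8, upper = Inf),
                 list(coef = c(up = 1), lower = -Inf, upper = 1))
  expect_error(solveNetFluxes(m, fluxConstraints(measured, ranges = ranges)),
               "infeasible")
  sol <- solveNetFluxes(m, fluxConstraints(
    data.frame(reaction = "up", value = 0, sd = 0.1)),
    onRankDeficient = "minnorm")
  expect_error(normalizeFluxes(sol, "up"), "zero")
})
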