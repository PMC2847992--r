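test_that("network curation filter keeps literature edges inside the universe", {
  net <- toyNetwork()
  filt <- filterNetwork(net)
  e <- edges(filt)
  # hand counts from the bundled file: TF2's 'other' edge and TF4's
  # out-of-universe target are dropped, TF5's duplicate collapses
  m <- table(e$tf)
  expect_equal(as.integer(m[c("TF1", "TF2", "TF3", "TF4", "TF5")]),
               c(3L, 2L, 4L, 1L, 2L))
  expect_true(all(e$target %in% universe(net)))
  expect_false(any(duplicated(e[, c("tf", "target")])))
  # evidence filter: a network of only non-literature edges empties out
  net2 <- regulatoryNetwork("T", "E01", evidence = "other",
                            universe = "E01")
  expect_warning(filterNetwork(net2), "no edges")
  # out-of-universe-only targets also empty out
  net3 <- regulatoryNetwork("T", "X99", universe = "E01")
  expect_warning(filterNetwork(net3), "no edges")
})

test_that("f values match exhaustive subset enumeration on small universes", {
  worst <- 0
  for (N in 2:8) {
    for (n in 1:N) {
      for (m in 1:N) {
        for (k in 0:min(m, n)) {
          worst <- max(worst,
                       abs(fValue(k, m, n, N) - oracleFEnumeration(k, m, n, N)))
        }
      }
    }
  }
  expect_lt(worst, 1e-12)
  # hand-enumerated worked examples
  expect_equal(fValue(0, 3, 2, 5), 1)
  expect_equal(fValue(2, 2, 2, 5), 0.1)
  expect_equal(fValue(1, 2, 2, 5), 0.7)
  expect_error(fValue(3, 2, 2, 5), "min")
})

test_that("f is monotone in k, normalized, and per-TF independent", {
  set.seed(31)
  for (rep in 1:200) {
    N <- sample(5:60, 1)
    n <- sample(1:N, 1)
    m <- sample(1:N, 1)
    ks <- 0:min(m, n)
    f <- vapply(ks, fValue, numeric(1), m = m, n = n, N = N)
    expect_equal(f[1], 1)
    expect_true(all(diff(f) <= 1e-12))
    # pmf sums to one
    expect_equal(sum(dhyper(0:min(m, n), m, N - m, n)), 1, tolerance = 1e-12)
  }
  # adding an unrelated TF leaves existing f values untouched
  net <- filterNetwork(toyNetwork())
  r1 <- rankTFs(net, c("E01", "E02", "E03"))
  bigger <- regulatoryNetwork(
    c(edges(net)$tf, "TFnew", "TFnew"),
    c(edges(net)$target, "E06", "E07"),
    universe = universe(net))
  r2 <- rankTFs(filterNetwork(bigger), c("E01", "E02", "E03"))
  common <- intersect(r1$tf, r2$tf)
  expect_equal(r1$f[match(common, r1$tf)], r2$f[match(common, r2$tf)])
})

test_that("ranking prefers specific regulators and handles ties and degeneracy", {
  # exact-cover TF beats an everything-TF
  uni <- sprintf("E%02d", 1:10)
  diff <- c("E01", "E02", "E03")
  net <- regulatoryNetwork(
    tf = c(rep("exact", 3), rep("broad", 10)),
    target = c(diff, uni), universe = uni)
  rk <- rankTFs(filterNetwork(net), diff)
  expect_equal(rk$tf[1], "exact")
  expect_lt(rk$f[1], rk$f[2])
  # k and m are reported per TF as in the parenthetical convention
  expect_equal(rk$k[rk$tf == "broad"], 3L)
  expect_equal(rk$m[rk$tf == "broad"], 10L)
  # n = N degenerate case: all f = 1
  expect_warning(rkAll <- rankTFs(filterNetwork(net), uni), "degenerate|n = N")
  expect_true(all(rkAll$f == 1))
  expect_true(attr(rkAll, "degenerate"))
})

test_that("top-5 selection expands ties at the fifth-lowest f value", {
  uni <- sprintf("E%02d", 1:12)
  diff <- uni[1:4]
  # six TFs with identical target sets -> identical f; all must be selected
  tfs <- paste0("T", 1:6)
  net <- regulatoryNetwork(
    tf = rep(tfs, each = 2), target = rep(c("E01", "E02"), 6),
    universe = uni)
  rk <- rankTFs(filterNetwork(net), diff, top = 5)
  expect_equal(sum(rk$selected), 6L)
  expect_equal(length(unique(rk$f[rk$selected])), 1L)
})

test_that("planted regulators rank in the top five across seeded replicates", {
  # scaled-down version (60 replicates); the acceptance suite runs 200
  hits <- vapply(1:60, function(s) {
    sim <- simulateNetwork(syntheticTruth(seed = s))
    rk <- rankTFs(filterNetwork(sim$network), sim$diffSet)
    all(sim$activeTFs %in% rk$tf[rk$selected])
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  # null case: no preferential targeting -> recovery near chance
  nullHits <- vapply(1:60, function(s) {
    sim <- simulateNetwork(syntheticTruth(seed = s, hitProbability = 18 / 47))
    rk <- rankTFs(filterNetwork(sim$network), sim$diffSet)
    all(sim$activeTFs %in% rk$tf[rk$selected])
  }, logical(1))
  expect_lt(mean(nullHits), 0.9)
})
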