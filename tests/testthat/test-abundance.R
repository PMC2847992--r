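plateSeries <- function(gain = 3, auto = 1, noise = 0, seed = NULL,
                        mu = 0.3, plateau = 12) {
  if (!is.null(seed)) set.seed(seed)
  tt <- seq(0, 20, by = 0.5)
  bm <- 100 * exp(mu * pmin(tt, plateau))
  g <- (gain + auto) * bm
  if (noise > 0) {
    bm <- bm * exp(rnorm(length(tt), 0, noise))
    g <- g * exp(rnorm(length(tt), 0, noise))
  }
  data.frame(time = tt, biomass = bm, gfp = g)
}

test_that("corrected GFP/biomass slope equals the expression level", {
  s <- plateSeries(gain = 3)
  r <- plateSeries(gain = 0)
  est <- expressionLevel(s, r)
  expect_equal(est$level, 3, tolerance = 1e-9)
  expect_equal(est$status, "ok")
  # self-correction: strain identical to reference -> level 0
  self <- expressionLevel(r, r)
  expect_equal(self$level, 0)
  # doubling the gfp gain doubles levels (calibration contract)
  s2 <- s; s2$gfp <- 2 * s2$gfp
  r2 <- r; r2$gfp <- 2 * r2$gfp
  expect_equal(expressionLevel(s2, r2)$level, 2 * est$level,
               tolerance = 1e-9)
})

test_that("no-growth and below-detection strains are flagged", {
  flat <- data.frame(time = 0:10, biomass = rep(100, 11), gfp = rep(150, 11))
  est <- expressionLevel(flat, plateSeries(gain = 0))
  expect_equal(est$status, "ng")
  expect_true(is.na(est$level))
  # reference brighter than strain -> below detection, level clamped to 0
  dim <- plateSeries(gain = 0.5)
  bright <- plateSeries(gain = 2)
  est2 <- expressionLevel(dim, bright)
  expect_equal(est2$status, "below_detection")
  expect_equal(est2$level, 0)
  # growing series sampled so sparsely that the window holds < 4 points
  tt <- c(0, 5, 10, 15, 20)
  bm <- 100 * exp(0.3 * pmin(tt, 12))
  sparse <- data.frame(time = tt, biomass = bm, gfp = 2 * bm)
  expect_error(expressionLevel(sparse, sparse), "window")
})

test_that("generator round trip recovers the planted expression level", {
  truth <- syntheticTruth(seed = 2)
  levels <- replicate(8, {
    sd <- sample.int(1e6, 1)
    s <- simulatePlate(truth, seed = sd)
    r <- simulatePlate(truth, expression = 0, seed = sd + 1)
    expressionLevel(s, r)$level
  })
  expect_lt(abs(mean(levels) - truth$expression) / truth$expression, 0.10)
})

test_that("fold changes call a planted effect and keep exchangeability", {
  lv <- simulateExpressionContrast(syntheticTruth(seed = 4))
  fc <- foldChanges(lv, baseline = "glucose")
  expect_s3_class(fc, "FoldChangeTable")
  expect_gt(fc$pyruvate_fold, 2.5)
  expect_lt(fc$pyruvate_fold, 3.5)
  expect_lte(fc$pyruvate_p, 0.12)
  expect_equal(fc$pyruvate_code, "ok")
  # permuting replicate labels changes nothing
  lvp <- lv[sample(nrow(lv)), ]
  lvp$replicate <- ave(seq_len(nrow(lvp)), lvp$condition, FUN = seq_along)
  fcp <- foldChanges(lvp, baseline = "glucose")
  expect_equal(fcp$pyruvate_fold, fc$pyruvate_fold)
  expect_equal(fcp$pyruvate_p, fc$pyruvate_p)
})

test_that("identical replicate sets give fold 1 and nsc; ng and bd propagate", {
  lv <- data.frame(
    enzyme = "E", condition = rep(c("glucose", "pyr"), each = 4),
    replicate = rep(1:4, 2),
    level = c(2.0, 2.1, 1.9, 2.0, 2.0, 2.1, 1.9, 2.0),
    status = "ok")
  fc <- foldChanges(lv, baseline = "glucose")
  expect_equal(fc$pyr_fold, 1)
  expect_equal(fc$pyr_code, "nsc")
  lv$status[lv$condition == "pyr"] <- "ng"
  expect_equal(foldChanges(lv, "glucose")$pyr_code, "ng")
  lv$status[lv$condition == "pyr"] <- "below_detection"
  lv$level[lv$condition == "pyr"] <- 0
  fcb <- foldChanges(lv, "glucose")
  expect_equal(fcb$pyr_code, "bd")
  expect_equal(fcb$pyr_fold, 0)
})

test_that("pattern classification reproduces the published examples and partitions", {
  t2 <- loadTable2Fixture()
  cls <- classifyPatterns(t2)
  byEnzyme <- setNames(cls$class, cls$enzyme)
  expect_equal(byEnzyme[["Cit1p"]], "positively_related")   # up gal & pyr
  expect_equal(byEnzyme[["Aco2p"]], "negatively_related")   # down on pyr
  expect_equal(byEnzyme[["Yea6p"]], "unchanged")            # all nsc
  expect_equal(byEnzyme[["Pda1p"]], "pyruvate_only_up")
  # exhaustive and mutually exclusive: one class per enzyme, counts add up
  expect_equal(nrow(cls), nrow(t2))
  expect_equal(sum(table(cls$class)), 47L)
})

test_that("correlation screen selects Cit1p positively and Pdc1p negatively", {
  t2 <- loadTable2Fixture()
  scr <- suppressWarnings(correlateWithRespiration(t2))
  cit <- scr[scr$enzyme == "Cit1p", ]
  # closed-form Pearson on the four points (1, 1, 6.0, 14.1) vs degrees
  rOracle <- cor(c(1, 1, 6.0, 14.1), c(0, 0.06, 6.9, 13.3))
  expect_equal(cit$r, rOracle, tolerance = 1e-12)
  expect_true(cit$selected)
  pdc <- scr[scr$enzyme == "Pdc1p", ]
  expect_lt(pdc$r, 0)
  # constant profiles are excluded with a warning
  expect_warning(correlateWithRespiration(t2), "zero variance")
  expect_true(is.na(scr$r[scr$enzyme == "Yea6p"]))
  # no-growth strains cannot be screened
  expect_true(is.na(scr$r[scr$enzyme == "Rip1p"]))
})

test_that("differential summary counts are a pure function of the table", {
  t2 <- loadTable2Fixture()
  s1 <- summarizeDifferential(t2)
  s2 <- summarizeDifferential(loadTable2Fixture())
  expect_identical(s1, s2)
  empty <- t2[0, ]
  s0 <- summarizeDifferential(empty)
  expect_equal(unlist(s0), c(up_gal = 0, up_pyr = 0, up_tca_resp_union = 0,
                             down_tca_resp_union = 0, pct_changed = 0))
  noPath <- t2
  noPath$pathway[3] <- NA
  expect_error(summarizeDifferential(noPath), "Pdb1p")
})
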