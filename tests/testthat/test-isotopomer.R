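test_that("correction matrix reduces to identity with no non-backbone atoms", {
  expect_equal(isotopeCorrectionMatrix(c(C = 0), 4), diag(4))
  expect_equal(isotopeCorrectionMatrix(integer(0), 3), diag(3))
})

test_that("one extra carbon gives columns of the natural 13C pair", {
  M <- isotopeCorrectionMatrix(c(C = 1), 2)
  expect_equal(M, matrix(c(0.9893, 0.0107, 0, 0.9893), 2, 2))
})

test_that("shift distributions equal the brute-force polynomial expansion", {
  comps <- list(c(H = 30, Si = 2),
                c(C = 8, H = 26, N = 1, O = 2, Si = 2),   # Ala fragment
                c(C = 14, H = 40, N = 1, O = 4, Si = 3))  # Asp fragment
  for (comp in comps) {
    d <- fragmentShiftDistribution(comp)
    o <- oracleShiftDistribution(comp)
    len <- min(length(d), length(o))
    expect_equal(d[1:len], o[1:len], tolerance = 1e-12)
    M <- isotopeCorrectionMatrix(comp, 4)
    expect_equal(M[, 1], d[1:4])
    expect_true(all(M[upper.tri(M)] == 0))
    expect_true(all(colSums(M) <= 1 + 1e-12))
  }
  expect_error(fragmentShiftDistribution(c(C = -1)), "non-negative")
})

test_that("correction matrices compose under composition union", {
  a <- c(C = 3, H = 10)
  b <- c(O = 2, Si = 1)
  ab <- c(C = 3, H = 10, O = 2, Si = 1)
  L <- 6
  expect_equal(isotopeCorrectionMatrix(ab, L),
               isotopeCorrectionMatrix(a, L) %*% isotopeCorrectionMatrix(b, L),
               tolerance = 1e-12)
})

test_that("forward-then-correct round trip recovers the labeling pattern", {
  comp <- c(C = 14, H = 40, N = 1, O = 4, Si = 3)
  set.seed(11)
  for (rep in 1:20) {
    x <- mdv(runif(5), nCarbons = 4, fragmentId = "f")
    w <- sample(c(0, 0.2, 0.4), 1)
    exp <- labelingExperiment(tracerPurity = 1, fractionUnlabeled = w)
    y <- forwardMDV(x, comp, exp)
    back <- correctMDV(y, comp, exp)
    expect_equal(abundances(back), abundances(x), tolerance = 1e-6)
    expect_true(all(abundances(back) >= 0))
    expect_equal(sum(abundances(back)), 1, tolerance = 1e-9)
  }
})

test_that("identity conditions leave the MDV unchanged and natural input corrects to m0", {
  x <- mdv(c(0.7, 0.2, 0.1), nCarbons = 2, fragmentId = "f")
  # no non-backbone atoms, no backbone correction, w = 0 -> output = input
  out <- correctMDV(x, integer(0), labelingExperiment(fractionUnlabeled = 0),
                    correctBackbone = FALSE)
  expect_equal(abundances(out), abundances(x), tolerance = 1e-9)
  # a fully natural (unlabeled) fragment corrects to a point mass at m0
  nat <- forwardMDV(mdv(c(1, 0, 0, 0), nCarbons = 3, fragmentId = "nat"),
                    c(H = 7), labelingExperiment(tracerPurity = 1))
  corr <- correctMDV(nat, c(H = 7), labelingExperiment(tracerPurity = 1))
  expect_equal(abundances(corr), c(1, 0, 0, 0), tolerance = 1e-9)
})

test_that("plain inversion and NNLS agree on clean data; w >= 1 is rejected", {
  comp <- c(C = 5, Si = 1)
  x <- mdv(c(0.5, 0.3, 0.1, 0.1), nCarbons = 3, fragmentId = "f")
  y <- forwardMDV(x, comp, labelingExperiment(tracerPurity = 1))
  a <- correctMDV(y, comp, method = "nnls")
  b <- correctMDV(y, comp, method = "solve")
  expect_equal(abundances(a), abundances(b), tolerance = 1e-8)
  expect_error(labelingExperiment(fractionUnlabeled = 1), "fractionUnlabeled")
})

test_that("nnls solves small systems against the analytic solution", {
  # well-conditioned system with interior solution: matches lsfit
  A <- matrix(c(2, 0, 1, 0, 3, 1), 3, 2)
  b <- c(4, 3, 2.5)
  ls <- qr.solve(A, b)
  expect_true(all(ls > 0))
  expect_equal(nnls(A, b)$x, unname(ls), tolerance = 1e-10)
  # a system whose unconstrained solution is negative gets clamped
  A2 <- matrix(c(1, 1, 1, 2), 2, 2)
  b2 <- c(1, -1)
  fit <- nnls(A2, b2)
  expect_true(all(fit$x >= 0))
  # KKT: gradient non-negative at active coords, zero at passive
  g <- drop(crossprod(A2, A2 %*% fit$x - b2))
  expect_true(all(g >= -1e-8))
  expect_true(all(abs(g[fit$x > 0]) < 1e-8))
})

test_that("bundled TBDMS fragment compositions load and are usable", {
  frags <- tbdmsFragments()
  expect_true(all(c("Ala_M57", "Asp_M57", "Glu_M57", "Gly_M57") %in%
                    names(frags)))
  expect_true(all(vapply(frags, function(v) all(v >= 0), logical(1))))
  M <- isotopeCorrectionMatrix(frags$Ala_M57, 4)
  expect_equal(dim(M), c(4L, 4L))
})
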