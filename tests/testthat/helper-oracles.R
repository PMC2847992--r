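# Independent oracles used across the suite.  These deliberately avoid the
# package's internal helpers: lm() instead of the closed-form regression,
# stats::convolve() instead of the package convolution, exhaustive grids and
# subset enumeration instead of algebra.

# exhaustive growth-window search with lm(), same selection rule
oracleGrowthWindow <- function(time, od, minPoints = 6L, r2Threshold = 0.99) {
  keep <- od > 0
  t <- time[keep]; y <- log(od[keep]); n <- length(t)
  best <- NULL
  for (i in seq_len(n - minPoints + 1L)) {
    for (j in seq.int(i + minPoints - 1L, n)) {
      fit <- stats::lm(yy ~ tt, data = data.frame(tt = t[i:j], yy = y[i:j]))
      slope <- unname(stats::coef(fit)[2])
      r2 <- summary(fit)$r.squared
      cand <- list(mu = slope, r2 = r2, window = c(t[i], t[j]))
      if (is.null(best)) { best <- cand; next }
      if (cand$r2 >= r2Threshold && best$r2 >= r2Threshold) {
        if (cand$mu > best$mu) best <- cand
      } else if (cand$r2 >= r2Threshold && best$r2 < r2Threshold) {
        best <- cand
      } else if (cand$r2 < r2Threshold && best$r2 < r2Threshold &&
                 cand$r2 > best$r2) {
        best <- cand
      }
    }
  }
  best
}

# polynomial-expansion oracle for isotope distributions (stats::convolve)
oracleShiftDistribution <- function(composition, tables = naturalAbundances()) {
  d <- 1
  for (el in names(composition)) {
    for (i in seq_len(composition[[el]])) {
      d <- stats::convolve(d, rev(tables[[el]]), type = "open")
    }
  }
  d
}

# grid-search oracle for the two-precursor mixing fraction
oracleMixingGrid <- function(p, a, b, step = 0.001) {
  grid <- seq(0, 1, by = step)
  sse <- vapply(grid, function(R) sum((p - (R * a + (1 - R) * b))^2),
                numeric(1))
  grid[which.min(sse)]
}

# exhaustive-enumeration oracle for the hypergeometric tail: universe 1..N,
# TF targets 1..m, differential sets enumerated with combn
oracleFEnumeration <- function(k, m, n, N) {
  if (n == 0L) return(if (k == 0L) 1 else NA_real_)
  sets <- utils::combn(N, n)
  mean(apply(sets, 2, function(s) sum(s <= m) >= k))
}

# brute-force oracle for constrained weighted least squares on the null
# space (<= 3 degrees of freedom).  Every subset of the inequality
# constraints is tried as a candidate active set; each candidate is solved
# by generic stacked least squares (the pinned constraints entering as
# heavily weighted rows), candidates violating any constraint are
# discarded, and the best feasible candidate wins.  A dense grid over the
# null-space coefficients double-checks that no grid point beats it.
# Purely enumerative; shares no algebra with the package solver.
oracleNullspaceGrid <- function(model, measured, ranges = list(),
                                width = 5, gridPoints = 41L) {
  S <- stoichiometryMatrix(model)
  bal <- S[respfluxBalanced(model), , drop = FALSE]
  sv <- svd(bal, nu = 0, nv = ncol(bal))
  r <- sum(sv$d >= 1e-10 * max(sv$d))
  N <- sv$v[, (r + 1):ncol(bal), drop = FALSE]
  p <- ncol(N)
  stopifnot(p <= 3)
  rxns <- colnames(S)
  rev <- isReversible(model)

  # objective and inequality system over z
  C <- matrix(0, nrow(measured), length(rxns), dimnames = list(NULL, rxns))
  for (i in seq_len(nrow(measured))) C[i, measured$reaction[i]] <- 1
  C <- (C %*% N) / measured$sd
  d <- measured$value / measured$sd
  G <- N[!rev, , drop = FALSE]
  h <- numeric(nrow(G))
  for (rg in ranges) {
    a <- numeric(length(rxns)); names(a) <- rxns
    a[names(rg$coef)] <- rg$coef
    aN <- drop(a %*% N)
    if (is.finite(rg$lower)) { G <- rbind(G, aN); h <- c(h, rg$lower) }
    if (is.finite(rg$upper)) { G <- rbind(G, -aN); h <- c(h, -rg$upper) }
  }
  nIneq <- nrow(G)
  stopifnot(nIneq <= 14)
  feasible <- function(z) all(G %*% z >= h - 1e-7)
  objective <- function(z) sum((C %*% z - d)^2)

  BIG <- 1e7
  best <- NULL; bestVal <- Inf
  for (mask in 0:(2^nIneq - 1)) {
    act <- which(bitwAnd(mask, 2^(seq_len(nIneq) - 1)) > 0)
    if (length(act) > p) next
    Cs <- rbind(C, BIG * G[act, , drop = FALSE])
    ds <- c(d, BIG * h[act])
    z <- tryCatch(qr.solve(Cs, ds), error = function(e) NULL)
    if (is.null(z)) next
    if (length(act) && max(abs(G[act, , drop = FALSE] %*% z - h[act])) > 1e-5)
      next
    if (!feasible(z)) next
    val <- objective(z)
    if (val < bestVal) { bestVal <- val; best <- z }
  }
  stopifnot(!is.null(best))
  # dense-grid cross-check: no feasible grid point may do better
  axes <- lapply(seq_len(p), function(i)
    seq(-width, width, length.out = gridPoints))
  gr <- as.matrix(expand.grid(axes))
  for (i in seq_len(nrow(gr))) {
    z <- gr[i, ]
    if (feasible(z) && objective(z) < bestVal - 1e-9)
      stop("grid point beats the enumeration oracle; oracle inconsistent")
  }
  v <- drop(N %*% best)
  names(v) <- rxns
  v
}

respfluxBalanced <- function(model) model@balanced

# cascade-constructed feasible glucose-like flux vector on the bundled
# model; built by sequential mass-balance arithmetic, independent of the
# solver.  `tca` is the respiratory TCA flux (mdh_mit).
cascadeGlucoseFluxes <- function(uptake = 16.3, mu = 0.33, ppp = 2.4,
                                 glycerol = 1, acetate = 0.797, tca = 0,
                                 biomass = c(g6p_cyt = 0.9, p5p_cyt = 0.9,
                                             t3p_cyt = 0.3, pyr_cyt = 1.9,
                                             accoa_cyt = 0.9, akg_mit = 1.1,
                                             oaa_mit = 1.3)) {
  bm <- biomass * mu
  p5p_t3p <- (ppp - bm[["p5p_cyt"]]) / 3
  glycolysis <- uptake - ppp - bm[["g6p_cyt"]]
  pyk <- 2 * glycolysis + 5 * p5p_t3p - bm[["t3p_cyt"]] - glycerol
  tca_lump <- tca                       # mae = 0, mal_mit_tr = 0
  idh <- tca_lump + bm[["akg_mit"]]
  cs <- idh
  oaa_mit_tr <- cs + bm[["oaa_mit"]] - tca
  pyc <- oaa_mit_tr                     # mdh_cyt = 0, pck = 0
  pdh <- cs
  pyr_mit <- pdh
  pdc <- pyk - bm[["pyr_cyt"]] - pyr_mit - pyc
  acs <- bm[["accoa_cyt"]]
  ald <- acetate + acs
  adh <- pdc - ald
  co2_mit <- pdh + idh + tca_lump
  co2_ex <- ppp + pdc + co2_mit - pyc
  c(uptake = uptake, ppp = ppp, p5p_t3p = p5p_t3p, glycolysis = glycolysis,
    pyk = pyk, pck = 0, pdc = pdc, adh = adh, ald = ald, acs = acs,
    glycerol = glycerol, pyr_mit = pyr_mit, pdh = pdh, pyc = pyc,
    oaa_mit_tr = oaa_mit_tr, mdh_cyt = 0, mal_mit_tr = 0, cs = cs,
    idh = idh, tca_lump = tca_lump, mdh_mit = tca, mae = 0,
    etoh_ex = adh, ace_ex = acetate, glyc_ex = glycerol,
    co2_mit_tr = co2_mit, co2_ex = co2_ex, biomass = mu)
}

# constraint set that pins all nine degrees of freedom of the bundled model
cascadeConstraints <- function(v, sdFrac = 0.0) {
  meas <- data.frame(
    reaction = c("uptake", "biomass", "etoh_ex", "ace_ex", "glyc_ex",
                 "co2_ex"),
    value = unname(v[c("uptake", "biomass", "etoh_ex", "ace_ex", "glyc_ex",
                       "co2_ex")]),
    sd = c(1.1, 0.01, 1.5, 0.1, 0.1, 2))
  rppp <- unname(v[["ppp"]] / v[["uptake"]])
  Rana <- unname(v[["oaa_mit_tr"]] / (v[["oaa_mit_tr"]] + v[["mdh_mit"]]))
  fluxConstraints(meas, ratios = list(
    list(coef = c(ppp = 1, uptake = -rppp), sd = 0.02),
    list(coef = c(oaa_mit_tr = 1 - Rana, mdh_mit = -Rana), sd = 0.02),
    list(coef = c(mae = 1), sd = 0.01),
    list(coef = c(mdh_cyt = 1), sd = 0.01),
    list(coef = c(pck = 1), sd = 0.01)))
}
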