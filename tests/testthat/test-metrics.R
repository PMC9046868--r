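test_that("totalMass is the 4D midpoint quadrature", {
  g <- smallGrid(8)
  ones <- array(1, c(8, 8, 8, 8))
  expect_equal(totalMass(ones, g), 1)           # unit density on the unit^4 box
  expect_equal(totalMass(0 * ones, g), 0)
  expect_equal(totalMass(2 * ones, g), 2 * totalMass(ones, g))
  expect_error(totalMass(array(1, c(4, 4, 4, 4)), g), "shape mismatch")
})

test_that("the structural marginal integrates out space exactly", {
  g <- smallGrid(8)
  set.seed(5)
  fx <- matrix(runif(64), 8, 8)
  gy <- matrix(runif(64), 8, 8)
  c4 <- array(outer(as.vector(fx), as.vector(gy)), c(8, 8, 8, 8))
  marg <- structuralMarginal(c4, g)
  # separable density: marginal proportional to the structural factor
  expect_equal(marg / sum(marg), gy / sum(gy))
  # Fubini: the marginal holds the whole mass
  expect_equal(sum(marg) * g@dxStructural^2, totalMass(c4, g),
               tolerance = 1e-12)
  expect_equal(structuralMarginal(0 * c4, g), matrix(0, 8, 8))
})

test_that("subpopulation fractions partition the mass", {
  g <- buildGrids(8, 24)
  atlas <- defaultAtlas()
  ny <- 24

  # mass concentrated at the proliferative anchor
  c4 <- array(0, c(8, 8, ny, ny))
  yc <- structuralCenters(g)
  k <- which.min(abs(yc - 0.20))
  c4[4, 4, k, k] <- 1
  fr <- subpopFractions(c4, atlas, g)
  expect_equal(unname(fr["proliferative"]), 1)

  # uniform density: each fraction equals its disc's share of grid cells,
  # verified by exhaustive distance computation over the grid centers
  cU <- array(1, c(8, 8, ny, ny))
  frU <- subpopFractions(cU, atlas, g)
  pts <- cbind(rep(yc, times = ny), rep(yc, each = ny))
  for (nm in anchorNames(atlas)) {
    ctr <- anchorPosition(atlas, nm)
    d <- sqrt((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2)
    # count centers whose *nearest* in-radius anchor is nm
    d2all <- sapply(seq_len(6), function(i)
      (pts[, 1] - atlas@anchors$y1[i])^2 + (pts[, 2] - atlas@anchors$y2[i])^2)
    nearest <- max.col(-d2all, ties.method = "first")
    inDisc <- sqrt(d2all[cbind(seq_len(nrow(pts)), nearest)]) <=
      atlasRadius(atlas)
    expected <- sum(inDisc & atlas@anchors$name[nearest] == nm) / (ny * ny)
    expect_equal(unname(frU[nm]), expected)
  }
  expect_equal(sum(frU), 1, tolerance = 1e-12)

  # zero density: flagged, all fractions zero
  fr0 <- subpopFractions(0 * cU, atlas, g)
  expect_true(attr(fr0, "zeroMass"))
  expect_equal(unname(sum(fr0)), 0)
})

test_that("heterogeneity variance matches closed forms", {
  ny <- 32
  g <- buildGrids(8, ny)
  # a single occupied structural cell: variance ~ 0
  c4 <- array(0, c(8, 8, ny, ny))
  c4[, , 16, 16] <- 1
  expect_equal(heterogeneityVariance(c4, g), 0)

  # uniform on the unit square: trace variance 2 * 1/12 = 1/6 (the discrete
  # cell-center quadrature gives (1 - 1/ny^2)/6)
  cU <- array(1, c(8, 8, ny, ny))
  expect_equal(heterogeneityVariance(cU, g), (1 - 1 / ny^2) / 6,
               tolerance = 1e-12)
  expect_equal(heterogeneityVariance(cU, g), 1 / 6, tolerance = 0.005)

  # two equal point masses: variance = |p - q|^2 / 4 for the occupied centers
  c2 <- array(0, c(8, 8, ny, ny))
  c2[, , 1, 1] <- 1
  c2[, , ny, ny] <- 1
  yc <- structuralCenters(g)
  d2 <- (yc[ny] - yc[1])^2 * 2
  expect_equal(heterogeneityVariance(c2, g), d2 / 4)

  expect_error(heterogeneityVariance(0 * c2, g), "undefined metric")
})

test_that("variance is translation invariant and scales quadratically", {
  ny <- 16
  g1 <- buildGrids(8, ny)
  set.seed(8)
  w <- matrix(runif(ny * ny), ny, ny)
  c4 <- array(rep(as.vector(w), each = 64), c(8, 8, ny, ny))
  v1 <- heterogeneityVariance(c4, g1)
  # translation: shift the whole pattern by whole cells
  sh <- rbind(w[9:16, ], w[1:8, ])
  cSh <- array(rep(as.vector(sh), each = 64), c(8, 8, ny, ny))
  # a cyclic shift is not a translation of the support unless the pattern
  # stays inside; use a compactly supported pattern instead
  wC <- matrix(0, ny, ny); wC[3:6, 3:6] <- matrix(runif(16), 4, 4)
  cC <- array(rep(as.vector(wC), each = 64), c(8, 8, ny, ny))
  wT <- matrix(0, ny, ny); wT[9:12, 9:12] <- wC[3:6, 3:6]
  cT <- array(rep(as.vector(wT), each = 64), c(8, 8, ny, ny))
  expect_equal(heterogeneityVariance(cC, g1), heterogeneityVariance(cT, g1))
  # scaling the extent by L scales the variance by L^2
  g2 <- buildGrids(8, ny, structuralSide = 2)
  expect_equal(heterogeneityVariance(c4, g2), 4 * v1)
})

test_that("mode counting finds well-separated bumps and ignores flat fields", {
  ny <- 32
  g <- buildGrids(8, ny)
  yc <- structuralCenters(g)
  bump <- function(ctr, s = 0.05)
    outer(exp(-(yc - ctr[1])^2 / (2 * s^2)), exp(-(yc - ctr[2])^2 / (2 * s^2)))
  # bump centers off the cell boundaries (a peak exactly between two cells
  # has no strict maximum by construction)
  expect_equal(countModes(bump(c(0.52, 0.47))), 1L)
  two <- bump(c(0.27, 0.22)) + bump(c(0.73, 0.78))
  expect_equal(countModes(two), 2L)
  expect_equal(countModes(matrix(1, ny, ny)), 0L)   # no strict maxima
  expect_equal(countModes(matrix(0, ny, ny)), 0L)
  # a faint third bump below the relative threshold is not counted
  three <- two + 0.01 * bump(c(0.73, 0.22))
  expect_equal(countModes(three, relThreshold = 0.05), 2L)
  expect_error(countModes(-two), "contract violation")
})

test_that("time to resistance interpolates the baseline crossing", {
  # crossing between t=100 (0.9 M0) and t=110 (1.1 M0) -> 105
  times <- c(0, 50, 100, 110)
  mass <- c(1, 0.5, 0.9, 1.1)
  expect_equal(timeToResistance(mass, times, baseline = 1, start = 0), 105)
  # strictly below baseline: none
  expect_true(is.na(timeToResistance(c(1, 0.5, 0.4), c(0, 1, 2), 1, 0)))
  # monotone decreasing: none
  expect_true(is.na(timeToResistance(c(1, 0.8, 0.6), c(0, 1, 2), 1, 0)))
  # invariant under uniform rescaling of the mass series
  expect_equal(timeToResistance(7 * mass, times, baseline = 7, start = 0), 105)
})

test_that("phase segmentation recovers shrink / MRD / regrow", {
  t <- 0:250
  m <- c(seq(1, 0.1, length.out = 51), rep(0.1, 100),
         seq(0.1, 1.2, length.out = 100))
  ph <- segmentPhases(m, t, slopeTol = 0.002, minDuration = 10)
  expect_equal(ph$label, c("shrink", "MRD", "regrow"))
  expect_lt(abs(ph$end[1] - 50), 10)
  expect_lt(abs(ph$end[2] - 150), 10)
  # the phases partition the horizon
  expect_equal(ph$start[1], 0)
  expect_equal(ph$end[3], 250)

  # monotone increasing: one regrow phase
  phUp <- segmentPhases(seq(1, 2, length.out = 100), 0:99)
  expect_equal(phUp$label, "regrow")
  # constant: one MRD phase
  phFlat <- segmentPhases(rep(1, 100), 0:99)
  expect_equal(phFlat$label, "MRD")
  # invariant under uniform rescaling
  ph2 <- segmentPhases(5 * m, t, slopeTol = 0.002, minDuration = 10)
  expect_equal(ph2$label, ph$label)
  expect_equal(ph2$end, ph$end)
})

test_that("zoning overlap is the spatial cosine similarity", {
  nx <- 8; ny <- 24
  g <- buildGrids(nx, ny)
  atlas <- defaultAtlas()
  yc <- structuralCenters(g)
  kP <- which.min(abs(yc - 0.20))          # a cell inside the proliferative disc
  kI <- c(which.min(abs(yc - 0.85)), which.min(abs(yc - 0.50)))  # invasive

  mk <- function(spatialCellsP, spatialCellsI) {
    c4 <- array(0, c(nx, nx, ny, ny))
    for (s in spatialCellsP) c4[s[1], s[2], kP, kP] <- 1
    for (s in spatialCellsI) c4[s[1], s[2], kI[1], kI[2]] <- 1
    c4
  }
  # identical spatial fields -> overlap 1
  z1 <- zoningOverlap(mk(list(c(1, 1)), list(c(1, 1))), atlas, g)
  expect_equal(z1$overlap["proliferative", "invasive"], 1)
  # disjoint spatial supports -> overlap 0
  z0 <- zoningOverlap(mk(list(c(1, 1)), list(c(8, 8))), atlas, g)
  expect_equal(z0$overlap["proliferative", "invasive"], 0)
  # hand-computed cosine: (1,0,...) vs (1,1,0,...) -> 1/sqrt(2)
  zH <- zoningOverlap(mk(list(c(1, 1)), list(c(1, 1), c(2, 1))), atlas, g)
  expect_equal(zH$overlap["proliferative", "invasive"], 1 / sqrt(2))
  # zonation index: 1 - mean off-diagonal overlap over the two live fields
  expect_equal(zH$zonationIndex, 1 - 1 / sqrt(2))
  expect_error(zoningOverlap(array(0, c(nx, nx, ny, ny)), atlas, g),
               "undefined metric")
})
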