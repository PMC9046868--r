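test_that("grids are cell-centered and reproducible from the configuration", {
  g <- buildGrids(4, 4)
  expect_equal(spatialCenters(g), c(0.125, 0.375, 0.625, 0.875))
  expect_equal(structuralCenters(g), c(0.125, 0.375, 0.625, 0.875))

  g24 <- buildGrids(24, 24)
  expect_equal(nCells4D(g24), 24^4)

  gWide <- buildGrids(4, 4, spatialSide = 2)
  expect_equal(gWide@dxSpatial, 0.5)
  # centers strictly inside the extent
  expect_true(all(spatialCenters(gWide) > 0 & spatialCenters(gWide) < 2))
})

test_that("bad resolutions are configuration errors naming the key", {
  expect_error(buildGrids(3, 8), "grid.n_spatial")
  expect_error(buildGrids(8, 3), "grid.n_structural")
  expect_error(buildGrids(8.5, 8), "grid.n_spatial")
})

test_that("the default atlas has the six anchors at their compass positions", {
  atlas <- defaultAtlas()
  nms <- anchorNames(atlas)
  expect_length(nms, 6L)
  expect_setequal(nms, c("proliferative", "invasive", "pigmented",
                         "NCSC", "SMC", "URC"))
  expect_false(anyDuplicated(nms) > 0)

  p <- anchorPosition(atlas, "proliferative")
  expect_true(all(p < 0.5))                        # south-west
  smc <- anchorPosition(atlas, "SMC")
  expect_gt(smc[2], 0.75)                          # north
  expect_equal(smc[1], 0.5, tolerance = 0.01)
  inv <- anchorPosition(atlas, "invasive")
  expect_gt(inv[1], 0.75)                          # east
  expect_true(inv[2] > 0.25 && inv[2] < 0.75)
  pig <- anchorPosition(atlas, "pigmented")
  expect_true(pig[1] < 0.5 && pig[2] > 0.5)        # north-west
  ncsc <- anchorPosition(atlas, "NCSC")
  expect_true(all(ncsc > 0.5))                     # north-east
  urc <- anchorPosition(atlas, "URC")
  expect_true(urc[1] > 0.5 && urc[2] < 0.5)        # south-east
})

test_that("classifyState assigns anchors, boundaries and the center correctly", {
  atlas <- defaultAtlas()
  # each anchor lies inside its own disc
  for (nm in anchorNames(atlas))
    expect_identical(classifyState(anchorPosition(atlas, nm), atlas), nm)

  # the structural center is farther than one radius from every anchor
  # (verified by exhaustive distance computation)
  a <- atlas@anchors
  d <- sqrt((0.5 - a$y1)^2 + (0.5 - a$y2)^2)
  expect_true(all(d > atlasRadius(atlas)))
  expect_identical(classifyState(c(0.5, 0.5), atlas), "unassigned")

  # closed discs: a point at distance exactly one radius belongs to the disc
  p <- anchorPosition(atlas, "proliferative") + c(atlasRadius(atlas), 0)
  expect_identical(classifyState(p, atlas), "proliferative")

  expect_error(classifyState(c(1.2, 0.5), atlas), "domain error")
})

test_that("overlapping discs are broken by the nearest anchor", {
  atlas <- defaultAtlas(radius = 0.3)
  # invasive (0.85, 0.50) and NCSC (0.85, 0.85) discs overlap at radius 0.3
  expect_identical(classifyState(c(0.85, 0.70), atlas), "NCSC")
  expect_identical(classifyState(c(0.85, 0.64), atlas), "invasive")
})

test_that("the subdomains are a deterministic partial cover of the extent", {
  atlas <- defaultAtlas()
  g <- buildGrids(8, 24)
  yc <- structuralCenters(g)
  pts <- cbind(rep(yc, times = 24), rep(yc, each = 24))
  lab1 <- classifyState(pts, atlas)
  lab2 <- classifyState(pts, atlas)
  expect_identical(lab1, lab2)              # deterministic and total
  expect_true(all(nchar(lab1) > 0))
  frac <- mean(lab1 != "unassigned")
  expect_gt(frac, 0)                        # discs are visible on the grid
  expect_lt(frac, 1)                        # ... but do not cover the extent
})

test_that("atlas validity rejects bad geographies", {
  a <- defaultAtlas()@anchors
  expect_error(subpopulationAtlas(a[-1, ], radius = 0.15), "six anchors")
  expect_error(subpopulationAtlas(a, radius = 0.6), "radius")
  bad <- a; bad$y1[1] <- 1.4
  expect_error(subpopulationAtlas(bad, radius = 0.15), "inside")
})
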