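test_that("the advection field stabilizes the proliferative-SMC attractor line", {
  atlas <- defaultAtlas()
  p1 <- defaultParams(structural = list(k_adv = 1))
  # on the attractor at the proliferative abscissa (south edge)
  expect_equal(advectionField(c(0.20, 0), atlas, p1)[1, ], c(0, 0))
  # on the attractor at the SMC abscissa (north edge)
  expect_equal(advectionField(c(0.50, 1), atlas, p1)[1, ], c(0, 0))
  # direct evaluation of the closed form at an intermediate phenotype
  phi <- advectionField(c(0.70, 0.5), atlas, p1)
  expect_equal(phi[1, 1], -0.35)   # a(0.5) = 0.35 for the reference anchors
  expect_equal(phi[1, 2], 0)       # advection is horizontal only
  # scales linearly with the stiffness
  p2 <- defaultParams(structural = list(k_adv = 0.5))
  expect_equal(advectionField(c(0.70, 0.5), atlas, p2)[1, 1], -0.175)
  expect_error(advectionField(c(0.5, 1.5), atlas, p1), "domain error")
})

test_that("structural diffusivity has the stated north/south and west/east profile", {
  p <- refParams
  s <- p@structural
  # horizontal diffusion is maximal at the north edge, minimal at the south
  expect_equal(unname(structuralDiffusivity(c(0.3, 1), p)[1, "D_h"]), s$d_h_max)
  expect_equal(unname(structuralDiffusivity(c(0.3, 0), p)[1, "D_h"]), s$d_h_min)
  # vertical diffusion is minimal at the center, maximal (and symmetric)
  # at the west/east edges
  expect_equal(unname(structuralDiffusivity(c(0.5, 0.3), p)[1, "D_v"]), s$d_v_min)
  expect_equal(unname(structuralDiffusivity(c(0, 0.3), p)[1, "D_v"]), s$d_v_max)
  expect_equal(structuralDiffusivity(c(1, 0.3), p)[1, "D_v"],
               structuralDiffusivity(c(0, 0.3), p)[1, "D_v"])
})

test_that("structural transport conserves mass and vanishes on uniform slices", {
  g <- smallGrid(12)
  atlas <- defaultAtlas()
  pNoAdv <- defaultParams(structural = list(k_adv = 0))
  u <- matrix(1, 12, 12)
  expect_equal(structuralTransportDivergence(u, g, atlas, pNoAdv),
               matrix(0, 12, 12))

  # conservation for arbitrary nonnegative slices, with advection on
  set.seed(11)
  for (i in 1:5) {
    slice <- matrix(runif(12 * 12), 12, 12)
    div <- structuralTransportDivergence(slice, g, atlas, refParams)
    expect_lt(abs(sum(div) * g@dxStructural^2),
              1e-12 * sum(slice) * g@dxStructural^2)
  }

  expect_error(structuralTransportDivergence(-u, g, atlas, refParams),
               "contract violation")
})

test_that("constant-coefficient diffusion converges at second order to the heat operator", {
  atlas <- defaultAtlas()
  D <- 1e-3
  p <- defaultParams(structural = list(k_adv = 0, d_h_min = D, d_h_max = D,
                                       d_v_min = D, d_v_max = D))
  err <- function(n) {
    g <- buildGrids(8, n)
    yc <- structuralCenters(g)
    s2 <- 0.08^2
    slice <- outer(exp(-(yc - 0.5)^2 / (2 * s2)),
                   exp(-(yc - 0.5)^2 / (2 * s2)))
    num <- structuralTransportDivergence(slice, g, atlas, p)
    # analytic Laplacian of the product Gaussian, times D
    r2 <- outer((yc - 0.5)^2, (yc - 0.5)^2, "+")
    exact <- D * slice * (r2 / s2^2 - 2 / s2)
    sqrt(mean((num - exact)^2))
  }
  order <- log2(err(32) / err(64))
  expect_gt(order, 1.7)
  expect_lt(order, 2.3)
})

test_that("pure upwind advection is monotone below the CFL bound", {
  g <- smallGrid(16)
  atlas <- defaultAtlas()
  p <- defaultParams(structural = list(k_adv = 0.5, d_h_min = 0, d_h_max = 0,
                                       d_v_min = 0, d_v_max = 0))
  dt <- 0.5 * g@dxStructural / 0.5  # CFL for |u| <= k_adv * extent
  set.seed(4)
  slice <- matrix(runif(16 * 16), 16, 16)
  for (i in 1:50)
    slice <- slice + dt * structuralTransportDivergence(slice, g, atlas, p)
  expect_gte(min(slice), -1e-14)
})

test_that("a blob drifts onto the attractor line exponentially at rate k_adv", {
  g <- smallGrid(24)
  atlas <- defaultAtlas()
  k <- 0.4
  p <- defaultParams(structural = list(k_adv = k, d_h_min = 0, d_h_max = 0,
                                       d_v_min = 0, d_v_max = 0))
  # narrow band at y2 ~ 0.5 so the attractor abscissa is a(0.5) = 0.35
  slice <- gaussSlice(g, center = c(0.7, 0.5), sigma = 0.05)
  slice[, structuralCenters(g) < 0.45 | structuralCenters(g) > 0.55] <- 0
  a <- 0.35
  dt <- 0.02
  e0 <- abs(sliceCom1(slice, g) - a)
  s1 <- evolveSlice(slice, g, atlas, p, tEnd = 2, dt = dt)
  e1 <- abs(sliceCom1(s1, g) - a)
  s2 <- evolveSlice(s1, g, atlas, p, tEnd = 2, dt = dt)
  e2 <- abs(sliceCom1(s2, g) - a)
  rate1 <- log(e0 / e1) / 2
  rate2 <- log(e1 / e2) / 2
  expect_equal(rate1, k, tolerance = 0.2)
  expect_equal(rate2, k, tolerance = 0.2)
})

test_that("advection maintains hierarchy: URC stays below SMC from a naive start", {
  g <- smallGrid(24)
  atlas <- defaultAtlas()
  # the hierarchy property concerns the advection-dominated regime: state
  # diffusion small relative to the drift toward the attractor line
  p <- defaultParams(structural = list(k_adv = 0.05, d_h_min = 2e-4,
                                       d_h_max = 2e-3, d_v_min = 2e-4,
                                       d_v_max = 2.5e-3))
  slice <- gaussSlice(g, center = anchorPosition(atlas, "proliferative"),
                      sigma = 0.06)
  dt <- 0.1
  masks <- melanosim:::subpopMasks(atlas, g)
  names(masks) <- anchorNames(atlas)
  occ <- function(s, nm) sum(s[masks[[nm]]])
  # skip the first days, where both subdomains hold only far-tail mass
  slice <- evolveSlice(slice, g, atlas, p, tEnd = 20, dt = dt)
  for (chunk in 1:4) {
    slice <- evolveSlice(slice, g, atlas, p, tEnd = 10, dt = dt)
    expect_lt(occ(slice, "URC"), occ(slice, "SMC"))
  }
})
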