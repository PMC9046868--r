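test_that("the reaction source grows only with nutrient and kills only with drug", {
  nx <- 6; ny <- 8
  g <- buildGrids(nx, ny)
  atlas <- defaultAtlas()
  p <- refParams
  set.seed(2)
  c4 <- array(runif(nx^2 * ny^2), c(nx, nx, ny, ny))
  zero <- matrix(0, nx, nx)
  one <- matrix(1, nx, nx)

  # zero nutrient: saturating kinetics shut growth down entirely
  src0 <- reactionSource(c4, zero, zero, zero, g, atlas, p)
  expect_equal(src0, 0 * c4)

  # no drug anywhere: treatment is the only cause of death, so the source
  # is nonnegative
  src1 <- reactionSource(c4, one, zero, zero, g, atlas, p)
  expect_gte(min(src1), 0)

  # with drug on board the proliferative states are net-killed
  srcB <- reactionSource(c4, one, one, zero, g, atlas, p)
  expect_lt(min(srcB), 0)

  expect_error(reactionSource(c4, -one, zero, zero, g, atlas, p),
               "contract violation")
})

test_that("proliferation is fully suppressed at the SMC anchor when requested", {
  atlas <- defaultAtlas()
  p <- defaultParams(source = list(smc_suppression = 1))
  expect_equal(proliferationProfile(anchorPosition(atlas, "SMC"), atlas, p), 0)
  # and is near-maximal at the proliferative anchor (the wide SMC suppression
  # bump tilts the true maximum slightly to the south-west)
  pk <- proliferationProfile(anchorPosition(atlas, "proliferative"), atlas, p)
  g <- buildGrids(8, 16)
  yc <- structuralCenters(g)
  pts <- cbind(rep(yc, 16), rep(yc, each = 16))
  expect_gte(pk, 0.85 * max(proliferationProfile(pts, atlas, p)))
})

test_that("stableDt scales parabolically with spacing and linearly with safety", {
  # diffusion-dominated setup: enormous structural diffusivity
  p <- defaultParams(structural = list(d_h_max = 1, d_v_max = 1,
                                       d_h_min = 1, d_v_min = 1))
  dtCoarse <- stableDt(p, buildGrids(8, 8), safety = 1, maxDt = 10)
  dtFine <- stableDt(p, buildGrids(8, 16), safety = 1, maxDt = 10)
  expect_equal(dtCoarse / dtFine, 4, tolerance = 0.05)

  g <- buildGrids(16, 16)
  expect_equal(stableDt(refParams, g, safety = 0.45),
               0.5 * stableDt(refParams, g, safety = 0.9))

  # the step never exceeds the individual diffusion bound h^2 / (4 D)
  dt <- stableDt(refParams, g, safety = 1)
  Dmax <- max(unlist(refParams@structural[c("d_h_max", "d_v_max")]))
  expect_lte(dt, g@dxStructural^2 / (4 * Dmax))
})

test_that("transport-only stepping conserves mass to round-off and is deterministic", {
  cfg <- tinyConfig(horizon = 10, n = 8,
                    source = list(p_max = 0),
                    response = list(delta_B = 0, delta_H = 0))
  tr <- runSimulation(cfg)
  drift <- abs(tr@mass - tr@mass[1]) / tr@mass[1]
  expect_lt(max(drift), 1e-10)
  expect_equal(sum(tr@clippedMass), 0)

  tr2 <- runSimulation(cfg)
  expect_identical(tr@mass, tr2@mass)   # bit-identical rerun

  # one explicit step is bit-deterministic too
  g <- buildGrids(8, 8)
  atlas <- defaultAtlas()
  st <- initialState(g, atlas, refParams)
  sch <- treatmentSchedule("continuous", "BRAF_MEKi")
  s1 <- stepState(st, 0.05, g, atlas, refParams, sch)
  s2 <- stepState(st, 0.05, g, atlas, refParams, sch)
  expect_identical(s1@c, s2@c)
})

test_that("a pure-decay drug field halves in ln(2)/lam_w days", {
  g <- buildGrids(8, 8)
  atlas <- defaultAtlas()
  # empty tissue, no dosing, no transport of cells to disturb the drug
  p <- defaultParams(source = list(p_max = 0),
                     response = list(delta_B = 0, delta_H = 0),
                     environment = list(eps_w = 0, D_w = 0))
  lam <- p@environment$lam_w
  st <- initialState(g, atlas, p)
  st@wB <- matrix(1, 8, 8)
  sch <- treatmentSchedule("none", "BRAF_MEKi")
  dt <- 0.05
  tHalf <- log(2) / lam
  nSteps <- round(tHalf / dt)
  for (i in seq_len(nSteps)) st <- stepState(st, dt, g, atlas, p, sch)
  # Heun is second order: per-step error (lam dt)^3/6, accumulated ~ (lam dt)^2
  expect_equal(mean(st@wB), exp(-lam * nSteps * dt), tolerance = 1e-3)
})

test_that("the fused solver right-hand side equals the composed module operators", {
  nx <- 6; ny <- 8
  g <- buildGrids(nx, ny)
  atlas <- defaultAtlas()
  p <- refParams
  set.seed(13)
  st <- list(c = array(runif(nx^2 * ny^2), c(nx, nx, ny, ny)),
             v = matrix(runif(nx^2, 0.5, 1), nx, nx),
             n = matrix(runif(nx^2, 0.5, 1.5), nx, nx),
             a = matrix(runif(nx^2, 0, 0.3), nx, nx),
             wB = matrix(runif(nx^2), nx, nx),
             wH = matrix(runif(nx^2), nx, nx))
  ctx <- melanosim:::solverContext(g, atlas, p)
  dose <- c(BRAF_MEKi = 1, HCT = 0)
  fused <- melanosim:::modelRhs(st, dose, ctx)$dc

  rho <- melanosim:::totalSpatialDensity(st$c, g)
  composed <- array(0, dim(st$c))
  for (k in 1:ny) for (l in 1:ny)
    composed[, , k, l] <- composed[, , k, l] +
      spatialTransportDivergence(st$c[, , k, l], st$n, st$v, rho, g, p)
  for (i in 1:nx) for (j in 1:nx)
    composed[i, j, , ] <- composed[i, j, , ] +
      structuralTransportDivergence(st$c[i, j, , ], g, atlas, p)
  composed <- composed + reactionSource(st$c, st$n, st$wB, st$wH, g, atlas, p,
                                        rho = rho)
  expect_equal(fused, composed, tolerance = 1e-12)
})

test_that("an untreated tumor never loses mass", {
  cfg <- tinyConfig(horizon = 30, n = 8)
  tr <- runSimulation(cfg)
  expect_gte(min(diff(tr@mass)), -1e-12 * tr@mass[1])
  expect_gt(tr@mass[length(tr@mass)], tr@mass[1])
})

test_that("simulation refuses a config whose stable step is too small", {
  cfg <- tinyConfig(horizon = 5, n = 8,
                    structural_fluxes = list(d_h_max = 50, d_v_max = 50))
  cfg$run$min_dt <- 1e-3
  expect_error(runSimulation(cfg), "refused")
})
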