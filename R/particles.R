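# Monte Carlo particle oracle: an independent small-scale simulator of the
# same drift-diffusion(-growth) dynamics, used to verify the grid solver.

# reflect coordinates into [lo, hi] (mirror boundaries = zero-flux)
reflectInto <- function(x, lo, hi) {
  span <- hi - lo
  x <- (x - lo) %% (2 * span)
  x <- ifelse(x > span, 2 * span - x, x)
  x + lo
}

#' Simulate the particle counterpart of the continuity equation
#'
#' Euler-Maruyama integration of the state/space stochastic processes whose
#' law solves the same divergence-form (Fickian) equations as the grid
#' solver:
#' `dY = (Phi(Y) + div_Y D_y(Y)) dt + sqrt(2 D_y) dW`, mirrored at the
#' boundaries, and analogously in space with taxis drift read from frozen
#' environment fields (one-way coupling). The `div D` drift correction makes
#' the Ito particle law match Fickian diffusion for state-dependent
#' diffusivity. Optional birth/death acts multiplicatively on particle
#' weights via the same proliferation and kill profiles as the solver.
#'
#' @param config scenario configuration (validated as in [runSimulation()]).
#'   The environment fields are frozen at their initial condition.
#' @param nParticles number of particles (>= 1).
#' @param seed integer seed; runs are reproducible for a fixed seed.
#' @param dt time step in days (default 0.02).
#' @param horizon end time in days (defaults to `config$run$horizon`).
#' @param sources include proliferation/kill weight dynamics (default FALSE:
#'   pure transport, matching a transport-only solver run).
#'
#' @return A [ParticleEnsemble-class] at the horizon.
#' @export
simulateParticles <- function(config = list(), nParticles = 10000L,
                              seed = 1L, dt = 0.02, horizon = NULL,
                              sources = FALSE) {
  config <- validateConfig(config)
  grid <- buildGrids(config$grid$n_spatial, config$grid$n_structural,
                     config$grid$spatial_side, config$grid$structural_side)
  atlas <- atlasFromConfig(config, grid)
  params <- paramsFromConfig(config)
  if (is.null(horizon)) horizon <- config$run$horizon
  stopifnot(nParticles >= 1)
  dtMax <- 0.25 / max(params@structural$k_adv, 1e-12)
  if (dt > dtMax)
    stop("refused: dt ", dt, " above the advection stability bound ",
         signif(dtMax, 3), call. = FALSE)

  set.seed(as.integer(seed))
  ic <- config$initial_condition
  extY <- grid@structuralExtent; extX <- grid@spatialExtent
  st0 <- initialState(grid, atlas, params, ic)

  # particles start from the solver's initial law: sample a 4D grid cell with
  # probability proportional to its mass and place the particle at the cell
  # center (the finite-volume state is mass at cell centers, so at t = 0 the
  # two representations agree exactly and the oracle isolates the dynamics)
  nx <- grid@nSpatial; ny <- grid@nStructural
  cellId <- sample.int(length(st0@c), nParticles, replace = TRUE,
                       prob = as.vector(st0@c))
  cellId <- cellId - 1L
  i1 <- cellId %% nx; r <- cellId %/% nx
  i2 <- r %% nx; r <- r %/% nx
  k1 <- r %% ny; k2 <- r %/% ny
  hx <- grid@dxSpatial; hy <- grid@dxStructural
  pos <- cbind(extX[1] + (i1 + 0.5) * hx,
               extX[1] + (i2 + 0.5) * hx)
  sta <- cbind(extY[1] + (k1 + 0.5) * hy,
               extY[1] + (k2 + 0.5) * hy)
  w <- rep(1, nParticles)

  # frozen environment: taxis drift and volume-filling from the initial state
  rm(cellId, i1, i2, k1, k2, r)
  rho0 <- totalSpatialDensity(st0@c, grid)
  sp <- params@spatial
  hx <- grid@dxSpatial
  gradC <- function(f) {
    nx <- nrow(f)
    gx <- (f[c(2:nx, nx), ] - f[c(1, 1:(nx - 1)), ]) /
      (hx * ifelse(row(f) %in% c(1, nx), 1, 2))
    gy <- (f[, c(2:nx, nx)] - f[, c(1, 1:(nx - 1))]) /
      (hx * ifelse(col(f) %in% c(1, nx), 1, 2))
    list(gx = gx, gy = gy)
  }
  gn <- gradC(st0@n); gv <- gradC(st0@v)
  driftX1 <- sp$chi_n * gn$gx + sp$chi_v * gv$gx
  driftX2 <- sp$chi_n * gn$gy + sp$chi_v * gv$gy
  volFac <- pmax(1 - rho0 / sp$rho_max, 0)
  DxEff <- if (identical(sp$volume_filling, "taxis")) {
    matrix(sp$D_x, nrow(rho0), ncol(rho0))
  } else sp$D_x * volFac

  cellIdx <- function(x) pmin(pmax(ceiling(normCoord(x, extX) *
                                             grid@nSpatial), 1L),
                              grid@nSpatial)
  eps <- 1e-4 * diff(extY)
  nSteps <- ceiling(horizon / dt)
  dtLast <- horizon - (nSteps - 1) * dt
  for (s in seq_len(nSteps)) {
    h <- if (s == nSteps) dtLast else dt
    if (h <= 0) break
    ## structural step
    drift <- advectionField(sta, atlas, params)
    # divergence-of-D correction, by central differencing of the profiles
    y1p <- cbind(pmin(sta[, 1] + eps, extY[2]), sta[, 2])
    y1m <- cbind(pmax(sta[, 1] - eps, extY[1]), sta[, 2])
    dDh <- (structuralDiffusivity(y1p, params, extY)[, 1] -
              structuralDiffusivity(y1m, params, extY)[, 1]) /
      (y1p[, 1] - y1m[, 1])
    y2p <- cbind(sta[, 1], pmin(sta[, 2] + eps, extY[2]))
    y2m <- cbind(sta[, 1], pmax(sta[, 2] - eps, extY[1]))
    dDv <- (structuralDiffusivity(y2p, params, extY)[, 2] -
              structuralDiffusivity(y2m, params, extY)[, 2]) /
      (y2p[, 2] - y2m[, 2])
    D <- structuralDiffusivity(sta, params, extY)
    sta[, 1] <- sta[, 1] + (drift[, 1] + dDh) * h +
      sqrt(2 * D[, 1] * h) * rnorm(nParticles)
    sta[, 2] <- sta[, 2] + (drift[, 2] + dDv) * h +
      sqrt(2 * D[, 2] * h) * rnorm(nParticles)
    sta[, 1] <- reflectInto(sta[, 1], extY[1], extY[2])
    sta[, 2] <- reflectInto(sta[, 2], extY[1], extY[2])
    ## spatial step (frozen fields)
    i1 <- cellIdx(pos[, 1]); i2 <- cellIdx(pos[, 2])
    lin <- cbind(i1, i2)
    Dx <- DxEff[lin]
    pos[, 1] <- pos[, 1] + driftX1[lin] * h + sqrt(2 * Dx * h) * rnorm(nParticles)
    pos[, 2] <- pos[, 2] + driftX2[lin] * h + sqrt(2 * Dx * h) * rnorm(nParticles)
    pos[, 1] <- reflectInto(pos[, 1], extX[1], extX[2])
    pos[, 2] <- reflectInto(pos[, 2], extX[1], extX[2])
    ## birth/death on weights
    if (sources) {
      P <- proliferationProfile(sta, atlas, params)
      g <- st0@n[lin] / (params@source$n_half + st0@n[lin])
      rate <- P * g * volFac[lin]
      w <- w * exp(rate * h)
    }
  }
  new("ParticleEnsemble", positions = pos, states = sta, weights = w,
      seed = as.integer(seed), t = horizon)
}

#' Total-variation distance between a particle ensemble and a grid density
#'
#' Histograms the weighted ensemble on the 4D grid, normalizes both the
#' histogram and the grid density to probability distributions, and returns
#' their total-variation distance (in `[0, 1]`; 0 for identical, 1 for
#' disjoint distributions).
#'
#' @param ensemble a [ParticleEnsemble-class].
#' @param pdeDensity 4D density array matching `grid`.
#' @param grid a [GridSpec-class].
#' @return scalar in `[0, 1]`.
#' @export
densityDistance <- function(ensemble, pdeDensity, grid) {
  W <- sum(ensemble@weights)
  M <- sum(pdeDensity)
  if (W <= 0 || M <= 0)
    stop("undefined distance: zero total weight or mass", call. = FALSE)
  nx <- grid@nSpatial; ny <- grid@nStructural
  binX <- function(x) pmin(pmax(ceiling(normCoord(x, grid@spatialExtent) * nx),
                                1L), nx)
  binY <- function(y) pmin(pmax(ceiling(normCoord(y, grid@structuralExtent) *
                                          ny), 1L), ny)
  hist4 <- weightedHist4D(binX(ensemble@positions[, 1]),
                          binX(ensemble@positions[, 2]),
                          binY(ensemble@states[, 1]),
                          binY(ensemble@states[, 2]),
                          ensemble@weights,
                          c(nx, nx, ny, ny))
  0.5 * sum(abs(hist4 / W - pdeDensity / M))
}

#' Canned oracle-agreement check
#'
#' Runs the transport-only reference verification instance (a coarse
#' 8^2 x 8^2 grid, drift + diffusion only) with both the grid solver and the
#' particle oracle and returns the total-variation distance between the two
#' at the horizon. This is the package's end-to-end solver verification.
#'
#' @param seed integer seed for the particle simulation.
#' @param nParticles ensemble size (default 2e5).
#' @param horizon days (default 5).
#' @return list with `tv` (the distance), `trajectory`, `ensemble`.
#' @export
verifyOracle <- function(seed = 1L, nParticles = 2e5, horizon = 5) {
  cfg <- oracleConfig(horizon)
  tr <- runSimulation(cfg)
  grid <- buildGrids(cfg$grid$n_spatial, cfg$grid$n_structural)
  ens <- simulateParticles(cfg, nParticles = nParticles, seed = seed,
                           dt = 0.02, horizon = horizon)
  final <- tr@snapshots[[length(tr@snapshots)]]
  list(tv = densityDistance(ens, final@c, grid), trajectory = tr,
       ensemble = ens)
}

# Transport-only verification scenario: no sources, no treatment, no taxis.
# Structural diffusion is moderate so the state distribution stays resolvable
# on the coarse grid; the spatial blob is kept compact and slowly diffusing so
# the Monte Carlo histogram noise over the 4D bins stays small at the
# reference ensemble size. The limited (minmod) advection scheme keeps the
# scheme's numerical diffusion below the physical diffusivity at this
# resolution.
oracleConfig <- function(horizon = 5) {
  list(
    grid = list(n_spatial = 8, n_structural = 8),
    structural_fluxes = list(k_adv = 0.05, d_h_min = 1e-3, d_h_max = 3e-3,
                             d_v_min = 1e-3, d_v_max = 3e-3,
                             advection_scheme = "minmod"),
    spatial_fluxes = list(D_x = 2e-4, chi_n = 0, chi_v = 0),
    source = list(p_max = 0),
    response = list(delta_B = 0, delta_H = 0),
    treatment = list(mode = "none"),
    initial_condition = list(spatial_sigma = 0.10, structural_sigma = 0.15,
                             spatial_center = c(0.5, 0.5),
                             structural_center = c(0.5, 0.5),
                             peak_density = 0.02),
    run = list(horizon = horizon, snapshot_interval = max(1, horizon))
  )
}
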