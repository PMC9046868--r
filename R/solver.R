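#' Proliferation profile over the structural plane
#'
#' `P(y) = p_max * G(y; y_prolif, sigma_P) * (1 - smc_suppression *
#' G(y; y_SMC, sigma_S))`: proliferation peaks at the proliferative state and
#' is suppressed around the minimally mitotic starved-like (SMC) state; the
#' suppression bump is wide enough to cover the treatment-induced northern
#' states (pigmented, NCSC), which proliferate slowly.
#'
#' @inheritParams drugResponse
#' @return numeric vector of rates (1/day).
#' @export
proliferationProfile <- function(y, atlas, params) {
  y <- rbind2cols(y)
  s <- params@source
  s$p_max * gaussBump(y, anchorPosition(atlas, "proliferative"), s$sigma_P) *
    (1 - s$smc_suppression *
       gaussBump(y, anchorPosition(atlas, "SMC"), s$sigma_S))
}

# structural-plane profiles evaluated on the grid (ny x ny matrices)
structuralProfiles <- function(grid, atlas, params) {
  yc <- structuralCenters(grid)
  ny <- grid@nStructural
  pts <- cbind(rep(yc, times = ny), rep(yc, each = ny))
  list(
    P = matrix(proliferationProfile(pts, atlas, params), ny, ny),
    psiB = matrix(drugResponse(pts, "BRAF_MEKi", atlas, params), ny, ny),
    psiH = matrix(drugResponse(pts, "HCT", atlas, params), ny, ny)
  )
}

# total spatial cell density: structural quadrature of the 4D density
totalSpatialDensity <- function(c4, grid) {
  nx <- grid@nSpatial
  m <- matrix(rowSums(matrix(c4, nx * nx, grid@nStructural^2)), nx, nx)
  m * grid@dxStructural^2
}

#' Proliferation and drug-kill source term
#'
#' `S = P(y) g(n(x)) (1 - rho/rho_max)_+ c  -  sum_i delta_i psi_i(y) w_i(x) c`
#' with Michaelis-Menten nutrient limitation `g(n) = n / (n_half + n)`.
#' Treatment is the only cause of active cell death: with both drugs absent
#' the source is nonnegative everywhere.
#'
#' @param c4 4D density array (nx, nx, ny, ny), nonnegative.
#' @param n,wB,wH nx x nx nutrient and drug fields.
#' @param grid a [GridSpec-class].
#' @param atlas a [SubpopulationAtlas-class].
#' @param params a [ModelParams-class].
#' @param rho optional precomputed total spatial density.
#'
#' @return 4D array of time-derivative contributions.
#' @export
reactionSource <- function(c4, n, wB, wH, grid, atlas, params, rho = NULL) {
  if (any(c4 < 0) || any(n < 0) || any(wB < 0) || any(wH < 0))
    stop("contract violation: negative inputs", call. = FALSE)
  if (is.null(rho)) rho <- totalSpatialDensity(c4, grid)
  pr <- structuralProfiles(grid, atlas, params)
  s <- params@source; r <- params@response
  nxx <- grid@nSpatial^2
  grow <- (n / (s$n_half + n)) * pmax(1 - rho / params@spatial$rho_max, 0)
  killB <- r$delta_B * wB
  killH <- r$delta_H * wH
  # broadcast: spatial factors recycle along the flattened 4D array; the
  # structural profiles are expanded once per structural cell
  cv <- as.vector(c4)
  out <- cv * as.vector(grow) * rep(as.vector(pr$P), each = nxx) -
    cv * as.vector(killB) * rep(as.vector(pr$psiB), each = nxx) -
    cv * as.vector(killH) * rep(as.vector(pr$psiH), each = nxx)
  array(out, dim = dim(c4))
}

#' Largest stable explicit time step
#'
#' Positivity/stability bound for the explicit scheme: `safety` divided by
#' the sum over axes of `2 D / h^2` (diffusion) and `|u|_max / h` (advection)
#' plus the fastest linear reaction/decay rate, evaluated from conservative
#' characteristic scales of the fields (drug at its dosing equilibrium, acid
#' and nutrient at their capacity scales). This sum form implies each of the
#' individual bounds `h^2/(4 D)`, `h/|u|` and `1/rate`.
#'
#' @param params a [ModelParams-class].
#' @param grid a [GridSpec-class].
#' @param safety factor in (0, 1].
#' @param maxDt upper cap returned when all rates are zero (days).
#' @param doseMax largest administration rate of the scenario
#'   (concentration/day), used for the drug-kill rate scale.
#'
#' @return time step in days.
#' @export
stableDt <- function(params, grid, safety = 0.9, maxDt = 0.25, doseMax = 1) {
  stopifnot(safety > 0, safety <= 1)
  st <- params@structural; sp <- params@spatial
  e <- params@environment; r <- params@response; so <- params@source
  hx <- grid@dxSpatial; hy <- grid@dxStructural
  extS <- grid@structuralExtent; extX <- grid@spatialExtent

  # advection: structural pull toward the attractor line; taxis bounded by
  # sensitivity times the field scale per domain length
  uStruct <- st$k_adv * diff(extS)
  nScale <- e$alpha_n * e$v_max / max(e$lam_n, 1e-12)
  uTaxis <- (sp$chi_n * nScale + sp$chi_v * e$v_max) / diff(extX) * 4

  # fastest linear rates seen by any field
  wScale <- doseMax / max(e$lam_w, 1e-12)
  rates <- c(e$r_v, e$lam_av * (e$alpha_a * sp$rho_max / max(e$lam_a, 1e-12)) +
               e$lam_v,
             e$beta_n * sp$rho_max + e$lam_n, e$lam_a,
             e$lam_w + e$eps_w * sp$rho_max,
             so$p_max, (r$delta_B + r$delta_H) * wScale)
  denom <- 2 * (st$d_h_max + st$d_v_max) / hy^2 +
    4 * max(sp$D_x, e$D_n, e$D_a, e$D_w) / hx^2 +
    uStruct / hy + 2 * uTaxis / hx + max(rates)
  if (denom <= 0) return(maxDt)
  min(safety / denom, maxDt)
}

# assemble the per-run context of precomputed, time-independent pieces
solverContext <- function(grid, atlas, params) {
  list(grid = grid, atlas = atlas, params = params,
       faces = structuralFaces(grid, atlas, params),
       profiles = structuralProfiles(grid, atlas, params),
       scheme = if (identical(params@structural$advection_scheme, "minmod"))
         1L else 0L)
}

# full right-hand side of all six fields
modelRhs <- function(st, dose, ctx) {
  grid <- ctx$grid; params <- ctx$params
  rho <- totalSpatialDensity(st$c, grid)
  sf <- spatialFaces(st$n, st$v, rho, grid, params)
  s <- params@source; r <- params@response; e <- params@environment
  grow <- (st$n / (s$n_half + st$n)) *
    pmax(1 - rho / params@spatial$rho_max, 0)
  dc <- cellRhs4D(st$c, dim(st$c),
                  sf$uxFace, sf$uyFace, sf$dxFace, sf$dyFace,
                  ctx$faces$u1Face, ctx$faces$dhFace, ctx$faces$dvFace,
                  ctx$profiles$P, ctx$profiles$psiB, ctx$profiles$psiH,
                  grow, r$delta_B * st$wB, r$delta_H * st$wH,
                  grid@dxSpatial, grid@dxSpatial,
                  grid@dxStructural, grid@dxStructural, ctx$scheme)
  env <- environmentRhs(st$v, st$n, st$a, st$wB, st$wH, rho, dose, grid, params)
  list(dc = dc, dv = env$dv, dn = env$dn, da = env$da,
       dwB = env$dwB, dwH = env$dwH)
}

# clip tiny negatives, returning the clipped cell mass for the audit log
clipFields <- function(st, grid) {
  clipped <- 0
  neg <- st$c < 0
  if (any(neg)) {
    clipped <- -sum(st$c[neg]) * cellVolume4D(grid)
    st$c[neg] <- 0
  }
  for (nm in c("v", "n", "a", "wB", "wH")) st[[nm]][st[[nm]] < 0] <- 0
  st$clipped <- clipped
  st
}

.stateToList <- function(state) {
  list(c = state@c, v = state@v, n = state@n, a = state@a,
       wB = state@wB, wH = state@wH)
}

#' Advance the full state by one explicit Heun step
#'
#' Second-order two-stage (Heun) step of all six coupled fields: spatial and
#' structural transport, reaction source and environment dynamics, with the
#' dose rates taken from the schedule at the start and end of the step.
#' Negative values produced by the step are clipped to zero; the clipped cell
#' mass is returned for auditing.
#'
#' @param state a [FieldState-class].
#' @param dt time step (days), at most [stableDt()].
#' @param grid,atlas,params model setup.
#' @param schedule a [TreatmentSchedule-class].
#' @param context optional precomputed solver context (internal fast path).
#'
#' @return A [FieldState-class] at `t + dt`, with attribute `clippedMass`.
#' @export
stepState <- function(state, dt, grid, atlas, params, schedule,
                      context = NULL) {
  ctx <- if (is.null(context)) solverContext(grid, atlas, params) else context
  new <- stepCore(.stateToList(state), state@t, state@treatmentOn, dt, ctx,
                  schedule)
  out <- new("FieldState", t = state@t + dt, c = new$c,
             v = new$v, n = new$n, a = new$a, wB = new$wB, wH = new$wH,
             treatmentOn = state@treatmentOn)
  attr(out, "clippedMass") <- new$clipped
  out
}

# the Heun step on plain field lists (the hot path; S4 construction and
# validity checking happen only at snapshot time)
stepCore <- function(st, t, treatmentOn, dt, ctx, schedule) {
  dose1 <- doseSchedule(t, schedule, treatmentOn)
  dose2 <- doseSchedule(t + dt, schedule, treatmentOn)
  k1 <- modelRhs(st, dose1, ctx)
  pred <- list(c = st$c + dt * k1$dc, v = st$v + dt * k1$dv,
               n = st$n + dt * k1$dn, a = st$a + dt * k1$da,
               wB = st$wB + dt * k1$dwB, wH = st$wH + dt * k1$dwH)
  pred <- clipFields(pred, ctx$grid)
  k2 <- modelRhs(pred, dose2, ctx)
  new <- list(c = st$c + dt / 2 * (k1$dc + k2$dc),
              v = st$v + dt / 2 * (k1$dv + k2$dv),
              n = st$n + dt / 2 * (k1$dn + k2$dn),
              a = st$a + dt / 2 * (k1$da + k2$da),
              wB = st$wB + dt / 2 * (k1$dwB + k2$dwB),
              wH = st$wH + dt / 2 * (k1$dwH + k2$dwH))
  new <- clipFields(new, ctx$grid)
  cm <- sum(new$c)
  if (!is.finite(cm) ||
      !all(is.finite(new$v)) || !all(is.finite(new$n)) ||
      !all(is.finite(new$a)) || !all(is.finite(new$wB)) ||
      !all(is.finite(new$wH))) {
    bad <- names(new)[vapply(new[1:6], function(f) any(!is.finite(f)),
                             logical(1))]
    stop("integration failure: non-finite values in field(s) ",
         paste(bad, collapse = ", "), " at t = ", t + dt, call. = FALSE)
  }
  new$mass <- cm
  new
}

#' Initial condition: a naive tumor
#'
#' Spatial Gaussian tumor profile times a structural Gaussian centered at the
#' proliferative anchor (the drug-sensitive melanocytic state). The ECNE
#' starts partially consumed under the tumor, nutrient at its ECNE/cell
#' equilibrium, acid and drugs at zero.
#'
#' @param grid,atlas,params model setup.
#' @param ic list of initial-condition settings: `spatial_sigma`,
#'   `structural_sigma`, `spatial_center` (length 2), `peak_density`
#'   (peak of the initial total spatial density, as a fraction of `rho_max`)
#'   and `ecne_dip` (fractional ECNE depletion under the tumor peak).
#'
#' @return A [FieldState-class] at `t = 0`.
#' @export
initialState <- function(grid, atlas, params,
                         ic = list(spatial_sigma = 0.1,
                                   structural_sigma = 0.06,
                                   spatial_center = c(0.5, 0.5),
                                   peak_density = 0.25,
                                   ecne_dip = 0.5)) {
  nx <- grid@nSpatial; ny <- grid@nStructural
  # cell-averaged Gaussian factors (exact finite-volume initial condition):
  # per-axis average over each cell via normal CDF differences
  cellAvgGauss <- function(nCells, h, lo, mu, sigma) {
    edges <- lo + (0:nCells) * h
    (stats::pnorm((edges[-1] - mu) / sigma) -
       stats::pnorm((edges[-(nCells + 1)] - mu) / sigma)) / h
  }
  fx1 <- cellAvgGauss(nx, grid@dxSpatial, grid@spatialExtent[1],
                      ic$spatial_center[1], ic$spatial_sigma)
  fx2 <- cellAvgGauss(nx, grid@dxSpatial, grid@spatialExtent[1],
                      ic$spatial_center[2], ic$spatial_sigma)
  spatial <- outer(fx1, fx2)
  spatial <- spatial / max(spatial)  # normalized tumor profile, peak 1
  y0 <- if (!is.null(ic$structural_center)) ic$structural_center
        else anchorPosition(atlas, "proliferative")
  fy1 <- cellAvgGauss(ny, grid@dxStructural, grid@structuralExtent[1],
                      y0[1], ic$structural_sigma)
  fy2 <- cellAvgGauss(ny, grid@dxStructural, grid@structuralExtent[1],
                      y0[2], ic$structural_sigma)
  struct <- outer(fy1, fy2)
  struct <- struct / max(struct)
  # normalize so the peak total spatial density is peak_density * rho_max
  structMass <- sum(struct) * grid@dxStructural^2
  amp <- ic$peak_density * params@spatial$rho_max / structMass
  c4 <- array(outer(as.vector(spatial * amp), as.vector(struct)),
              dim = c(nx, nx, ny, ny))
  rho <- totalSpatialDensity(c4, grid)
  e <- params@environment
  v <- e$v_max * (1 - ic$ecne_dip * spatial)
  n <- e$alpha_n * v / (e$beta_n * rho + e$lam_n)
  zero <- matrix(0, nx, nx)
  new("FieldState", t = 0, c = c4, v = v, n = n, a = zero,
      wB = zero, wH = zero, treatmentOn = FALSE)
}

#' Run a full simulation scenario
#'
#' Builds grids, atlas, parameters and schedule from a validated
#' configuration (see [loadConfig()] and [scenarioPreset()]), integrates from
#' `t = 0` to the horizon with adaptive treatment decisions at the configured
#' cadence, and records the burden at every step plus full-field snapshots at
#' the snapshot cadence. The run is fully deterministic.
#'
#' @param config configuration list (raw lists are validated first).
#' @param quiet suppress the per-run log line.
#'
#' @return A [Trajectory-class].
#' @examples
#' \donttest{
#' cfg <- scenarioPreset("continuous-braf")
#' cfg$grid$n_spatial <- 8; cfg$grid$n_structural <- 8; cfg$run$horizon <- 5
#' tr <- runSimulation(cfg)
#' }
#' @export
runSimulation <- function(config = list(), quiet = TRUE) {
  config <- validateConfig(config)
  grid <- buildGrids(config$grid$n_spatial, config$grid$n_structural,
                     config$grid$spatial_side, config$grid$structural_side)
  atlas <- atlasFromConfig(config, grid)
  params <- paramsFromConfig(config)
  schedule <- scheduleFromConfig(config)
  ctx <- solverContext(grid, atlas, params)

  run <- config$run
  doseMax <- max(schedule@doseRate, 0)
  dtS <- stableDt(params, grid, safety = run$dt_safety, maxDt = run$max_dt,
                  doseMax = if (schedule@mode == "none") 0 else doseMax)
  if (dtS < run$min_dt)
    stop("configuration refused: stable time step ", signif(dtS, 3),
         " below the minimum allowed ", run$min_dt, call. = FALSE)
  # integer number of steps per day keeps daily adaptive decisions and
  # snapshot times exact
  stepsPerDay <- max(1L, as.integer(ceiling(1 / dtS)))
  dt <- 1 / stepsPerDay
  horizon <- as.integer(run$horizon)
  nRec <- horizon * stepsPerDay + 1L

  state0 <- initialState(grid, atlas, params, config$initial_condition)
  st <- .stateToList(state0)
  tNow <- 0
  treatOn <- FALSE
  vol <- cellVolume4D(grid)
  times <- numeric(nRec); mass <- numeric(nRec)
  doseB <- numeric(nRec); doseH <- numeric(nRec)
  onRec <- numeric(nRec); clipRec <- numeric(nRec)
  snaps <- list(); snapTimes <- numeric(0)

  recAt <- function(i, clip) {
    times[i] <<- tNow
    mass[i] <<- sum(st$c) * vol
    d <- doseSchedule(tNow, schedule, treatOn)
    doseB[i] <<- d[["BRAF_MEKi"]]; doseH[i] <<- d[["HCT"]]
    onRec[i] <<- as.numeric(sum(d) > 0)
    clipRec[i] <<- clip
  }

  massAtStart <- NA_real_
  rec <- 1L
  recAt(rec, 0)
  if (abs(schedule@startTime) < 1e-9) massAtStart <- mass[1]
  snaps[[1]] <- state0; snapTimes <- 0

  if (!quiet)
    message("melanosim: ", schedule@mode, " run, dt = ", signif(dt, 4),
            " (", stepsPerDay, " steps/day), horizon ", horizon, " days")

  asFieldState <- function() {
    new("FieldState", t = tNow, c = st$c, v = st$v, n = st$n, a = st$a,
        wB = st$wB, wH = st$wH, treatmentOn = treatOn)
  }

  for (day in seq_len(horizon) - 1L) {
    # adaptive decision at the start of each decision interval
    if (schedule@mode == "adaptive" &&
        day + 1e-9 >= schedule@startTime &&
        (day - schedule@startTime) %% schedule@decisionInterval < 1e-9) {
      if (is.na(massAtStart)) massAtStart <- mass[rec]
      treatOn <- adaptiveDecision(mass[rec], massAtStart, treatOn, schedule)
    } else if (is.na(massAtStart) && day + 1 >= schedule@startTime) {
      massAtStart <- mass[rec]
    }
    for (s in seq_len(stepsPerDay)) {
      st <- stepCore(st, tNow, treatOn, dt, ctx, schedule)
      tNow <- tNow + dt
      rec <- rec + 1L
      times[rec] <- tNow
      mass[rec] <- st$mass * vol
      d <- doseSchedule(tNow, schedule, treatOn)
      doseB[rec] <- d[["BRAF_MEKi"]]; doseH[rec] <- d[["HCT"]]
      onRec[rec] <- as.numeric(sum(d) > 0)
      clipRec[rec] <- st$clipped
    }
    tNow <- round(tNow * stepsPerDay) / stepsPerDay  # keep day ticks exact
    if ((day + 1L) %% as.integer(run$snapshot_interval) == 0L) {
      snaps[[length(snaps) + 1L]] <- asFieldState()
      snapTimes <- c(snapTimes, tNow)
    }
  }

  new("Trajectory",
      times = times, mass = mass, doseB = doseB, doseH = doseH,
      treatmentOn = onRec, clippedMass = clipRec,
      snapshots = snaps, snapshotTimes = snapTimes,
      config = config, configHash = configHash(config))
}

#' @describeIn runSimulation the recorded series as a data.frame with the
#'   fixed schema `t_day, total_mass, dose_B, dose_H, treatment_on`.
#' @param trajectory a [Trajectory-class].
#' @export
trajectorySeries <- function(trajectory) {
  data.frame(t_day = trajectory@times,
             total_mass = trajectory@mass,
             dose_B = trajectory@doseB,
             dose_H = trajectory@doseH,
             treatment_on = trajectory@treatmentOn)
}
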