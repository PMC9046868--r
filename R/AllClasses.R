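#' @useDynLib melanosim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods new validObject is slot
#' @importFrom stats setNames rnorm runif
#' @importFrom utils write.csv read.csv
NULL

#' Cell-centered finite-volume grids for the spatial and structural planes
#'
#' Both planes are square, uniform, cell-centered grids. The spatial plane
#' holds the tumor cross-section; the structural plane is the abstract 2D
#' cell-state ("gene-expression map") domain. All coordinates are
#' dimensionless; time is measured in days throughout the package.
#'
#' @slot nSpatial integer, cells per spatial axis (>= 4).
#' @slot nStructural integer, cells per structural axis (>= 4).
#' @slot spatialExtent numeric(2), (lo, hi) shared by both spatial axes.
#' @slot structuralExtent numeric(2), (lo, hi) shared by both structural axes.
#' @slot dxSpatial,dxStructural numeric, cell widths.
#' @slot spatialCenters,structuralCenters numeric, cell-center coordinates.
#'
#' @seealso [buildGrids()]
#' @export
setClass("GridSpec",
  slots = c(
    nSpatial = "integer",
    nStructural = "integer",
    spatialExtent = "numeric",
    structuralExtent = "numeric",
    dxSpatial = "numeric",
    dxStructural = "numeric",
    spatialCenters = "numeric",
    structuralCenters = "numeric"
  )
)

setValidity("GridSpec", function(object) {
  msgs <- character()
  if (length(object@nSpatial) != 1L || object@nSpatial < 4L)
    msgs <- c(msgs, "nSpatial must be a single integer >= 4")
  if (length(object@nStructural) != 1L || object@nStructural < 4L)
    msgs <- c(msgs, "nStructural must be a single integer >= 4")
  for (nm in c("spatialExtent", "structuralExtent")) {
    e <- slot(object, nm)
    if (length(e) != 2L || !all(is.finite(e)) || diff(e) <= 0)
      msgs <- c(msgs, paste(nm, "must be (lo, hi) with hi > lo"))
  }
  if (object@dxSpatial <= 0 || object@dxStructural <= 0)
    msgs <- c(msgs, "cell widths must be strictly positive")
  if (length(msgs)) msgs else TRUE
})

#' Atlas of the six melanoma cell-state subpopulations
#'
#' Holds the six named anchors (cardinal positions in the structural plane)
#' and the common radius of the closed discs that define each subpopulation's
#' structural subdomain. The discs are a partial cover: states between discs
#' are intermediate phenotypes and classify as `"unassigned"`.
#'
#' @slot anchors data.frame with columns `name`, `y1`, `y2` (one row per
#'   subpopulation: proliferative, invasive, pigmented, NCSC, SMC, URC).
#' @slot radius numeric, subdomain disc radius (structural length units).
#' @slot extent numeric(2), the structural extent the atlas lives on.
#'
#' @seealso [defaultAtlas()], [classifyState()]
#' @export
setClass("SubpopulationAtlas",
  slots = c(anchors = "data.frame", radius = "numeric", extent = "numeric")
)

setValidity("SubpopulationAtlas", function(object) {
  a <- object@anchors
  msgs <- character()
  if (!all(c("name", "y1", "y2") %in% names(a)))
    msgs <- c(msgs, "anchors must have columns name, y1, y2")
  else {
    if (nrow(a) != 6L) msgs <- c(msgs, "exactly six anchors are required")
    if (anyDuplicated(a$name)) msgs <- c(msgs, "anchor names must be unique")
    e <- object@extent
    if (any(a$y1 < e[1] | a$y1 > e[2] | a$y2 < e[1] | a$y2 > e[2]))
      msgs <- c(msgs, "anchor positions must lie inside the structural extent")
    side <- diff(e)
    if (object@radius <= 0 || object@radius >= side / 2)
      msgs <- c(msgs, "radius must satisfy 0 < radius < half the extent side")
  }
  if (length(msgs)) msgs else TRUE
})

#' Model parameters (reference parameter set)
#'
#' Groups every rate constant and profile parameter of the model. Each slot
#' is a named numeric-ish list; [defaultParams()] documents the meaning,
#' units and default of every entry.
#'
#' @slot structural cell-state advection/diffusion parameters.
#' @slot spatial spatial motility parameters.
#' @slot environment ECNE / nutrient / acid / drug field parameters.
#' @slot response drug-response profile parameters.
#' @slot source proliferation profile parameters.
#'
#' @seealso [defaultParams()]
#' @export
setClass("ModelParams",
  slots = c(
    structural = "list",
    spatial = "list",
    environment = "list",
    response = "list",
    source = "list"
  )
)

.paramFields <- list(
  structural = c("k_adv", "d_h_min", "d_h_max", "d_v_min", "d_v_max"),
  spatial = c("D_x", "chi_n", "chi_v", "rho_max"),
  environment = c("r_v", "v_max", "lam_av", "lam_v", "D_n", "D_a", "D_w",
                  "alpha_n", "beta_n", "lam_n", "alpha_a", "lam_a",
                  "lam_w", "eps_w"),
  response = c("sigma_B", "w_inv", "att_depth", "sigma_att", "delta_B",
               "sigma_H", "delta_H"),
  source = c("p_max", "sigma_P", "smc_suppression", "sigma_S", "n_half")
)

setValidity("ModelParams", function(object) {
  msgs <- character()
  for (grp in names(.paramFields)) {
    vals <- slot(object, grp)
    missing <- setdiff(.paramFields[[grp]], names(vals))
    if (length(missing))
      msgs <- c(msgs, paste0(grp, ": missing parameter(s) ",
                             paste(missing, collapse = ", ")))
    num <- unlist(vals[intersect(names(vals), .paramFields[[grp]])])
    if (length(num) && (!is.numeric(num) || any(!is.finite(num)) || any(num < 0)))
      msgs <- c(msgs, paste0(grp, ": all parameters must be finite and nonnegative"))
  }
  s <- object@structural
  if (length(s) && !is.null(s$d_h_min) && !is.null(s$d_h_max) &&
      s$d_h_max < s$d_h_min)
    msgs <- c(msgs, "d_h_max must be >= d_h_min")
  if (length(s) && !is.null(s$d_v_min) && !is.null(s$d_v_max) &&
      s$d_v_max < s$d_v_min)
    msgs <- c(msgs, "d_v_max must be >= d_v_min")
  if (!is.null(object@spatial$rho_max) && object@spatial$rho_max <= 0)
    msgs <- c(msgs, "rho_max must be > 0")
  if (!is.null(object@environment$v_max) && object@environment$v_max <= 0)
    msgs <- c(msgs, "v_max must be > 0")
  if (!is.null(object@response$att_depth) &&
      (object@response$att_depth < 0 || object@response$att_depth > 1))
    msgs <- c(msgs, "att_depth must lie in [0, 1]")
  if (!is.null(object@source$smc_suppression) && object@source$smc_suppression > 1)
    msgs <- c(msgs, "smc_suppression must be <= 1")
  if (length(msgs)) msgs else TRUE
})

#' Treatment schedule
#'
#' Dosing policy: `"none"` (untreated), `"continuous"` (one drug without
#' interruption), `"sequential"` (first listed drug until `switchTime`, the
#' second thereafter) or `"adaptive"` (the first listed drug, switched on
#' above `upperThreshold * M0` and off below `lowerThreshold * M0`, with
#' hysteresis in between; decisions taken every `decisionInterval` days).
#' At most one drug is dosed at any time.
#'
#' @slot mode character, one of none/continuous/sequential/adaptive.
#' @slot drugOrder character vector over `"BRAF_MEKi"`, `"HCT"`.
#' @slot switchTime numeric day (sequential only).
#' @slot doseRate named numeric, administration rate per drug
#'   (concentration/day) while ON.
#' @slot decisionInterval numeric days (adaptive).
#' @slot lowerThreshold,upperThreshold numeric fractions of the burden at
#'   treatment start (adaptive).
#' @slot startTime numeric day treatment begins.
#'
#' @seealso [treatmentSchedule()], [doseSchedule()], [adaptiveDecision()]
#' @export
setClass("TreatmentSchedule",
  slots = c(
    mode = "character",
    drugOrder = "character",
    switchTime = "numeric",
    doseRate = "numeric",
    decisionInterval = "numeric",
    lowerThreshold = "numeric",
    upperThreshold = "numeric",
    startTime = "numeric"
  )
)

setValidity("TreatmentSchedule", function(object) {
  msgs <- character()
  if (!object@mode %in% c("none", "continuous", "sequential", "adaptive"))
    msgs <- c(msgs, "mode must be none, continuous, sequential or adaptive")
  if (!all(object@drugOrder %in% c("BRAF_MEKi", "HCT")))
    msgs <- c(msgs, "drugOrder entries must be BRAF_MEKi or HCT")
  if (object@mode %in% c("continuous", "adaptive") && length(object@drugOrder) < 1L)
    msgs <- c(msgs, paste0(object@mode, " mode requires one drug in drugOrder"))
  if (object@mode == "sequential") {
    if (length(object@drugOrder) < 2L)
      msgs <- c(msgs, "sequential mode requires two drugs in drugOrder")
    if (!length(object@switchTime) || object@switchTime <= object@startTime)
      msgs <- c(msgs, "switchTime must exceed startTime for sequential mode")
  }
  if (object@mode == "adaptive") {
    if (object@decisionInterval <= 0)
      msgs <- c(msgs, "decisionInterval must be > 0")
    if (!(object@lowerThreshold > 0 &&
          object@lowerThreshold < object@upperThreshold))
      msgs <- c(msgs, "need 0 < lowerThreshold < upperThreshold")
  }
  if (any(object@doseRate < 0)) msgs <- c(msgs, "dose rates must be nonnegative")
  if (object@startTime < 0) msgs <- c(msgs, "startTime must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Full simulation state at one time
#'
#' @slot t numeric, time in days.
#' @slot c 4D array (nx, nx, ny, ny): cell density over space x state.
#' @slot v,n,a,wB,wH matrices (nx, nx): ECNE, nutrient, acid and the two
#'   drug concentration fields.
#' @slot treatmentOn logical, current adaptive on/off state.
#'
#' @export
setClass("FieldState",
  slots = c(
    t = "numeric", c = "array",
    v = "matrix", n = "matrix", a = "matrix",
    wB = "matrix", wH = "matrix",
    treatmentOn = "logical"
  )
)

setValidity("FieldState", function(object) {
  msgs <- character()
  flds <- list(c = object@c, v = object@v, n = object@n, a = object@a,
               wB = object@wB, wH = object@wH)
  for (nm in names(flds)) {
    f <- flds[[nm]]
    if (any(!is.finite(f))) msgs <- c(msgs, paste0(nm, " has non-finite values"))
    else if (any(f < 0)) msgs <- c(msgs, paste0(nm, " has negative values"))
  }
  if (length(dim(object@c)) != 4L) msgs <- c(msgs, "c must be a 4D array")
  if (length(msgs)) msgs else TRUE
})

#' Recorded trajectory of a simulation run
#'
#' @slot times numeric, strictly increasing times (days) of the mass series.
#' @slot mass numeric, total tumor burden at `times`.
#' @slot doseB,doseH numeric, administration rate of each drug at `times`.
#' @slot treatmentOn numeric 0/1, dosing state at `times`.
#' @slot clippedMass numeric, cell mass removed by negativity clipping per
#'   recorded step (audit trail of the positivity fix-up).
#' @slot snapshots list of [FieldState-class] at `snapshotTimes`.
#' @slot snapshotTimes numeric, subset of `times`.
#' @slot config list, the fully validated configuration that produced the run.
#' @slot configHash character, provenance hash of `config`.
#'
#' @export
setClass("Trajectory",
  slots = c(
    times = "numeric", mass = "numeric",
    doseB = "numeric", doseH = "numeric", treatmentOn = "numeric",
    clippedMass = "numeric",
    snapshots = "list", snapshotTimes = "numeric",
    config = "list", configHash = "character"
  )
)

setValidity("Trajectory", function(object) {
  msgs <- character()
  if (length(object@times) > 1L && any(diff(object@times) <= 0))
    msgs <- c(msgs, "times must be strictly increasing")
  if (any(object@mass < 0)) msgs <- c(msgs, "mass must be nonnegative")
  nT <- length(object@times)
  for (nm in c("mass", "doseB", "doseH", "treatmentOn", "clippedMass"))
    if (length(slot(object, nm)) != nT)
      msgs <- c(msgs, paste0(nm, " must align with times"))
  if (length(object@snapshots) != length(object@snapshotTimes))
    msgs <- c(msgs, "snapshots and snapshotTimes must align")
  if (length(object@snapshotTimes) &&
      !all(vapply(object@snapshotTimes,
                  function(t) any(abs(object@times - t) < 1e-9), logical(1))))
    msgs <- c(msgs, "snapshot times must be a subset of times")
  if (length(msgs)) msgs else TRUE
})

#' Derived metrics of a trajectory
#'
#' @slot timeToResistance numeric day, or `NA_real_` if the burden never
#'   regains its pre-treatment value within the horizon.
#' @slot phases data.frame with columns `label` (shrink/MRD/regrow),
#'   `start`, `end` (days).
#' @slot varianceSeries data.frame `t`, `variance` (structural variance).
#' @slot modeCountSeries data.frame `t`, `modes`.
#' @slot fractionSeries data.frame: `t` plus one column per subpopulation
#'   and `unassigned`.
#' @slot zoningOverlap symmetric 6x6 matrix of spatial cosine overlaps of the
#'   subpopulation density fields at the final snapshot.
#' @slot zonationIndex numeric in `[0, 1]`; 1 - mean off-diagonal overlap.
#'
#' @export
setClass("MetricsReport",
  slots = c(
    timeToResistance = "numeric",
    phases = "data.frame",
    varianceSeries = "data.frame",
    modeCountSeries = "data.frame",
    fractionSeries = "data.frame",
    zoningOverlap = "matrix",
    zonationIndex = "numeric"
  )
)

#' Monte Carlo particle ensemble
#'
#' The stochastic-process counterpart of the continuity equation, used as an
#' independent verification oracle for the grid solver.
#'
#' @slot positions n x 2 matrix of spatial positions.
#' @slot states n x 2 matrix of structural states.
#' @slot weights numeric, nonnegative per-particle weights.
#' @slot seed integer seed the ensemble was generated from.
#' @slot t numeric, time in days.
#'
#' @seealso [simulateParticles()], [densityDistance()]
#' @export
setClass("ParticleEnsemble",
  slots = c(
    positions = "matrix", states = "matrix", weights = "numeric",
    seed = "integer", t = "numeric"
  )
)

setValidity("ParticleEnsemble", function(object) {
  msgs <- character()
  if (ncol(object@positions) != 2L || ncol(object@states) != 2L)
    msgs <- c(msgs, "positions and states must have two columns")
  if (nrow(object@positions) != nrow(object@states) ||
      nrow(object@positions) != length(object@weights))
    msgs <- c(msgs, "positions, states and weights must align")
  if (any(object@weights < 0)) msgs <- c(msgs, "weights must be nonnegative")
  if (length(msgs)) msgs else TRUE
})

# ---- show methods ----------------------------------------------------------

setMethod("show", "GridSpec", function(object) {
  cat("GridSpec:", object@nSpatial, "^2 spatial x",
      object@nStructural, "^2 structural cells\n")
  cat("  spatial extent   [", object@spatialExtent[1], ",",
      object@spatialExtent[2], "], h =", signif(object@dxSpatial, 4), "\n")
  cat("  structural extent[", object@structuralExtent[1], ",",
      object@structuralExtent[2], "], h =", signif(object@dxStructural, 4), "\n")
})

setMethod("show", "SubpopulationAtlas", function(object) {
  cat("SubpopulationAtlas: 6 anchors, disc radius", object@radius, "\n")
  print(object@anchors, row.names = FALSE)
})

setMethod("show", "FieldState", function(object) {
  d <- dim(object@c)
  cat("FieldState at t =", object@t, "days;",
      "c:", paste(d, collapse = "x"),
      "; treatment", if (object@treatmentOn) "ON" else "OFF", "\n")
})

setMethod("show", "Trajectory", function(object) {
  cat("Trajectory:", length(object@times), "recorded times over",
      max(object@times), "days;", length(object@snapshots), "snapshots\n")
  cat("  mass:", signif(object@mass[1], 4), "->",
      signif(object@mass[length(object@mass)], 4),
      " (config ", object@configHash, ")\n", sep = "")
})

setMethod("show", "MetricsReport", function(object) {
  cat("MetricsReport\n")
  ttr <- object@timeToResistance
  cat("  time to resistance:",
      if (is.na(ttr)) "not reached" else paste(signif(ttr, 4), "days"), "\n")
  if (nrow(object@phases)) {
    cat("  phases:", paste(sprintf("%s[%g,%g]", object@phases$label,
                                   signif(object@phases$start, 4),
                                   signif(object@phases$end, 4)),
                           collapse = " "), "\n")
  }
  cat("  zonation index:", signif(object@zonationIndex, 4), "\n")
})

setMethod("show", "ParticleEnsemble", function(object) {
  cat("ParticleEnsemble:", nrow(object@positions), "particles at t =",
      object@t, "days (seed", object@seed, ")\n")
})
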