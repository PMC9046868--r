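# Configuration: a nested key tree (YAML on disk), validated against the
# versioned reference defaults. Unknown keys are rejected with the nearest
# valid name; missing keys are filled from the defaults.

#' The reference configuration
#'
#' Full nested default configuration: grid resolutions, atlas geography,
#' all model parameter groups, treatment schedule, initial condition and run
#' control. Every scenario is a (possibly empty) set of overrides of this
#' tree.
#'
#' @return nested named list.
#' @export
defaultConfig <- function() {
  p <- defaultParams()
  list(
    grid = list(n_spatial = 24L, n_structural = 24L,
                spatial_side = 1, structural_side = 1),
    atlas = list(
      radius = 0.15,
      anchors = list(proliferative = c(0.20, 0.20),
                     invasive = c(0.85, 0.50),
                     pigmented = c(0.20, 0.85),
                     NCSC = c(0.85, 0.85),
                     SMC = c(0.50, 0.90),
                     URC = c(0.80, 0.15))
    ),
    structural_fluxes = p@structural,
    spatial_fluxes = p@spatial,
    environment = p@environment,
    response = p@response,
    source = p@source,
    treatment = list(mode = "none",
                     drug_order = "BRAF_MEKi",
                     switch_time = 100,
                     dose_B = 1, dose_H = 1,
                     decision_interval = 1,
                     lower_threshold = 0.25,
                     upper_threshold = 0.5,
                     start_time = 0),
    initial_condition = list(spatial_sigma = 0.1,
                             structural_sigma = 0.06,
                             spatial_center = c(0.5, 0.5),
                             structural_center = NULL,
                             peak_density = 0.5,
                             ecne_dip = 0.5),
    run = list(horizon = 300, snapshot_interval = 5,
               dt_safety = 0.9, max_dt = 0.25, min_dt = 1e-5)
  )
}

# recursive merge of overrides into defaults, rejecting unknown keys
mergeConfig <- function(base, over, path = "") {
  if (is.null(over) || (is.list(over) && length(over) == 0L)) return(base)
  if (!is.list(over))
    stop("configuration error: '", path, "' must be a key group", call. = FALSE)
  keys <- names(over)
  if (is.null(keys) || any(keys == ""))
    stop("configuration error: unnamed entries under '", path, "'",
         call. = FALSE)
  for (k in keys) {
    full <- if (nzchar(path)) paste0(path, ".", k) else k
    if (!k %in% names(base)) {
      cand <- names(base)[order(utils::adist(k, names(base)))][1]
      stop("configuration error: unknown key '", full,
           "'; nearest valid name is '",
           if (nzchar(path)) paste0(path, ".", cand) else cand, "'",
           call. = FALSE)
    }
    if (is.list(base[[k]]) && !is.null(names(base[[k]]))) {
      base[[k]] <- mergeConfig(base[[k]], over[[k]], full)
    } else {
      # base[k] <- list(...) keeps keys whose override value is NULL
      base[k] <- list(over[[k]])
    }
  }
  base
}

#' Validate a configuration
#'
#' Merges a (partial) configuration into the reference defaults, rejecting
#' unknown keys (reporting the nearest valid name) and out-of-range values.
#' A validated configuration passes through unchanged, so validation is
#' idempotent.
#'
#' @param config nested list of overrides (may be empty).
#' @return the full validated configuration list.
#' @export
validateConfig <- function(config = list()) {
  cfg <- mergeConfig(defaultConfig(), config)
  # range checks beyond what the typed constructors enforce
  tr <- cfg$treatment
  if (!tr$mode %in% c("none", "continuous", "sequential", "adaptive"))
    stop("configuration error: treatment.mode must be one of ",
         "none/continuous/sequential/adaptive, got '", tr$mode, "'",
         call. = FALSE)
  if (tr$mode == "sequential" && length(tr$drug_order) < 2L)
    stop("configuration error: treatment.mode 'sequential' requires two ",
         "drugs in treatment.drug_order", call. = FALSE)
  for (key in c("dose_B", "dose_H", "decision_interval", "start_time"))
    if (tr[[key]] < 0)
      stop("configuration error: treatment.", key, " must be >= 0 (got ",
           tr[[key]], ")", call. = FALSE)
  ic <- cfg$initial_condition
  for (key in c("spatial_sigma", "structural_sigma", "peak_density"))
    if (ic[[key]] <= 0)
      stop("configuration error: initial_condition.", key,
           " must be > 0 (got ", ic[[key]], ")", call. = FALSE)
  if (ic$ecne_dip < 0 || ic$ecne_dip > 1)
    stop("configuration error: initial_condition.ecne_dip must be in [0, 1]",
         call. = FALSE)
  run <- cfg$run
  if (run$horizon < 1)
    stop("configuration error: run.horizon must be >= 1 day", call. = FALSE)
  if (run$snapshot_interval < 1)
    stop("configuration error: run.snapshot_interval must be >= 1 day",
         call. = FALSE)
  if (run$dt_safety <= 0 || run$dt_safety > 1)
    stop("configuration error: run.dt_safety must be in (0, 1]", call. = FALSE)
  # constructors enforce the rest (grids, atlas, params, schedule)
  atlasFromConfig(cfg)
  paramsFromConfig(cfg)
  scheduleFromConfig(cfg)
  cfg
}

# build the typed objects from a validated configuration
atlasFromConfig <- function(cfg, grid = NULL) {
  a <- cfg$atlas
  nms <- c("proliferative", "invasive", "pigmented", "NCSC", "SMC", "URC")
  if (!setequal(names(a$anchors), nms))
    stop("configuration error: atlas.anchors must name exactly: ",
         paste(nms, collapse = ", "), call. = FALSE)
  pos <- do.call(rbind, a$anchors[nms])
  extent <- c(0, cfg$grid$structural_side)
  subpopulationAtlas(
    data.frame(name = nms, y1 = pos[, 1], y2 = pos[, 2],
               stringsAsFactors = FALSE),
    radius = a$radius, extent = extent)
}

paramsFromConfig <- function(cfg) {
  defaultParams(structural = cfg$structural_fluxes,
                spatial = cfg$spatial_fluxes,
                environment = cfg$environment,
                response = cfg$response,
                source = cfg$source)
}

scheduleFromConfig <- function(cfg) {
  tr <- cfg$treatment
  treatmentSchedule(mode = tr$mode,
                    drugOrder = unlist(tr$drug_order),
                    switchTime = tr$switch_time,
                    doseRate = c(BRAF_MEKi = tr$dose_B, HCT = tr$dose_H),
                    decisionInterval = tr$decision_interval,
                    lowerThreshold = tr$lower_threshold,
                    upperThreshold = tr$upper_threshold,
                    startTime = tr$start_time)
}

#' Load / save a scenario configuration
#'
#' `loadConfig()` reads a YAML scenario file, validates it against the
#' reference defaults and attaches a provenance hash; an empty file yields
#' the pure defaults. `saveConfig()` writes a configuration back to YAML;
#' load-save-load is idempotent.
#'
#' @param path file path.
#' @return `loadConfig()`: the validated configuration list with attribute
#'   `hash`.
#' @export
loadConfig <- function(path) {
  if (!file.exists(path))
    stop("configuration file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  cfg <- validateConfig(raw)
  attr(cfg, "hash") <- configHash(cfg)
  cfg
}

#' @rdname loadConfig
#' @param config configuration list.
#' @export
saveConfig <- function(config, path) {
  attr(config, "hash") <- NULL
  yaml::write_yaml(config, path, precision = 15L)
  invisible(path)
}

#' Provenance hash of a configuration
#'
#' Deterministic 32-bit polynomial hash of the YAML serialization, used to
#' tie trajectories back to the configuration that produced them.
#'
#' @param config configuration list.
#' @return 8-character hex string.
#' @export
configHash <- function(config) {
  attr(config, "hash") <- NULL
  s <- yaml::as.yaml(config, precision = 15L)
  bytes <- utf8ToInt(s)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Scenario presets
#'
#' The treatment scenarios studied with the model: `continuous-braf`
#' (uninterrupted BRAF/MEK inhibition), `continuous-hct` (uninterrupted
#' hypothetical cancer treatment), `braf-then-hct` and `hct-then-braf`
#' (sequential combinations), `adaptive-braf` (threshold-triggered BRAF/MEKi
#' with daily decisions) and `no-treatment`.
#'
#' @param name preset name, see [presetNames()].
#' @return validated configuration list.
#' @export
scenarioPreset <- function(name) {
  over <- switch(name,
    "no-treatment" = list(treatment = list(mode = "none")),
    "continuous-braf" = list(treatment = list(mode = "continuous",
                                              drug_order = "BRAF_MEKi")),
    "continuous-hct" = list(treatment = list(mode = "continuous",
                                             drug_order = "HCT")),
    "braf-then-hct" = list(treatment = list(mode = "sequential",
                                            drug_order = c("BRAF_MEKi", "HCT"),
                                            switch_time = 40)),
    "hct-then-braf" = list(treatment = list(mode = "sequential",
                                            drug_order = c("HCT", "BRAF_MEKi"),
                                            switch_time = 30)),
    "adaptive-braf" = list(treatment = list(mode = "adaptive",
                                            drug_order = "BRAF_MEKi",
                                            lower_threshold = 0.25,
                                            upper_threshold = 0.5,
                                            decision_interval = 1)),
    stop("unknown preset '", name, "'; available: ",
         paste(presetNames(), collapse = ", "), call. = FALSE)
  )
  validateConfig(over)
}

#' @rdname scenarioPreset
#' @export
presetNames <- function() {
  c("continuous-braf", "continuous-hct", "braf-then-hct", "hct-then-braf",
    "adaptive-braf", "no-treatment")
}
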