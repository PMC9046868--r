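# Reference-resolution scenario runs shared across the acceptance tests.
# Each preset is simulated once per test session (deterministic, seed-free)
# and cached; the suite orders tests so every criterion reuses these runs.

.scenarioCache <- new.env(parent = emptyenv())

referenceRun <- function(name) {
  if (is.null(.scenarioCache[[name]])) {
    .scenarioCache[[name]] <- runSimulation(scenarioPreset(name))
  }
  .scenarioCache[[name]]
}

referenceGrid <- function() {
  cfg <- defaultConfig()
  buildGrids(cfg$grid$n_spatial, cfg$grid$n_structural)
}

ttrOf <- function(trajectory) {
  timeToResistance(trajectory@mass, trajectory@times, trajectory@mass[1],
                   trajectory@config$treatment$start_time)
}

# time-to-resistance with the beyond-horizon convention for ordering
ttrOrdering <- function(trajectory) {
  t <- ttrOf(trajectory)
  if (is.na(t)) Inf else t
}
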