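# Shared fixtures: everything is built in code at test time.

refAtlas <- defaultAtlas()
refParams <- defaultParams()

smallGrid <- function(n = 16L) buildGrids(n, n)

# a smooth positive structural slice (products of Gaussians), ny x ny
gaussSlice <- function(grid, center = c(0.5, 0.5), sigma = 0.1, floor = 0) {
  yc <- structuralCenters(grid)
  ny <- grid@nStructural
  m <- outer(exp(-(yc - center[1])^2 / (2 * sigma^2)),
             exp(-(yc - center[2])^2 / (2 * sigma^2)))
  m + floor
}

# small scenario config for fast end-to-end runs
tinyConfig <- function(horizon = 10, n = 8L, treatment = list(mode = "none"),
                       ...) {
  over <- list(grid = list(n_spatial = n, n_structural = n),
               treatment = treatment,
               run = list(horizon = horizon, snapshot_interval = 5))
  extra <- list(...)
  for (k in names(extra)) over[[k]] <- extra[[k]]
  over
}

# forward-Euler evolution of a structural slice under transport only
evolveSlice <- function(slice, grid, atlas, params, tEnd, dt) {
  nSteps <- ceiling(tEnd / dt)
  for (i in seq_len(nSteps))
    slice <- slice + dt * structuralTransportDivergence(slice, grid, atlas,
                                                        params)
  slice
}

# mass-weighted center of mass of a slice along axis 1
sliceCom1 <- function(slice, grid) {
  yc <- structuralCenters(grid)
  sum(slice * yc) / sum(slice)  # rows vary along axis 1, recycling is exact
}
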