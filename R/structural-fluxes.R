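#' Cell-state advection field
#'
#' The directed structural flux stabilizes an attractor line interpolating
#' between the proliferative (SW) and SMC (N) states: at state `y` the
#' horizontal velocity is `-k_adv * (y1 - a(y2))` with attractor abscissa
#' `a(y2) = (1 - s) * y1_prolif + s * y1_SMC`, `s` the normalized vertical
#' coordinate. The vertical component is identically zero (advection is
#' horizontal only; vertical state changes occur by diffusion).
#'
#' @param y structural point (length-2) or n x 2 matrix, inside the extent.
#' @param atlas a [SubpopulationAtlas-class].
#' @param params a [ModelParams-class].
#'
#' @return n x 2 matrix of structural velocities (1/day scale).
#' @examples
#' advectionField(c(0.7, 0.5), defaultAtlas(), defaultParams())
#' @export
advectionField <- function(y, atlas, params) {
  y <- rbind2cols(y)
  .checkInExtent(y, atlas@extent)
  a <- attractorAbscissa(y[, 2], atlas)
  k <- params@structural$k_adv
  cbind(-k * (y[, 1] - a), 0)
}

# abscissa of the advection attractor line at vertical coordinate y2
attractorAbscissa <- function(y2, atlas) {
  s <- normCoord(y2, atlas@extent)
  yP <- anchorPosition(atlas, "proliferative")[1]
  ySMC <- anchorPosition(atlas, "SMC")[1]
  (1 - s) * yP + s * ySMC
}

#' Anisotropic cell-state diffusivity
#'
#' Diagonal structural diffusion tensor `diag(D_h(y2), D_v(y1))`. Horizontal
#' diffusion increases linearly from south to north (rare stochastic
#' proliferative-to-URC transitions in the south, frequent east-west
#' exchanges in the north); vertical diffusion is parabolic in `y1`, maximal
#' at the west/east edges and minimal at the center (lower transition rates
#' between SMC and the southern states).
#'
#' @inheritParams advectionField
#' @param extent structural extent, numeric(2).
#' @return n x 2 matrix with columns `D_h`, `D_v` (length^2/day).
#' @export
structuralDiffusivity <- function(y, params, extent = c(0, 1)) {
  y <- rbind2cols(y)
  .checkInExtent(y, extent)
  s <- params@structural
  t1 <- normCoord(y[, 1], extent)
  t2 <- normCoord(y[, 2], extent)
  Dh <- s$d_h_min + (s$d_h_max - s$d_h_min) * t2
  Dv <- s$d_v_min + (s$d_v_max - s$d_v_min) * (2 * t1 - 1)^2
  cbind(D_h = Dh, D_v = Dv)
}

# Precompute the structural face arrays used by the finite-volume kernels:
#  u1Face  (ny+1) x ny : horizontal advective velocity at y1-faces
#  dhFace  (ny+1) x ny : horizontal diffusivity at y1-faces (arith. average)
#  dvFace  ny x (ny+1) : vertical diffusivity at y2-faces (arith. average)
structuralFaces <- function(grid, atlas, params) {
  ny <- grid@nStructural
  yc <- structuralCenters(grid)
  yf <- grid@structuralExtent[1] + (0:ny) * grid@dxStructural
  aLine <- attractorAbscissa(yc, atlas)
  k <- params@structural$k_adv
  u1Face <- -k * outer(yf, aLine, "-")  # (ny+1) x ny

  Dcent <- structuralDiffusivity(
    cbind(rep(yc, times = ny), rep(yc, each = ny)), params,
    extent = grid@structuralExtent)
  Dh <- matrix(Dcent[, 1], ny, ny)
  Dv <- matrix(Dcent[, 2], ny, ny)
  dhFace <- matrix(0, ny + 1, ny)
  dhFace[2:ny, ] <- (Dh[-1, , drop = FALSE] + Dh[-ny, , drop = FALSE]) / 2
  dvFace <- matrix(0, ny, ny + 1)
  dvFace[, 2:ny] <- (Dv[, -1, drop = FALSE] + Dv[, -ny, drop = FALSE]) / 2
  list(u1Face = u1Face, dhFace = dhFace, dvFace = dvFace,
       scheme = if (identical(params@structural$advection_scheme, "minmod"))
         1L else 0L)
}

#' Conservative divergence of the structural fluxes on one state slice
#'
#' Finite-volume divergence of the advective (upwind) plus diffusive
#' (central, face-averaged diffusivity) cell-state fluxes for the structural
#' slice of the density at one spatial cell, with zero-flux boundaries. The
#' output times the cell area sums to zero up to round-off.
#'
#' @param cYY ny x ny nonnegative matrix: density over the structural grid.
#' @param grid a [GridSpec-class].
#' @param atlas a [SubpopulationAtlas-class].
#' @param params a [ModelParams-class].
#'
#' @return ny x ny matrix of time-derivative contributions.
#' @export
structuralTransportDivergence <- function(cYY, grid, atlas, params) {
  if (any(cYY < 0))
    stop("contract violation: negative input density", call. = FALSE)
  ny <- grid@nStructural
  stopifnot(nrow(cYY) == ny, ncol(cYY) == ny)
  f <- structuralFaces(grid, atlas, params)
  zeroV <- matrix(0, ny, ny + 1)  # no vertical structural advection
  fvDivergence2D(cYY, f$u1Face, zeroV, f$dhFace, f$dvFace,
                 grid@dxStructural, grid@dxStructural, f$scheme)
}
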