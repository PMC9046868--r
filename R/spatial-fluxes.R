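# Spatial transport: undirected diffusion with volume filling, plus
# chemotaxis (up nutrient gradients) and haptotaxis (up ECNE gradients).

# Precompute the spatial face arrays shared by every structural slice:
#  uxFace (nx+1) x nx, uyFace nx x (nx+1): taxis velocity at faces
#  dxFace, dyFace: effective diffusivity at faces
spatialFaces <- function(n, v, rho, grid, params) {
  sp <- params@spatial
  nx <- grid@nSpatial
  h <- grid@dxSpatial
  gradFace1 <- function(f) {
    out <- matrix(0, nx + 1, nx)
    out[2:nx, ] <- (f[-1, , drop = FALSE] - f[-nx, , drop = FALSE]) / h
    out
  }
  gradFace2 <- function(f) {
    out <- matrix(0, nx, nx + 1)
    out[, 2:nx] <- (f[, -1, drop = FALSE] - f[, -nx, drop = FALSE]) / h
    out
  }
  uxFace <- sp$chi_n * gradFace1(n) + sp$chi_v * gradFace1(v)
  uyFace <- sp$chi_n * gradFace2(n) + sp$chi_v * gradFace2(v)

  # volume-filling factor, clipped at zero, averaged onto faces
  vol <- pmax(1 - rho / sp$rho_max, 0)
  avg1 <- matrix(0, nx + 1, nx)
  avg1[2:nx, ] <- (vol[-1, , drop = FALSE] + vol[-nx, , drop = FALSE]) / 2
  avg2 <- matrix(0, nx, nx + 1)
  avg2[, 2:nx] <- (vol[, -1, drop = FALSE] + vol[, -nx, drop = FALSE]) / 2

  if (identical(sp$volume_filling, "taxis")) {
    uxFace <- uxFace * avg1
    uyFace <- uyFace * avg2
    dxFace <- matrix(sp$D_x, nx + 1, nx)
    dyFace <- matrix(sp$D_x, nx, nx + 1)
    dxFace[c(1, nx + 1), ] <- 0
    dyFace[, c(1, nx + 1)] <- 0
  } else {
    dxFace <- sp$D_x * avg1
    dyFace <- sp$D_x * avg2
  }
  list(uxFace = uxFace, uyFace = uyFace, dxFace = dxFace, dyFace = dyFace)
}

#' Conservative divergence of the spatial fluxes on one spatial slice
#'
#' Finite-volume divergence of the spatial flux
#' `F_x = -D_x (1 - rho/rho_max)_+ grad(c) + c (chi_n grad(n) + chi_v grad(v))`
#' for the spatial slice of the density at one structural cell: volume-filled
#' central diffusion plus upwind chemotactic/haptotactic advection, zero-flux
#' boundaries. Output sums to zero (times cell area) up to round-off.
#'
#' @param cXX nx x nx nonnegative matrix: density over the spatial grid.
#' @param n,v nx x nx nutrient and ECNE fields.
#' @param rho nx x nx total spatial cell density (structural quadrature of
#'   the full density).
#' @param grid a [GridSpec-class].
#' @param params a [ModelParams-class].
#'
#' @return nx x nx matrix of time-derivative contributions.
#' @export
spatialTransportDivergence <- function(cXX, n, v, rho, grid, params) {
  nx <- grid@nSpatial
  dims <- vapply(list(cXX, n, v, rho), function(m)
    identical(dim(m), c(nx, nx)), logical(1))
  if (!all(dims))
    stop("contract violation: field shapes must match the spatial grid",
         call. = FALSE)
  if (any(cXX < 0) || any(n < 0) || any(v < 0) || any(rho < 0))
    stop("contract violation: negative input field", call. = FALSE)
  f <- spatialFaces(n, v, rho, grid, params)
  scheme <- if (identical(params@structural$advection_scheme, "minmod"))
    1L else 0L
  fvDivergence2D(cXX, f$uxFace, f$uyFace, f$dxFace, f$dyFace,
                 grid@dxSpatial, grid@dxSpatial, scheme)
}
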