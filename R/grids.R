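#' Build the spatial and structural finite-volume grids
#'
#' Constructs cell-centered, uniform grids for both planes. Coordinates are
#' cell centers, reproducible bit-exactly from the configuration (center of
#' cell i is `lo + (i - 1/2) * h`).
#'
#' @param nSpatial integer >= 4, cells per spatial axis.
#' @param nStructural integer >= 4, cells per structural axis.
#' @param spatialSide,structuralSide numeric side lengths of the (square)
#'   extents; both default to the unit square starting at 0.
#'
#' @return A [GridSpec-class].
#'
#' @examples
#' g <- buildGrids(4, 4)
#' spatialCenters(g)  # 0.125 0.375 0.625 0.875
#' @export
buildGrids <- function(nSpatial = 24L, nStructural = 24L,
                       spatialSide = 1, structuralSide = 1) {
  checkRes <- function(n, key) {
    if (length(n) != 1L || !is.finite(n) || n != round(n))
      stop("configuration error: '", key, "' must be a single integer, got ",
           deparse(n), call. = FALSE)
    if (n < 4)
      stop("configuration error: '", key, "' must be >= 4, got ", n,
           call. = FALSE)
    as.integer(n)
  }
  nSpatial <- checkRes(nSpatial, "grid.n_spatial")
  nStructural <- checkRes(nStructural, "grid.n_structural")
  if (spatialSide <= 0 || structuralSide <= 0)
    stop("configuration error: extent sides must be positive", call. = FALSE)
  dxS <- spatialSide / nSpatial
  dxY <- structuralSide / nStructural
  new("GridSpec",
      nSpatial = nSpatial, nStructural = nStructural,
      spatialExtent = c(0, spatialSide), structuralExtent = c(0, structuralSide),
      dxSpatial = dxS, dxStructural = dxY,
      spatialCenters = (seq_len(nSpatial) - 0.5) * dxS,
      structuralCenters = (seq_len(nStructural) - 0.5) * dxY)
}

#' @describeIn buildGrids spatial cell-center coordinates.
#' @param grid a [GridSpec-class].
#' @export
spatialCenters <- function(grid) grid@spatialCenters

#' @describeIn buildGrids structural cell-center coordinates.
#' @export
structuralCenters <- function(grid) grid@structuralCenters

#' @describeIn buildGrids total number of 4D cells.
#' @export
nCells4D <- function(grid) {
  as.numeric(grid@nSpatial)^2 * as.numeric(grid@nStructural)^2
}

# 4D midpoint-quadrature cell volume
cellVolume4D <- function(grid) grid@dxSpatial^2 * grid@dxStructural^2

# normalized coordinate within an extent
normCoord <- function(x, extent) (x - extent[1]) / (extent[2] - extent[1])
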