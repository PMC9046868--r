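#' The six-subpopulation structural geography
#'
#' Returns the reference atlas of the six melanoma cell-state anchors on the
#' unit structural square, placed by their compass positions: proliferative
#' south-west, invasive east, pigmented north-west, neural-crest stem cells
#' (NCSC) north-east, starved-like melanoma cells (SMC) north, and
#' uncharacterized resistant cells (URC) south-east. Each subpopulation's
#' structural subdomain is the closed disc of the given radius around its
#' anchor.
#'
#' @param radius disc radius (structural length units), default 0.15.
#' @param extent numeric(2) structural extent, default the unit interval on
#'   both axes.
#'
#' @return A [SubpopulationAtlas-class].
#' @examples
#' atlas <- defaultAtlas()
#' anchorNames(atlas)
#' @export
defaultAtlas <- function(radius = 0.15, extent = c(0, 1)) {
  anchors <- data.frame(
    name = c("proliferative", "invasive", "pigmented", "NCSC", "SMC", "URC"),
    y1 = c(0.20, 0.85, 0.20, 0.85, 0.50, 0.80),
    y2 = c(0.20, 0.50, 0.85, 0.85, 0.90, 0.15),
    stringsAsFactors = FALSE
  )
  # rescale the reference unit-square coordinates onto the requested extent
  side <- diff(extent)
  anchors$y1 <- extent[1] + anchors$y1 * side
  anchors$y2 <- extent[1] + anchors$y2 * side
  new("SubpopulationAtlas", anchors = anchors, radius = radius, extent = extent)
}

#' Build an atlas from explicit anchor coordinates
#'
#' @param anchors data.frame with columns `name`, `y1`, `y2` (six rows).
#' @param radius disc radius.
#' @param extent structural extent, numeric(2).
#' @return A [SubpopulationAtlas-class].
#' @export
subpopulationAtlas <- function(anchors, radius = 0.15, extent = c(0, 1)) {
  new("SubpopulationAtlas", anchors = as.data.frame(anchors),
      radius = radius, extent = extent)
}

#' @describeIn defaultAtlas the anchor names, in atlas order.
#' @param atlas a [SubpopulationAtlas-class].
#' @export
anchorNames <- function(atlas) atlas@anchors$name

#' @describeIn defaultAtlas position of one named anchor as numeric(2).
#' @param name anchor name.
#' @export
anchorPosition <- function(atlas, name) {
  i <- match(name, atlas@anchors$name)
  if (is.na(i)) stop("unknown anchor name: ", name, call. = FALSE)
  c(atlas@anchors$y1[i], atlas@anchors$y2[i])
}

#' @describeIn defaultAtlas the subdomain disc radius.
#' @export
atlasRadius <- function(atlas) atlas@radius

.checkInExtent <- function(y, extent, what = "structural point") {
  if (any(y < extent[1] - 1e-12) || any(y > extent[2] + 1e-12))
    stop("domain error: ", what, " outside the structural extent [",
         extent[1], ", ", extent[2], "]", call. = FALSE)
  invisible(TRUE)
}

#' Classify structural states into subpopulations
#'
#' A cell state belongs to a subpopulation if it lies inside that
#' subpopulation's closed disc; where discs overlap, the nearest anchor wins.
#' States in no disc are `"unassigned"` (intermediate phenotypes).
#'
#' @param y a structural point (length-2 numeric) or an n x 2 matrix of
#'   points. Must lie inside the structural extent.
#' @param atlas a [SubpopulationAtlas-class].
#'
#' @return Character vector of subpopulation names (or `"unassigned"`),
#'   one per row of `y`.
#' @examples
#' classifyState(c(0.20, 0.20), defaultAtlas())  # "proliferative"
#' classifyState(c(0.50, 0.50), defaultAtlas())  # "unassigned"
#' @export
classifyState <- function(y, atlas) {
  y <- rbind2cols(y)
  .checkInExtent(y, atlas@extent)
  a <- atlas@anchors
  # squared distances, n x 6
  d2 <- outer(y[, 1], a$y1, "-")^2 + outer(y[, 2], a$y2, "-")^2
  nearest <- max.col(-d2, ties.method = "first")
  inDisc <- d2[cbind(seq_len(nrow(y)), nearest)] <= atlas@radius^2 + 1e-15
  out <- rep("unassigned", nrow(y))
  out[inDisc] <- a$name[nearest[inDisc]]
  out
}

# coerce a length-2 vector or n x 2 matrix to an n x 2 matrix
rbind2cols <- function(y) {
  if (is.null(dim(y))) {
    if (length(y) != 2L) stop("a structural point must have two coordinates",
                              call. = FALSE)
    matrix(y, 1L, 2L)
  } else {
    if (ncol(y) != 2L) stop("points must be an n x 2 matrix", call. = FALSE)
    as.matrix(y)
  }
}

# logical ny x ny masks of the structural grid cells belonging to each
# subpopulation (atlas order); used by fraction and zoning metrics
subpopMasks <- function(atlas, grid) {
  yc <- structuralCenters(grid)
  pts <- cbind(rep(yc, times = length(yc)), rep(yc, each = length(yc)))
  lab <- classifyState(pts, atlas)
  lapply(anchorNames(atlas), function(nm) {
    matrix(lab == nm, grid@nStructural, grid@nStructural)
  })
}
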