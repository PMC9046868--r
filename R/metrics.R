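#' Total tumor burden
#'
#' 4D midpoint quadrature of the cell density: the model's operationalization
#' of "tumor volume".
#'
#' @param c4 4D density array (nx, nx, ny, ny), nonnegative.
#' @param grid a [GridSpec-class].
#' @return scalar burden (cells).
#' @export
totalMass <- function(c4, grid) {
  if (!identical(dim(c4), c(grid@nSpatial, grid@nSpatial,
                            grid@nStructural, grid@nStructural)))
    stop("shape mismatch between density and grid", call. = FALSE)
  sum(c4) * cellVolume4D(grid)
}

#' Structural marginal density
#'
#' Integrates the 4D density over space; the integral of the marginal equals
#' the total burden.
#'
#' @inheritParams totalMass
#' @return ny x ny matrix.
#' @export
structuralMarginal <- function(c4, grid) {
  if (!identical(dim(c4), c(grid@nSpatial, grid@nSpatial,
                            grid@nStructural, grid@nStructural)))
    stop("shape mismatch between density and grid", call. = FALSE)
  ny <- grid@nStructural
  m <- matrix(colSums(matrix(c4, grid@nSpatial^2, ny * ny)), ny, ny)
  m * grid@dxSpatial^2
}

#' Subpopulation mass fractions
#'
#' Fraction of the total burden whose structural cell center classifies into
#' each subpopulation disc; the remainder (intermediate phenotypes) is
#' reported as `unassigned`. Fractions sum to 1.
#'
#' @inheritParams totalMass
#' @param atlas a [SubpopulationAtlas-class].
#' @return named numeric: six subpopulations plus `unassigned`, with
#'   attribute `zeroMass = TRUE` (and all-zero fractions) when the density
#'   is empty.
#' @export
subpopFractions <- function(c4, atlas, grid) {
  marg <- structuralMarginal(c4, grid)
  M <- sum(marg) * grid@dxStructural^2
  masks <- subpopMasks(atlas, grid)
  names(masks) <- anchorNames(atlas)
  out <- setNames(numeric(7), c(anchorNames(atlas), "unassigned"))
  if (M <= 0) {
    attr(out, "zeroMass") <- TRUE
    return(out)
  }
  for (nm in names(masks))
    out[nm] <- sum(marg[masks[[nm]]]) * grid@dxStructural^2 / M
  out["unassigned"] <- 1 - sum(out[names(masks)])
  attr(out, "zeroMass") <- FALSE
  out
}

#' Heterogeneity variance of the structural distribution
#'
#' Mass-weighted variance (trace of the covariance) of the cell-state
#' distribution: `Var = \int |y - ybar|^2 c \, dx \, dy / M`. The paper-level
#' heterogeneity metric: diffusion in state space grows it, a concentrated
#' (naive or mono-modal) tumor keeps it small.
#'
#' @inheritParams totalMass
#' @return scalar (structural length^2).
#' @export
heterogeneityVariance <- function(c4, grid) {
  marg <- structuralMarginal(c4, grid)
  w <- as.vector(marg)
  M <- sum(w)
  if (M <= 0)
    stop("undefined metric: zero total mass", call. = FALSE)
  yc <- structuralCenters(grid)
  ny <- grid@nStructural
  y1 <- rep(yc, times = ny); y2 <- rep(yc, each = ny)
  m1 <- sum(w * y1) / M; m2 <- sum(w * y2) / M
  sum(w * ((y1 - m1)^2 + (y2 - m2)^2)) / M
}

# separable Gaussian smoothing with edge renormalization (truncated kernel)
gaussSmooth2D <- function(m, width) {
  if (width <= 0) return(m)
  r <- max(1L, ceiling(3 * width))
  k <- exp(-(-r:r)^2 / (2 * width^2))
  sm1 <- function(x) {
    n <- length(x)
    out <- numeric(n)
    for (i in seq_len(n)) {
      lo <- max(1L, i - r); hi <- min(n, i + r)
      kk <- k[(lo - i + r + 1L):(hi - i + r + 1L)]
      out[i] <- sum(x[lo:hi] * kk) / sum(kk)
    }
    out
  }
  m <- apply(m, 2, sm1)
  t(apply(m, 1, sm1))
}

#' Count modes of a structural marginal
#'
#' Gaussian-smooths the marginal and counts strict 8-neighbor local maxima
#' above `relThreshold` times the global maximum. An exactly uniform (or
#' all-zero) field has no strict maxima and returns 0.
#'
#' @param marginal ny x ny nonnegative matrix.
#' @param smoothWidth Gaussian width in grid cells (default 2).
#' @param relThreshold fraction of the global maximum below which maxima are
#'   ignored (default 0.05).
#' @return integer mode count.
#' @export
countModes <- function(marginal, smoothWidth = 2, relThreshold = 0.05) {
  if (any(marginal < 0))
    stop("contract violation: negative marginal", call. = FALSE)
  if (all(marginal == 0)) return(0L)
  sm <- gaussSmooth2D(marginal, smoothWidth)
  n1 <- nrow(sm); n2 <- ncol(sm)
  thr <- relThreshold * max(sm)
  count <- 0L
  for (j in seq_len(n2)) for (i in seq_len(n1)) {
    v <- sm[i, j]
    if (v < thr) next
    isMax <- TRUE
    for (dj in -1:1) for (di in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > n1 || jj < 1 || jj > n2) next
      if (sm[ii, jj] >= v) { isMax <- FALSE; break }
    }
    if (isMax) count <- count + 1L
  }
  count
}

#' Time to resistance
#'
#' First time after treatment start at which the burden regains its baseline
#' (pre-treatment) value, linearly interpolated between samples; `NA` if the
#' burden stays below baseline for the whole series.
#'
#' @param mass numeric burden series.
#' @param times numeric times (days), aligned with `mass`.
#' @param baseline burden to regain (the burden at treatment start).
#' @param start treatment start day; only `t > start` counts.
#' @return day (numeric) or `NA_real_`.
#' @export
timeToResistance <- function(mass, times, baseline, start = 0) {
  if (!length(mass) || length(mass) != length(times))
    stop("mass and times must be nonempty and aligned", call. = FALSE)
  after <- times > start
  idx <- which(after & mass >= baseline)
  # ignore samples while the burden has not yet dropped below baseline? No:
  # the first regain after start counts, but only once the burden has been
  # below baseline at least once (otherwise "re-establishment" is immediate).
  below <- which(after & mass < baseline)
  if (!length(below)) {
    # never responded: resistance is immediate at treatment start
    return(if (length(idx)) times[idx[1]] else NA_real_)
  }
  cross <- idx[idx > below[1]]
  if (!length(cross)) return(NA_real_)
  i <- cross[1]
  if (i == 1L || mass[i - 1] >= baseline) return(times[i])
  # linear interpolation between the bracketing samples
  t0 <- times[i - 1]; t1 <- times[i]
  m0 <- mass[i - 1]; m1 <- mass[i]
  t0 + (baseline - m0) / (m1 - m0) * (t1 - t0)
}

#' Segment a burden curve into shrink / MRD / regrow phases
#'
#' Smooths the series with a moving average of window `minDuration` days,
#' classifies each time by the sign of the local slope against
#' `slopeTol * M0` per day (below: shrink, within: MRD, above: regrow),
#' merges runs shorter than `minDuration` into their neighbors, and returns
#' the maximal runs.
#'
#' @param mass numeric burden series (length >= 3).
#' @param times numeric days, aligned.
#' @param slopeTol slope threshold as fraction of the initial burden per day
#'   (default 0.002).
#' @param minDuration minimal phase duration in days (default 10).
#' @return data.frame with columns `label` (shrink/MRD/regrow), `start`,
#'   `end`.
#' @export
segmentPhases <- function(mass, times, slopeTol = 0.002, minDuration = 10) {
  if (length(mass) < 3L || length(mass) != length(times))
    stop("series must have length >= 3 and align with times", call. = FALSE)
  dtMed <- stats::median(diff(times))
  win <- max(1L, round(minDuration / dtMed))
  if (length(mass) <= win)
    stop("series shorter than the smoothing window", call. = FALSE)
  sm <- stats::filter(mass, rep(1 / win, win), sides = 2)
  sm <- as.numeric(sm)
  # extend the moving average to the edges with shrinking windows
  na <- which(is.na(sm))
  for (i in na) {
    lo <- max(1L, i - win %/% 2L); hi <- min(length(mass), i + win %/% 2L)
    sm[i] <- mean(mass[lo:hi])
  }
  slope <- c(diff(sm) / diff(times), NA)
  slope[length(slope)] <- slope[length(slope) - 1L]
  tol <- slopeTol * mass[1]
  lab <- ifelse(slope < -tol, "shrink", ifelse(slope > tol, "regrow", "MRD"))

  runs <- rle(lab)
  # merge runs shorter than minDuration into the longer neighbor
  repeat {
    if (length(runs$lengths) <= 1L) break
    durs <- runs$lengths * dtMed
    shortest <- which.min(durs)
    if (durs[shortest] >= minDuration) break
    nb <- if (shortest == 1L) 2L
          else if (shortest == length(runs$lengths)) shortest - 1L
          else if (runs$lengths[shortest - 1L] >= runs$lengths[shortest + 1L])
            shortest - 1L else shortest + 1L
    runs$values[shortest] <- runs$values[nb]
    lab2 <- inverse.rle(runs)
    runs <- rle(lab2)
  }
  ends <- cumsum(runs$lengths)
  starts <- c(1L, ends[-length(ends)] + 1L)
  data.frame(label = runs$values,
             start = times[starts], end = times[ends],
             stringsAsFactors = FALSE)
}

#' Spatial zoning of the subpopulations
#'
#' For each subpopulation `s`, its spatial density field `m_s(x)` is the
#' structural integral of the density over the subpopulation's disc. The
#' overlap of two subpopulations is the spatial cosine similarity of their
#' fields (0 when either field is identically zero); the zonation index is
#' one minus the mean off-diagonal overlap over pairs where both fields are
#' nonzero. Higher zonation = more mutually exclusive spatial patterns.
#'
#' @inheritParams subpopFractions
#' @return list with `overlap` (symmetric 6x6 matrix, unit diagonal for
#'   nonzero fields), `zonationIndex` scalar, and `fields` (list of nx x nx
#'   subpopulation density fields).
#' @export
zoningOverlap <- function(c4, atlas, grid) {
  if (totalMass(c4, grid) <= 0)
    stop("undefined metric: zero total mass", call. = FALSE)
  nx <- grid@nSpatial
  masks <- subpopMasks(atlas, grid)
  names(masks) <- anchorNames(atlas)
  cm <- matrix(c4, nx * nx, grid@nStructural^2)
  fields <- lapply(masks, function(msk) {
    sel <- which(as.vector(msk))
    f <- if (length(sel) == 1L) cm[, sel]
         else rowSums(cm[, sel, drop = FALSE])
    matrix(f * grid@dxStructural^2, nx, nx)
  })
  k <- length(fields)
  overlap <- matrix(0, k, k, dimnames = list(names(fields), names(fields)))
  norms <- vapply(fields, function(f) sqrt(sum(f^2)), numeric(1))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (norms[i] > 0 && norms[j] > 0)
      overlap[i, j] <- sum(fields[[i]] * fields[[j]]) / (norms[i] * norms[j])
  }
  diag(overlap)[norms > 0] <- 1
  pairs <- which(upper.tri(overlap) &
                   outer(norms > 0, norms > 0, "&"), arr.ind = TRUE)
  zi <- if (nrow(pairs)) 1 - mean(overlap[pairs]) else NA_real_
  list(overlap = overlap, zonationIndex = zi, fields = fields)
}

#' Full metrics report for a trajectory
#'
#' Computes every derived quantity: time-to-resistance, growth-phase
#' segmentation, and the per-snapshot heterogeneity variance, mode count and
#' subpopulation fraction series, plus the zoning overlap of the final
#' snapshot.
#'
#' @param trajectory a [Trajectory-class].
#' @param slopeTol,minDuration phase-segmentation settings, see
#'   [segmentPhases()].
#' @param smoothWidth,relThreshold mode-counting settings, see
#'   [countModes()].
#' @return A [MetricsReport-class].
#' @export
metricsReport <- function(trajectory, slopeTol = 0.002, minDuration = 10,
                          smoothWidth = 2, relThreshold = 0.05) {
  cfg <- trajectory@config
  grid <- buildGrids(cfg$grid$n_spatial, cfg$grid$n_structural,
                     cfg$grid$spatial_side, cfg$grid$structural_side)
  atlas <- atlasFromConfig(cfg, grid)
  start <- cfg$treatment$start_time
  baseline <- trajectory@mass[which(trajectory@times >= start)[1]]
  ttr <- timeToResistance(trajectory@mass, trajectory@times, baseline, start)
  phases <- segmentPhases(trajectory@mass, trajectory@times,
                          slopeTol = slopeTol, minDuration = minDuration)

  snaps <- trajectory@snapshots
  ts <- trajectory@snapshotTimes
  vars <- numeric(length(snaps)); modes <- integer(length(snaps))
  fracs <- vector("list", length(snaps))
  for (i in seq_along(snaps)) {
    c4 <- snaps[[i]]@c
    marg <- structuralMarginal(c4, grid)
    vars[i] <- if (sum(marg) > 0) heterogeneityVariance(c4, grid) else NA_real_
    modes[i] <- countModes(marg, smoothWidth, relThreshold)
    fracs[[i]] <- subpopFractions(c4, atlas, grid)
  }
  fracDf <- cbind(data.frame(t = ts), as.data.frame(do.call(rbind, fracs)))
  zon <- zoningOverlap(snaps[[length(snaps)]]@c, atlas, grid)
  new("MetricsReport",
      timeToResistance = ttr,
      phases = phases,
      varianceSeries = data.frame(t = ts, variance = vars),
      modeCountSeries = data.frame(t = ts, modes = modes),
      fractionSeries = fracDf,
      zoningOverlap = zon$overlap,
      zonationIndex = zon$zonationIndex)
}
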