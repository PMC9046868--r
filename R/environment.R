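# The five 2D environment fields: ECNE v, nutrient n, acid a, drugs wB, wH.

# five-point zero-flux Laplacian (ghost cells replicate the edge value,
# equivalent to zero-flux in conservative form on a uniform grid)
laplacian2D <- function(f, h) {
  n1 <- nrow(f); n2 <- ncol(f)
  up <- f[c(1L, seq_len(n1 - 1L)), , drop = FALSE]
  dn <- f[c(seq_len(n1 - 1L) + 1L, n1), , drop = FALSE]
  lf <- f[, c(1L, seq_len(n2 - 1L)), drop = FALSE]
  rt <- f[, c(seq_len(n2 - 1L) + 1L, n2), drop = FALSE]
  (up + dn + lf + rt - 4 * f) / h^2
}

#' Right-hand sides of the five environment fields
#'
#' The extracellular nutritional environment (ECNE) is immobile: it restores
#' logistically and is degraded by acid and by natural decay. Nutrient is
#' produced by the ECNE, consumed by cells, diffuses and decays. Acid is
#' produced by cells, diffuses and decays. Each drug diffuses, is
#' administered at a spatially uniform rate while its schedule is ON, decays
#' naturally and is taken up by cells. All Laplacians use zero-flux
#' boundaries.
#'
#' @param v,n,a,wB,wH nx x nx nonnegative fields: ECNE, nutrient, acid, and
#'   the BRAF/MEKi and HCT drug concentrations.
#' @param rho nx x nx total spatial cell density.
#' @param dose named numeric: administration rates
#'   `c(BRAF_MEKi = , HCT = )` (concentration/day), nonnegative.
#' @param grid a [GridSpec-class].
#' @param params a [ModelParams-class].
#'
#' @return Named list of five nx x nx time-derivative fields
#'   (`dv`, `dn`, `da`, `dwB`, `dwH`).
#' @export
environmentRhs <- function(v, n, a, wB, wH, rho, dose, grid, params) {
  if (any(v < 0) || any(n < 0) || any(a < 0) || any(wB < 0) || any(wH < 0) ||
      any(rho < 0))
    stop("contract violation: negative field values", call. = FALSE)
  if (any(dose < 0))
    stop("contract violation: negative dose rates", call. = FALSE)
  e <- params@environment
  h <- grid@dxSpatial
  doseB <- if ("BRAF_MEKi" %in% names(dose)) dose[["BRAF_MEKi"]] else 0
  doseH <- if ("HCT" %in% names(dose)) dose[["HCT"]] else 0
  list(
    dv = e$r_v * v * (1 - v / e$v_max) - e$lam_av * a * v - e$lam_v * v,
    dn = e$D_n * laplacian2D(n, h) + e$alpha_n * v -
      e$beta_n * rho * n - e$lam_n * n,
    da = e$D_a * laplacian2D(a, h) + e$alpha_a * rho - e$lam_a * a,
    dwB = e$D_w * laplacian2D(wB, h) + doseB - e$lam_w * wB -
      e$eps_w * rho * wB,
    dwH = e$D_w * laplacian2D(wH, h) + doseH - e$lam_w * wH -
      e$eps_w * rho * wH
  )
}
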