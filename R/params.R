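#' Reference model parameter set
#'
#' All model rate constants, grouped as in the configuration file. Every
#' quantity is dimensionless except time, measured in days; lengths are in
#' units of the unit-square domain sides. The defaults are the package's
#' calibrated reference set: they are chosen so that the untreated tumor
#' doubles in roughly two weeks, continuous BRAF/MEKi therapy produces the
#' three-phase response with resistance onset near four months, and the
#' hypothetical cancer treatment (HCT) alone fails within two months. See the
#' methods vignette for the calibration rationale of each value.
#'
#' Groups and entries:
#' \describe{
#'   \item{structural}{`k_adv` cell-state advection stiffness (1/day);
#'     `d_h_min`, `d_h_max` horizontal structural diffusivity bounds
#'     (length^2/day, linear south-to-north increase); `d_v_min`, `d_v_max`
#'     vertical structural diffusivity bounds (parabolic, maximal at the
#'     west/east edges).}
#'   \item{spatial}{`D_x` cell diffusivity (length^2/day); `chi_n`
#'     chemotactic sensitivity to nutrient; `chi_v` haptotactic sensitivity
#'     to ECNE; `rho_max` crowding capacity (cells/length^2).}
#'   \item{environment}{ECNE: `r_v` logistic restoration rate, `v_max`
#'     capacity, `lam_av` acid-induced degradation, `lam_v` natural decay.
#'     Nutrient: `D_n` diffusivity, `alpha_n` production per unit ECNE,
#'     `beta_n` consumption per cell, `lam_n` decay. Acid: `D_a`, `alpha_a`
#'     production per cell, `lam_a` decay. Drugs: `D_w` diffusivity, `lam_w`
#'     natural decay, `eps_w` cell-mediated uptake.}
#'   \item{response}{`sigma_B` width of the BRAF/MEKi response components;
#'     `w_inv` weight of its invasive component; `att_depth`, `sigma_att`
#'     depth/width of the pigmented (NW) attenuation; `delta_B` kill-rate
#'     coefficient (per unit drug per day); `sigma_H`, `delta_H` the same
#'     for HCT.}
#'   \item{source}{`p_max` maximal proliferation rate (1/day); `sigma_P`
#'     width of the proliferative growth bump; `smc_suppression` in `[0, 1]`,
#'     depth of growth suppression around the starved-like (SMC) state;
#'     `sigma_S` its width; `n_half` nutrient half-saturation.}
#' }
#'
#' @param ... named overrides, either whole groups (`structural = list(...)`
#'   merged into the group) or ignored if unknown (an error).
#'
#' @return A [ModelParams-class].
#' @examples
#' p <- defaultParams(structural = list(k_adv = 0.1))
#' @export
defaultParams <- function(...) {
  base <- list(
    structural = list(
      k_adv = 0.01,
      d_h_min = 4e-4, d_h_max = 2.5e-3,
      d_v_min = 2e-4, d_v_max = 1e-3,
      advection_scheme = "upwind"
    ),
    spatial = list(
      D_x = 5e-4, chi_n = 2e-3, chi_v = 1e-3, rho_max = 1,
      volume_filling = "diffusion"
    ),
    environment = list(
      r_v = 0.2, v_max = 1, lam_av = 0.2, lam_v = 0.01,
      D_n = 2e-3, D_a = 2e-3, D_w = 2e-3,
      alpha_n = 1, beta_n = 2, lam_n = 0.5,
      alpha_a = 0.5, lam_a = 0.5,
      lam_w = 1, eps_w = 0.2
    ),
    response = list(
      sigma_B = 0.20, w_inv = 0.3, att_depth = 0.8, sigma_att = 0.18,
      delta_B = 0.32, sigma_H = 0.26, delta_H = 1.5
    ),
    source = list(
      p_max = 0.15, sigma_P = 0.7, smc_suppression = 0.95, sigma_S = 0.45,
      n_half = 0.3
    )
  )
  over <- list(...)
  bad <- setdiff(names(over), names(base))
  if (length(bad))
    stop("configuration error: unknown parameter group(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  for (grp in names(over)) {
    unknown <- setdiff(names(over[[grp]]), names(base[[grp]]))
    if (length(unknown))
      stop("configuration error: unknown parameter(s) in ", grp, ": ",
           paste(unknown, collapse = ", "), call. = FALSE)
    base[[grp]][names(over[[grp]])] <- over[[grp]]
  }
  p <- new("ModelParams",
           structural = base$structural, spatial = base$spatial,
           environment = base$environment, response = base$response,
           source = base$source)
  validObject(p)
  p
}

#' @describeIn defaultParams accessor for one parameter group
#'   (`"structural"`, `"spatial"`, `"environment"`, `"response"`,
#'   `"source"`).
#' @param params a [ModelParams-class].
#' @param group group name.
#' @export
paramGroup <- function(params, group) {
  if (!group %in% slotNames(params))
    stop("unknown parameter group: ", group, call. = FALSE)
  slot(params, group)
}

#' @importFrom methods slotNames
NULL

setMethod("show", "ModelParams", function(object) {
  cat("ModelParams (reference set unless overridden)\n")
  for (grp in c("structural", "spatial", "environment", "response", "source")) {
    vals <- slot(object, grp)
    num <- vals[vapply(vals, is.numeric, logical(1))]
    cat(" ", grp, ": ",
        paste(names(num), signif(unlist(num), 3), sep = "=", collapse = ", "),
        "\n", sep = "")
  }
})
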