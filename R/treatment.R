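#' Construct a treatment schedule
#'
#' @param mode `"none"`, `"continuous"`, `"sequential"` or `"adaptive"`.
#' @param drugOrder character vector over `"BRAF_MEKi"`, `"HCT"`; the order
#'   matters for sequential mode.
#' @param switchTime day of the sequential switch.
#' @param doseRate named numeric administration rates while ON.
#' @param decisionInterval days between adaptive decisions.
#' @param lowerThreshold,upperThreshold adaptive thresholds as fractions of
#'   the burden at treatment start.
#' @param startTime day treatment begins.
#'
#' @return A [TreatmentSchedule-class].
#' @export
treatmentSchedule <- function(mode = "continuous",
                              drugOrder = "BRAF_MEKi",
                              switchTime = 100,
                              doseRate = c(BRAF_MEKi = 1, HCT = 1),
                              decisionInterval = 1,
                              lowerThreshold = 0.25,
                              upperThreshold = 0.5,
                              startTime = 0) {
  s <- new("TreatmentSchedule",
           mode = mode, drugOrder = drugOrder, switchTime = switchTime,
           doseRate = doseRate, decisionInterval = decisionInterval,
           lowerThreshold = lowerThreshold, upperThreshold = upperThreshold,
           startTime = startTime)
  validObject(s)
  s
}

setMethod("show", "TreatmentSchedule", function(object) {
  cat("TreatmentSchedule:", object@mode,
      "(", paste(object@drugOrder, collapse = " -> "), ")\n")
  if (object@mode == "sequential")
    cat("  switch at day", object@switchTime, "\n")
  if (object@mode == "adaptive")
    cat("  thresholds", object@lowerThreshold, "/", object@upperThreshold,
        "of initial burden, decision every", object@decisionInterval, "days\n")
})

# isotropic Gaussian bump peaking at 1
gaussBump <- function(y, center, sigma) {
  d2 <- (y[, 1] - center[1])^2 + (y[, 2] - center[2])^2
  exp(-d2 / (2 * sigma^2))
}

#' Structural drug-response profiles
#'
#' How strongly a drug kills a cell in state `y`, normalized to peak 1.
#' BRAF/MEK inhibition targets a distribution centered on the proliferative
#' state, stretching (with reduced weight) into the invasive state, and
#' attenuated in the pigmented north-west; the hypothetical cancer treatment
#' (HCT) targets the invasive and URC states with a wider effectiveness span.
#'
#' @param y structural point (length-2) or n x 2 matrix inside the extent.
#' @param drug `"BRAF_MEKi"` or `"HCT"`.
#' @param atlas a [SubpopulationAtlas-class].
#' @param params a [ModelParams-class].
#'
#' @return Numeric vector of response values in `[0, 1]`.
#' @examples
#' drugResponse(c(0.2, 0.2), "BRAF_MEKi", defaultAtlas(), defaultParams())
#' @export
drugResponse <- function(y, drug, atlas, params) {
  y <- rbind2cols(y)
  .checkInExtent(y, atlas@extent)
  pmin(pmax(.rawResponse(y, drug, atlas, params), 0), 1)
}

.rawResponse <- function(y, drug, atlas, params) {
  r <- params@response
  switch(drug,
    BRAF_MEKi = {
      base <- gaussBump(y, anchorPosition(atlas, "proliferative"), r$sigma_B) +
        r$w_inv * gaussBump(y, anchorPosition(atlas, "invasive"), r$sigma_B)
      att <- 1 - r$att_depth *
        gaussBump(y, anchorPosition(atlas, "pigmented"), r$sigma_att)
      base * att
    },
    HCT = {
      gaussBump(y, anchorPosition(atlas, "invasive"), r$sigma_H) +
        gaussBump(y, anchorPosition(atlas, "URC"), r$sigma_H)
    },
    stop("configuration error: unknown drug id '", drug, "'", call. = FALSE)
  )
}

#' Per-drug dose rates at a given time
#'
#' Continuous mode doses the single listed drug for all `t >= startTime`;
#' sequential mode doses the first listed drug on `[startTime, switchTime)`
#' and the second from `switchTime` on; adaptive mode doses the first listed
#' drug whenever the adaptive controller is ON. At most one drug is dosed at
#' any time.
#'
#' @param t day, `t >= 0`.
#' @param schedule a [TreatmentSchedule-class].
#' @param adaptiveOn logical, current adaptive on/off state (ignored unless
#'   mode is adaptive).
#'
#' @return Named numeric `c(BRAF_MEKi = , HCT = )` of administration rates.
#' @export
doseSchedule <- function(t, schedule, adaptiveOn = TRUE) {
  stopifnot(t >= 0)
  out <- c(BRAF_MEKi = 0, HCT = 0)
  if (schedule@mode == "none" || t < schedule@startTime) return(out)
  rate <- function(d) unname(schedule@doseRate[d])
  active <- switch(schedule@mode,
    continuous = schedule@drugOrder[1],
    sequential = if (t < schedule@switchTime) schedule@drugOrder[1]
                 else schedule@drugOrder[2],
    adaptive = if (isTRUE(adaptiveOn)) schedule@drugOrder[1] else NA_character_
  )
  if (!is.na(active)) out[active] <- rate(active)
  out
}

#' Adaptive on/off decision with hysteresis
#'
#' Treatment turns ON when the burden exceeds `upperThreshold * initialMass`,
#' OFF when it drops below `lowerThreshold * initialMass`, and keeps the
#' previous state inside the band.
#'
#' @param currentMass current tumor burden (> 0 expected).
#' @param initialMass burden at treatment start (> 0).
#' @param prevState logical, previous on/off state.
#' @param schedule a [TreatmentSchedule-class].
#'
#' @return logical: dose ON (`TRUE`) or OFF (`FALSE`).
#' @export
adaptiveDecision <- function(currentMass, initialMass, prevState, schedule) {
  if (!is.finite(initialMass) || initialMass <= 0)
    stop("contract violation: nonpositive initial mass", call. = FALSE)
  if (currentMass > schedule@upperThreshold * initialMass) TRUE
  else if (currentMass < schedule@lowerThreshold * initialMass) FALSE
  else isTRUE(prevState)
}
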