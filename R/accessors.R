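#' Construct cell parameters
#'
#' Builds a [CellParameters-class] object from the reference-model defaults,
#' overriding any named constant.  The usual overrides are the two study
#' conductances, e.g. \code{cellParameters(gK1 = 2, gNa = 1)}.
#'
#' @param ... named scalar overrides of entries of [defaultCellConstants()].
#' @return a validated [CellParameters-class] object.
#' @examples
#' p <- cellParameters(gNa = 2)
#' gNa(p)
#' @export
cellParameters <- function(...) {
  v <- defaultCellConstants()
  over <- list(...)
  if (length(over)) {
    nm <- names(over)
    if (is.null(nm) || any(nm == ""))
      stop("all overrides must be named")
    bad <- setdiff(nm, names(v))
    if (length(bad))
      stop("unknown constants: ", paste(bad, collapse = ", "))
    v[nm] <- as.numeric(over)
  }
  new("CellParameters", values = v)
}

#' Extract the raw constants vector
#'
#' @param params a [CellParameters-class] object.
#' @return named numeric vector in the canonical (compiled-code) order.
#' @export
paramVector <- function(params) {
  stopifnot(is(params, "CellParameters"))
  params@values
}

#' Accessors for the study conductances
#'
#' @param params a [CellParameters-class] object.
#' @param value replacement conductance, uS.
#' @return the conductance in uS, or the modified object for the setters.
#' @name conductances
NULL

#' @rdname conductances
#' @export
gK1 <- function(params) unname(paramVector(params)["gK1"])

#' @rdname conductances
#' @export
gNa <- function(params) unname(paramVector(params)["gNa"])

#' @rdname conductances
#' @export
`gK1<-` <- function(params, value) {
  params@values["gK1"] <- value
  validObject(params)
  params
}

#' @rdname conductances
#' @export
`gNa<-` <- function(params, value) {
  params@values["gNa"] <- value
  validObject(params)
  params
}

#' Construct a cell state
#'
#' @param state named numeric vector of length 22 in canonical order.
#' @return a validated [CellState-class] object.
#' @export
cellState <- function(state) {
  if (is(state, "CellState")) return(state)
  new("CellState", state = state)
}

#' @describeIn cellState extract the named 22-vector.
#' @param x a [CellState-class] object.
#' @export
stateVector <- function(x) {
  if (is(x, "CellState")) x@state else x
}

#' Construct a fiber configuration
#'
#' @param nCells number of cells in the chain (default 100).
#' @param gGj gap-junction conductance per interface, uS (default 10).
#' @param params shared [CellParameters-class] (defaults).
#' @param cellLength cell length in um (74).
#' @return a validated [FiberConfig-class] object.
#' @export
fiberConfig <- function(nCells = 100, gGj = 10, params = cellParameters(),
                        cellLength = 74) {
  new("FiberConfig", nCells = as.integer(nCells), gGj = gGj,
      cellLength = cellLength, params = params, passive = FALSE,
      gm = NA_real_, eRest = NA_real_)
}

#' @describeIn fiberConfig number of cells.
#' @param config a [FiberConfig-class] object.
#' @export
nCells <- function(config) config@nCells

#' @describeIn fiberConfig coupling conductance (uS).
#' @export
gGj <- function(config) config@gGj

#' @describeIn fiberConfig the shared cell parameters.
#' @export
cellParams <- function(config) config@params

#' Construct a stimulus protocol
#'
#' Default values reflect the study design: 0.2 ms square pulses at 1 Hz,
#' first pulse at 5 ms, two consecutive pulses, inward (negative) current.
#'
#' @param amplitude per-cell pulse amplitude, nA (<= 0; inward negative).
#' @param duration pulse width, ms.
#' @param period pacing period, ms.
#' @param nPulses number of pulses.
#' @param onset time of first pulse onset, ms.
#' @param targetCells indices of stimulated cells (`1` for a single cell,
#'   `1:4` for the fiber protocol).
#' @return a validated [StimulusProtocol-class] object.
#' @export
stimulusProtocol <- function(amplitude, duration = 0.2, period = 1000,
                             nPulses = 2, onset = 5, targetCells = 1L) {
  new("StimulusProtocol", amplitude = amplitude, duration = duration,
      period = period, nPulses = as.integer(nPulses), onset = onset,
      targetCells = as.integer(targetCells))
}

#' @describeIn stimulusProtocol the pulse on/off times (ms) of the schedule,
#'   as a two-column matrix.
#' @param protocol a [StimulusProtocol-class] object.
#' @export
pulseWindows <- function(protocol) {
  if (protocol@nPulses == 0L)
    return(matrix(numeric(0), ncol = 2,
                  dimnames = list(NULL, c("on", "off"))))
  on <- protocol@onset + (seq_len(protocol@nPulses) - 1) * protocol@period
  cbind(on = on, off = on + protocol@duration)
}

setMethod("show", "CellParameters", function(object) {
  v <- object@values
  cat("CellParameters (22-state guinea-pig ventricular model)\n")
  cat(sprintf("  gK1 = %.4g uS, gNa = %.4g uS, Cm = %.4g nF\n",
              v["gK1"], v["gNa"], v["Cm"]))
  cat(sprintf("  [K]o = %.4g mM, kmK1 = %.4g mM, T = %g K\n",
              v["Ko"], v["kmK1"], v["T"]))
  cat(sprintf("  plus %d further reference-model constants\n",
              length(v) - 6L))
})

setMethod("show", "CellState", function(object) {
  y <- object@state
  cat("CellState: V =", format(y[["V"]], digits = 6), "mV;",
      "m =", format(y[["m"]], digits = 4),
      "h =", format(y[["h"]], digits = 4), "\n")
  cat("  [Na]i =", format(y[["Nai"]], digits = 5), "mM,",
      "[K]i =", format(y[["Ki"]], digits = 6), "mM,",
      "[Ca]i =", format(y[["Cai"]], digits = 4), "mM\n")
})

setMethod("show", "FiberConfig", function(object) {
  cat(sprintf("FiberConfig: %d cells x %d states, gGj = %.4g uS, Lc = %g um%s\n",
              object@nCells, 22L, object@gGj, object@cellLength,
              if (object@passive) " (passive membrane)" else ""))
  if (object@passive)
    cat(sprintf("  gm = %.4g uS, eRest = %.4g mV\n", object@gm, object@eRest))
  else
    cat(sprintf("  gK1 = %.4g uS, gNa = %.4g uS\n",
                gK1(object@params), gNa(object@params)))
})

setMethod("show", "StimulusProtocol", function(object) {
  cat(sprintf(
    "StimulusProtocol: %d pulse(s) of %.3g nA x %.3g ms, period %g ms, onset %g ms\n",
    object@nPulses, object@amplitude, object@duration, object@period,
    object@onset))
  cat("  target cells:", paste(object@targetCells, collapse = ", "), "\n")
})

setMethod("show", "SimulationTrace", function(object) {
  cat(sprintf("SimulationTrace: %d samples x %d cell(s), t in [%g, %g] ms\n",
              nrow(object@vm), ncol(object@vm), min(object@time),
              max(object@time)))
  cat(sprintf("  Vm range [%.3g, %.3g] mV; full states %s\n",
              min(object@vm), max(object@vm),
              if (is.null(object@states)) "not stored" else "stored"))
})

setMethod("show", "ThresholdResult", function(object) {
  if (object@excitable)
    cat(sprintf("ThresholdResult: %.4g nA (resolution %.3g nA, %d simulations)\n",
                object@threshold, object@resolution, object@nSimulations))
  else
    cat(sprintf("ThresholdResult: inexcitable up to %.4g nA (%d simulations)\n",
                -object@amplitudeCap, object@nSimulations))
})

setMethod("show", "SpaceConstantFit", function(object) {
  cat(sprintf(
    "SpaceConstantFit: lambda = %.4g cell lengths (A = %.4g mV, resid. norm %.3g mV, %d cells)\n",
    object@lambda, object@amplitude, object@residualNorm,
    length(object@cells)))
})
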