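#' @import methods
NULL

#' CellParameters: constants of the ventricular cell model
#'
#' Container for all constants of the 22-state ventricular myocyte model.
#' The conductances of the inward-rectifier potassium current (\code{gK1},
#' uS) and the fast sodium current (\code{gNa}, uS) are the free parameters
#' of this package; the remaining constants form the reference model's
#' complete bundle and default to the values of [defaultCellConstants()].
#'
#' @slot values named numeric vector of all model constants, in the fixed
#'   order required by the compiled right-hand side.
#' @seealso [cellParameters()], [gK1()], [gNa()]
#' @export
setClass("CellParameters", representation(values = "numeric"))

setValidity("CellParameters", function(object) {
  v <- object@values
  if (!identical(names(v), .paramOrder))
    return("constants must be a complete named vector in canonical order")
  pos <- c("gK1", "gNa", "Cm", "Ko", "kmK1", "T", "Nao", "Cao")
  if (any(!is.finite(v)))
    return("all constants must be finite")
  if (any(v[pos] <= 0))
    return(paste("these constants must be positive:",
                 paste(pos[v[pos] <= 0], collapse = ", ")))
  TRUE
})

#' CellState: state vector of one myocyte
#'
#' The 22 state variables of one cell: membrane potential \code{V} (mV),
#' the sodium gates \code{m} and \code{h}, the remaining gating variables
#' (all dimensionless, in [0, 1]) and the ionic concentrations (mM).
#'
#' @slot state named numeric vector of length 22 in canonical order.
#' @export
setClass("CellState", representation(state = "numeric"))

setValidity("CellState", function(object) {
  y <- object@state
  if (length(y) != 22L || !identical(names(y), .stateOrder))
    return("state must be a named 22-vector in canonical order")
  if (any(!is.finite(y))) return("state values must be finite")
  g <- y[.gateNames]
  if (any(g < 0 | g > 1)) return("gating variables must lie in [0, 1]")
  conc <- y[c("Nai", "Ki", "Cai", "Cads", "Caup", "Carel")]
  if (any(conc <= 0)) return("ion concentrations must be positive")
  TRUE
})

#' FiberConfig: a uniform monodomain fiber
#'
#' A chain of \code{nCells} identical cells coupled by linear gap-junction
#' conductances \code{gGj} (uS per cell-cell interface) with sealed
#' (no-flux) ends.  Parameters are spatially uniform.  When
#' \code{passive} is TRUE the membrane of every cell is a linear
#' conductance \code{gm} with reversal \code{eRest} (the analytic-cable
#' test fixture); the state layout is unchanged.
#'
#' @slot nCells number of cells (default 100).
#' @slot gGj coupling conductance per interface, uS (default 10).
#' @slot cellLength cell length, um (fixed at 74 in the study design).
#' @slot params shared [CellParameters-class].
#' @slot passive logical; linearized membrane instead of the ionic model.
#' @slot gm,eRest passive membrane conductance (uS) and rest potential (mV).
#' @export
setClass("FiberConfig", representation(
  nCells = "integer", gGj = "numeric", cellLength = "numeric",
  params = "CellParameters", passive = "logical", gm = "numeric",
  eRest = "numeric"))

setValidity("FiberConfig", function(object) {
  if (object@nCells < 2L) return("a fiber needs at least 2 cells")
  if (object@gGj < 0) return("gGj must be non-negative")
  if (object@cellLength <= 0) return("cell length must be positive")
  if (object@passive && object@gm <= 0)
    return("passive membrane conductance gm must be positive")
  TRUE
})

#' StimulusProtocol: square-pulse stimulus schedule
#'
#' A train of square current pulses.  Depolarizing (inward) stimulus
#' currents are negative by the outward-positive sign convention.
#'
#' @slot amplitude pulse amplitude per targeted cell, nA (<= 0).
#' @slot duration pulse duration, ms (default 0.2).
#' @slot period pulse period, ms (default 1000, i.e. 1 Hz pacing).
#' @slot nPulses number of pulses.
#' @slot onset time of the first pulse, ms.
#' @slot targetCells indices of the stimulated cells.
#' @export
setClass("StimulusProtocol", representation(
  amplitude = "numeric", duration = "numeric", period = "numeric",
  nPulses = "integer", onset = "numeric", targetCells = "integer"))

setValidity("StimulusProtocol", function(object) {
  if (object@duration <= 0) return("duration must be positive")
  if (object@nPulses > 1L && object@period <= object@duration)
    return("period must exceed pulse duration")
  if (object@amplitude > 0)
    return("depolarizing stimulus currents are negative (outward-positive convention)")
  if (object@nPulses < 0L) return("nPulses must be >= 0")
  if (length(object@targetCells) < 1L || any(object@targetCells < 1L))
    return("targetCells must be positive indices")
  TRUE
})

#' SimulationTrace: sampled output of a simulation
#'
#' @slot time sample times, ms (strictly increasing).
#' @slot vm matrix of membrane potentials, one row per sample, one column
#'   per cell (mV).
#' @slot states full state snapshots (matrix, columns in cell-major order)
#'   or NULL when only voltages were kept.
#' @slot protocol the [StimulusProtocol-class] that produced the trace.
#' @slot config the [FiberConfig-class] or [CellParameters-class] used.
#' @export
setClass("SimulationTrace", representation(
  time = "numeric", vm = "matrix", states = "ANY",
  protocol = "StimulusProtocol", config = "ANY", finalState = "numeric"))

setValidity("SimulationTrace", function(object) {
  if (length(object@time) != nrow(object@vm))
    return("time and vm are inconsistent")
  if (any(diff(object@time) <= 0)) return("time must be strictly increasing")
  if (any(!is.finite(object@vm))) return("vm contains non-finite values")
  TRUE
})

#' ThresholdResult: outcome of a stimulus-threshold search
#'
#' @slot threshold threshold amplitude, nA (negative), or NA when the
#'   preparation is inexcitable up to the amplitude cap.
#' @slot excitable logical flag.
#' @slot resolution search grid resolution, nA.
#' @slot nSimulations number of pacing simulations used by the search.
#' @slot amplitudeCap magnitude cap used to declare inexcitability, nA.
#' @export
setClass("ThresholdResult", representation(
  threshold = "numeric", excitable = "logical", resolution = "numeric",
  nSimulations = "integer", amplitudeCap = "numeric"))

#' SpaceConstantFit: exponential fit of a steady subthreshold profile
#'
#' @slot lambda space constant in cell lengths.
#' @slot amplitude fitted amplitude, mV.
#' @slot residualNorm residual sum-of-squares root of the fit, mV.
#' @slot cells cell indices included in the fit.
#' @slot deltaV end-of-pulse deviations from rest at those cells, mV.
#' @export
setClass("SpaceConstantFit", representation(
  lambda = "numeric", amplitude = "numeric", residualNorm = "numeric",
  cells = "integer", deltaV = "numeric"))

setValidity("SpaceConstantFit", function(object) {
  if (object@lambda <= 0) return("lambda must be positive")
  TRUE
})

#' PassiveFiberSpec: linearized-membrane fiber specification
#'
#' Specification of the passive test fixture: every cell's membrane current
#' is exactly \code{gm * (V - eRest)} (no gates, no rectification), so the
#' steady response to a sustained end current is the discrete-cable
#' solution in closed form.
#'
#' @slot gm linear membrane conductance per cell, uS.
#' @slot eRest resting potential, mV.
#' @slot Cm cell capacitance, nF.
#' @slot gGj coupling conductance, uS.
#' @slot nCells number of cells.
#' @export
setClass("PassiveFiberSpec", representation(
  gm = "numeric", eRest = "numeric", Cm = "numeric", gGj = "numeric",
  nCells = "integer"))

setValidity("PassiveFiberSpec", function(object) {
  if (object@gm <= 0 || object@Cm <= 0 || object@gGj <= 0)
    return("gm, Cm and gGj must be positive")
  if (object@nCells < 2L) return("a fiber needs at least 2 cells")
  TRUE
})
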