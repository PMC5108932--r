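#' Gap-junction interface currents
#'
#' For cell voltages \code{V[1..n]} returns the \code{n - 1} currents
#' flowing through each cell-cell interface,
#' \eqn{I_{gj}[i] = G_{gj}(V_i - V_{i+1})} (nA, positive from cell i to
#' cell i+1).  Sealed ends mean no current flows past the first or last
#' cell, so the coupling currents sum to zero over the fiber.
#'
#' @param V vector of membrane potentials, mV (one per cell).
#' @param gGj coupling conductance, uS.
#' @return numeric vector of length \code{length(V) - 1}, nA.
#' @export
gapCurrents <- function(V, gGj) {
  if (length(V) < 2L) stop("a fiber needs at least 2 cells")
  if (any(!is.finite(V))) stop("V must be finite")
  gGj * (V[-length(V)] - V[-1])
}

#' Broadcast a cell state across a fiber
#'
#' @param state a [CellState-class] object or named 22-vector.
#' @param nCells number of cells.
#' @return numeric vector of length \code{nCells * 22}, cell-major
#'   (all 22 states of cell 1, then cell 2, ...).
#' @export
broadcastState <- function(state, nCells) {
  y <- stateVector(state)
  if (length(y) != 22L) stop("cell state must have 22 components")
  rep(unname(y), nCells)
}

## internal: the stimulus vector (nA per cell) for a given protocol when
## the pulse is on
.stimVector <- function(protocol, nCells) {
  s <- numeric(nCells)
  tc <- protocol@targetCells
  if (any(tc > nCells)) stop("target cells outside the fiber")
  s[tc] <- protocol@amplitude
  s
}

## internal: passive parameter triple c(gm, eRest, Cm) for the C code
.passivePars <- function(config) {
  if (config@passive)
    c(config@gm, config@eRest, paramVector(config@params)[["Cm"]])
  else c(0, 0, 0)
}

#' Time derivative of a fiber state
#'
#' Evaluates the right-hand side of the monodomain chain: every cell obeys
#' \eqn{C_m\,dV_i/dt = G_{gj}(V_{i-1} - 2V_i + V_{i+1}) - I_{ion,i} -
#' I_{stim,i}} with one-sided coupling at the sealed ends, and all
#' non-voltage states evolve cell-locally.  With \code{gGj = 0} the fiber
#' derivative equals \code{nCells} independent single-cell derivatives.
#'
#' @param state flattened fiber state (length \code{nCells * 22},
#'   cell-major) or a [CellState-class] to broadcast.
#' @param t time, ms (autonomous system; solver-signature argument).
#' @param config a [FiberConfig-class] object.
#' @param stim per-cell external current, nA (length \code{nCells}; zero
#'   where unstimulated), or a single zero.
#' @return numeric vector of derivatives, same length and ordering as
#'   \code{state}.
#' @export
fiberDerivatives <- function(state, t = 0, config, stim = 0) {
  n <- config@nCells
  if (is(state, "CellState")) state <- broadcastState(state, n)
  if (length(state) != n * 22L)
    stop(sprintf("fiber state must have length %d (= %d cells x 22), got %d",
                 n * 22L, n, length(state)))
  if (length(stim) == 1L) stim <- rep(stim, n)
  if (length(stim) != n)
    stop("stimulus vector length must equal the number of cells")
  .Call(C_fiber_rhs, as.numeric(state),
        unname(paramVector(config@params)), config@gGj, as.numeric(stim),
        as.integer(config@passive), .passivePars(config))
}

#' Resting state of a fiber
#'
#' In a uniform fiber the single-cell rest point broadcast across all
#' cells is a rest point of the whole chain (no voltage gradients, so no
#' coupling currents).
#'
#' @param config a [FiberConfig-class] object.
#' @param ... passed to [restingState()].
#' @return flattened resting fiber state (length \code{nCells * 22}).
#' @export
fiberRestingState <- function(config, ...) {
  if (config@passive) {
    y <- .initialStateGuess()
    y["V"] <- config@eRest
    broadcastState(y, config@nCells)
  } else {
    broadcastState(restingState(config@params, ...), config@nCells)
  }
}
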