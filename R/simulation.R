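## Time integration of the cell and fiber systems with square-pulse
## stimulus scheduling.
##
## The integrator is deSolve's lsode, a variable-order implicit stiff
## method; the fiber Jacobian is block-tridiagonal, and with cell-major
## state ordering every coupling sits within a band of half-width 22, so
## a banded finite-difference Jacobian is used.  Integration is restarted
## exactly at each pulse on/off time so the square pulse is never smoothed
## across a step, and the on/off instants appear bit-exactly in the output
## grid.

## sampling grid: fineStep during each pulse, postStep through the
## post-pulse/upstroke window, coarseStep elsewhere
.sampleGrid <- function(t0, t1, windows, fineStep, postStep, coarseStep,
                        fineSpan) {
  pts <- seq(t0, t1, by = coarseStep)
  if (nrow(windows)) {
    for (k in seq_len(nrow(windows))) {
      on <- windows[k, 1]; off <- windows[k, 2]
      if (on > t1 || off < t0) next
      pts <- c(pts, seq(max(on, t0), min(off, t1), by = fineStep))
      postEnd <- min(on + fineSpan, t1)
      if (postEnd > off)
        pts <- c(pts, seq(min(off, t1), postEnd, by = postStep))
    }
  }
  sort(unique(c(pts, t1)))
}

## normalise (initial, config) into the internal simulation setup
.simSetup <- function(initial, config) {
  if (is(config, "CellParameters")) {
    n <- 1L; gGj <- 0; params <- config; passive <- FALSE
    pas <- c(0, 0, 0)
    if (is.null(initial)) initial <- restingState(params)
  } else if (is(config, "FiberConfig")) {
    n <- config@nCells; gGj <- config@gGj; params <- config@params
    passive <- config@passive; pas <- .passivePars(config)
    if (is.null(initial)) initial <- fiberRestingState(config)
  } else {
    stop("config must be a FiberConfig or CellParameters object")
  }
  if (is(initial, "CellState")) initial <- broadcastState(initial, n)
  if (length(initial) != n * 22L)
    stop("initial state length does not match the configuration")
  list(y0 = as.numeric(initial), n = n, gGj = gGj, params = params,
       passive = as.integer(passive), pas = pas)
}

#' Simulate a stimulated cell or fiber
#'
#' Integrates the model through a square-pulse stimulus schedule and
#' returns a sampled voltage trace.  The stiff solver (lsode) runs with
#' absolute and relative tolerances of 1e-6 by default; integration is
#' restarted at every pulse edge, and sampling is dense (0.01 ms) during
#' pulses and through the upstroke window so activation times are
#' resolved.
#'
#' @param initial initial state: a [CellState-class], a flattened fiber
#'   state, or NULL for the resting state.
#' @param protocol a [StimulusProtocol-class].
#' @param config a [FiberConfig-class], or a [CellParameters-class] for a
#'   single isolated cell.
#' @param tSpan integration window \code{c(t0, t1)} in ms; defaults to
#'   covering all pulses plus a 500 ms observation window.
#' @param atol,rtol solver tolerances.
#' @param saveStates keep full state snapshots (memory-heavy for fibers).
#' @param fineStep sampling step during pulses, ms.
#' @param postStep sampling step in the post-pulse window, ms.
#' @param coarseStep sampling step elsewhere, ms.
#' @param fineSpan length of the densely-sampled window after each pulse
#'   onset, ms (long enough to cover the propagating upstroke).
#' @return a [SimulationTrace-class] object.
#' @examples
#' \donttest{
#' prot <- stimulusProtocol(amplitude = -25, nPulses = 1)
#' tr <- runSimulation(NULL, prot, cellParameters(), tSpan = c(0, 400))
#' max(tr@vm)   # AP peak, about +20 mV
#' }
#' @export
runSimulation <- function(initial, protocol, config, tSpan = NULL,
                          atol = 1e-6, rtol = 1e-6, saveStates = FALSE,
                          fineStep = 0.01, postStep = 0.05,
                          coarseStep = 1, fineSpan = 60) {
  setup <- .simSetup(initial, config)
  n <- setup$n
  y <- setup$y0

  if (is.null(tSpan)) {
    tEnd <- protocol@onset +
      max(0, protocol@nPulses - 1L) * protocol@period + 500
    tSpan <- c(0, tEnd)
  }
  t0 <- tSpan[1]; t1 <- tSpan[2]
  win <- pulseWindows(protocol)
  win <- win[win[, 1] < t1 & win[, 2] > t0, , drop = FALSE]

  grid <- .sampleGrid(t0, t1, win, fineStep, postStep, coarseStep, fineSpan)
  ## segment boundaries: every pulse edge, plus a 1 ms window after each
  ## edge that is integrated with a bounded step (a square edge leaves the
  ## stimulated cells far from equilibrium, and an unrestricted first step
  ## there can wreck the Newton iteration)
  edges <- as.numeric(win)
  bounds <- sort(unique(c(t0, t1, edges, edges + 1)))
  bounds <- bounds[bounds >= t0 & bounds <= t1]
  stiffSeg <- function(a) {
    length(edges) > 0 && any(a >= edges - 1e-12 & a < edges + 1 - 1e-12)
  }

  parms <- unname(paramVector(setup$params))
  stimOn <- .stimVector(protocol, n)
  stimOff <- numeric(n)
  odefun <- function(t, y, parms)
    list(.Call(C_fiber_rhs, y, parms, setup$gGj, .currentStim,
               setup$passive, setup$pas))
  solverArgs <- if (n > 1L)
    list(method = "lsode", jactype = "bandint", bandup = 22L,
         banddown = 22L)
  else list(method = "lsoda")

  times <- numeric(0)
  vm <- NULL
  states <- NULL
  vcols <- 1L + seq(1L, by = 22L, length.out = n)

  for (k in seq_len(length(bounds) - 1L)) {
    a <- bounds[k]; b <- bounds[k + 1L]
    inPulse <- any(a >= win[, 1] - 1e-12 & a < win[, 2] - 1e-12)
    .currentStim <- if (inPulse) stimOn else stimOff
    ## interior sample points, keeping a safe distance from the segment
    ## endpoints and from each other (accumulated seq() rounding can
    ## produce near-duplicate output times, which the solver rejects)
    pts <- grid[grid > a + 1e-9 & grid < b - 1e-9]
    if (length(pts) > 1) pts <- pts[c(TRUE, diff(pts) > 1e-9)]
    segTimes <- c(a, pts, b)
    segArgs <- if (stiffSeg(a))
      list(maxsteps = 100000, hmax = 0.01) else list(maxsteps = 50000)
    sol <- suppressWarnings(do.call(deSolve::ode, c(list(
      y = y, times = segTimes, func = odefun, parms = parms,
      atol = atol, rtol = rtol), segArgs, solverArgs)))
    if (nrow(sol) < length(segTimes) || anyNA(sol[nrow(sol), ])) {
      ## bounded-step retry for rare step-size collapses
      sol <- suppressWarnings(do.call(deSolve::ode, c(list(
        y = y, times = segTimes, func = odefun, parms = parms,
        atol = atol, rtol = rtol, maxsteps = 300000, hmax = 0.05),
        solverArgs)))
    }
    if (nrow(sol) < length(segTimes) || anyNA(sol[nrow(sol), ]))
      stop(sprintf(paste(
        "stiff integration failed at t ~ %.3g ms (gK1 = %g, gNa = %g,",
        "gGj = %g uS)"), sol[nrow(sol), 1], gK1(setup$params),
        gNa(setup$params), setup$gGj))
    keep <- if (length(times)) -1L else seq_len(nrow(sol))
    times <- c(times, sol[keep, 1])
    vm <- rbind(vm, sol[keep, vcols, drop = FALSE])
    if (saveStates) states <- rbind(states, sol[keep, -1, drop = FALSE])
    y <- as.numeric(sol[nrow(sol), -1])
  }

  dimnames(vm) <- list(NULL, paste0("cell", seq_len(n)))
  new("SimulationTrace", time = times, vm = vm,
      states = states, protocol = protocol, config = config,
      finalState = y)
}

#' Accessors for simulation traces
#'
#' @param trace a [SimulationTrace-class] object.
#' @param cell cell index.
#' @return `traceTime`: sample times (ms); `traceVm`: the voltage of one
#'   cell (mV) or, with `cell = NULL`, the full time-by-cell matrix;
#'   `finalState`: the flattened state at the last sample.
#' @name trace-accessors
NULL

#' @rdname trace-accessors
#' @export
traceTime <- function(trace) trace@time

#' @rdname trace-accessors
#' @export
traceVm <- function(trace, cell = NULL) {
  if (is.null(cell)) trace@vm else trace@vm[, cell]
}

#' @rdname trace-accessors
#' @export
finalState <- function(trace) trace@finalState

#' Export a trace as a long data frame
#'
#' @param trace a [SimulationTrace-class] object.
#' @return data.frame with columns `time` (ms), `cell`, `Vm` (mV).
#' @export
traceAsDataFrame <- function(trace) {
  n <- ncol(trace@vm)
  data.frame(time = rep(trace@time, n),
             cell = rep(seq_len(n), each = length(trace@time)),
             Vm = as.vector(trace@vm))
}
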