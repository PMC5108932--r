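## Measurement protocols of the study: action-potential detection, stimulus
## thresholds for cells and fibers, conduction velocity, passive space
## constant and action-potential duration.

#' Detect an action potential in a voltage trace
#'
#' An action potential is counted when the membrane potential exceeds 0 mV
#' within the window: full APs overshoot to about +20 mV while subthreshold
#' responses stay below about -50 mV, so the 0 mV criterion separates the
#' two unambiguously.
#'
#' @param trace a [SimulationTrace-class] object.
#' @param cell cell index to inspect.
#' @param window time window \code{c(t0, t1)} in ms; default the whole
#'   trace.
#' @return logical.
#' @export
detectAP <- function(trace, cell = 1, window = NULL) {
  t <- trace@time
  if (is.null(window)) window <- range(t)
  sel <- t >= window[1] & t <= window[2]
  if (!any(sel)) stop("empty detection window")
  v <- if (is.null(cell)) trace@vm[sel, , drop = FALSE]
  else traceVm(trace, cell)[sel]
  max(v) > 0
}

## pacing run that requires every pulse of the protocol to elicit an AP at
## `detectCell` within its own detection window; simulates pulse by pulse
## and stops early on the first failure
.pacingSuccess <- function(config, protocol, detectCell, windowLen,
                           initial = NULL, coarseStep = 0.25) {
  win <- pulseWindows(protocol)
  nP <- nrow(win)
  tEnd <- win[nP, 1] + windowLen
  bounds <- c(0, if (nP > 1) win[-1, 1] else NULL, tEnd)
  y <- initial
  one <- methods::new("StimulusProtocol", amplitude = protocol@amplitude,
                      duration = protocol@duration,
                      period = protocol@period, nPulses = 1L,
                      onset = 0, targetCells = protocol@targetCells)
  for (k in seq_len(nP)) {
    one@onset <- win[k, 1]
    tr <- runSimulation(y, one, config,
                        tSpan = c(bounds[k], bounds[k + 1]),
                        coarseStep = coarseStep, fineStep = 0.05,
                        postStep = 0.1, fineSpan = 10)
    if (!detectAP(tr, detectCell,
                  window = c(win[k, 1], min(win[k, 1] + windowLen,
                                            bounds[k + 1]))))
      return(FALSE)
    y <- finalState(tr)
  }
  TRUE
}

## grid search for the smallest-magnitude amplitude (on a resolution grid)
## for which `success` holds: geometric bracketing followed by integer
## bisection, equivalent to a literal incremental scan because pacing
## success is monotone in the stimulus magnitude
.findThreshold <- function(success, resolution, cap, startGuess = NULL) {
  nSim <- 0L
  succ <- function(k) { nSim <<- nSim + 1L; success(-k * resolution) }
  kCap <- floor(cap / resolution)
  k <- if (!is.null(startGuess))
    max(1L, min(kCap, as.integer(ceiling(abs(startGuess) / resolution))))
  else max(1L, as.integer(ceiling(kCap / 256)))
  lo <- 0L; hi <- NA_integer_
  repeat {
    if (succ(k)) { hi <- k; break }
    lo <- k
    if (k >= kCap) break
    k <- min(kCap, k * 2L)
  }
  if (is.na(hi))
    return(new("ThresholdResult", threshold = NA_real_, excitable = FALSE,
               resolution = resolution, nSimulations = nSim,
               amplitudeCap = cap))
  while (hi - lo > 1L) {
    mid <- lo + (hi - lo) %/% 2L
    if (succ(mid)) hi <- mid else lo <- mid
  }
  new("ThresholdResult", threshold = -hi * resolution, excitable = TRUE,
      resolution = resolution, nSimulations = nSim, amplitudeCap = cap)
}

#' Stimulus-current threshold of an isolated cell
#'
#' Smallest-magnitude amplitude, on a 0.5 nA grid, of 0.2 ms square pulses
#' at 1 Hz for which two consecutive pulses each elicit an action
#' potential.  The search brackets geometrically and then bisects on the
#' amplitude grid, which returns the same grid value as a literal 0.5 nA
#' incremental scan (pacing success is monotone in pulse magnitude).
#'
#' @param params a [CellParameters-class] object.
#' @param resolution amplitude grid, nA.
#' @param nPulses number of consecutive pulses that must all fire.
#' @param duration,period,onset pulse shape and schedule, ms.
#' @param cap magnitude cap (nA) beyond which the cell is declared
#'   inexcitable; 1900 nA is 100 times the default-parameter threshold.
#' @param windowLen AP detection window after each pulse onset, ms.
#' @param startGuess optional starting amplitude for the bracketing (nA);
#'   results do not depend on it, only the number of simulations does.
#' @return a [ThresholdResult-class] object.
#' @export
findCellThreshold <- function(params = cellParameters(), resolution = 0.5,
                              nPulses = 2, duration = 0.2, period = 1000,
                              onset = 5, cap = 1900, windowLen = 50,
                              startGuess = NULL) {
  rest <- restingState(params)
  success <- function(amp) {
    prot <- stimulusProtocol(amplitude = amp, duration = duration,
                             period = period, nPulses = nPulses,
                             onset = onset, targetCells = 1L)
    .pacingSuccess(params, prot, detectCell = 1L, windowLen = windowLen,
                   initial = rest)
  }
  .findThreshold(success, resolution, cap, startGuess)
}

#' Stimulus-current threshold of a fiber
#'
#' As [findCellThreshold()], but the first four cells of the chain are
#' stimulated and success requires a propagating action potential: an AP
#' detected at a distal cell (cell 75 by default, far from both the
#' stimulated end and the sealed far end) after every pulse.
#'
#' @param config a [FiberConfig-class] object.
#' @param propagateCell distal cell whose activation defines propagation.
#' @param targetCells stimulated cells (default \code{1:4}).
#' @param windowLen detection window after each pulse onset, ms; the
#'   default spans most of the pacing cycle so slow decremental conduction
#'   still counts if it arrives.
#' @inheritParams findCellThreshold
#' @return a [ThresholdResult-class] object.
#' @export
findFiberThreshold <- function(config = fiberConfig(), resolution = 0.5,
                               nPulses = 2, duration = 0.2, period = 1000,
                               onset = 5, cap = 1900, windowLen = 900,
                               propagateCell = 75, targetCells = 1:4,
                               startGuess = NULL) {
  if (propagateCell > nCells(config))
    stop("propagation cell outside the fiber")
  rest <- fiberRestingState(config)
  success <- function(amp) {
    prot <- stimulusProtocol(amplitude = amp, duration = duration,
                             period = period, nPulses = nPulses,
                             onset = onset, targetCells = targetCells)
    .pacingSuccess(config, prot, detectCell = propagateCell,
                   windowLen = windowLen, initial = rest)
  }
  .findThreshold(success, resolution, cap, startGuess)
}

## activation time: instant of maximum dV/dt on the sampled upstroke,
## refined by quadratic interpolation; ties broken by earliest time
.activationTime <- function(t, v) {
  dv <- diff(v) / diff(t)
  tm <- (t[-1] + t[-length(t)]) / 2
  i <- which.max(dv)
  if (i > 1 && i < length(dv)) {
    ## vertex of the parabola through the three highest-slope samples
    x <- tm[(i - 1):(i + 1)]; yv <- dv[(i - 1):(i + 1)]
    den <- (yv[1] - 2 * yv[2] + yv[3])
    if (is.finite(den) && den < 0) {
      delta <- 0.5 * (yv[1] - yv[3]) / den
      if (abs(delta) <= 1) return(tm[i] + delta * (x[2] - x[1]))
    }
  }
  tm[i]
}

#' Conduction velocity of a propagating action potential
#'
#' Triggers a propagating AP with a single pulse at \code{factor} times the
#' fiber threshold applied to the first four cells, and divides the
#' distance between the measurement cells (50 cells of 74 um by default)
#' by the difference of their activation times.  Measuring between cells
#' 25 and 75 avoids the slow wave initiation at the stimulated end and the
#' sealed-end speed-up at the far end.
#'
#' @param config a [FiberConfig-class] object.
#' @param threshold fiber threshold amplitude, nA; when NULL it is measured
#'   first with [findFiberThreshold()].
#' @param factor stimulus amplitude as a multiple of threshold (1.5 by
#'   convention).
#' @param cells the two measurement cells.
#' @param onset pulse onset, ms.
#' @param window observation window after the pulse, ms.
#' @param ... passed to [findFiberThreshold()].
#' @return conduction velocity in cm/s, with the activation times and the
#'   threshold in attributes \code{"tAct"} and \code{"threshold"}.
#' @export
measureCV <- function(config = fiberConfig(), threshold = NULL,
                      factor = 1.5, cells = c(25, 75), onset = 5,
                      window = 300, ...) {
  if (is.null(threshold)) {
    thr <- findFiberThreshold(config, ...)
    if (!thr@excitable)
      stop(sprintf("fiber inexcitable (gK1 = %g, gNa = %g, gGj = %g uS)",
                   gK1(cellParams(config)), gNa(cellParams(config)),
                   gGj(config)))
    threshold <- thr@threshold
  }
  prot <- stimulusProtocol(amplitude = factor * threshold, nPulses = 1,
                           onset = onset, targetCells = 1:4)
  tr <- runSimulation(NULL, prot, config, tSpan = c(0, onset + window),
                      coarseStep = 1, fineStep = 0.01, postStep = 0.02,
                      fineSpan = window)
  t <- traceTime(tr)
  tAct <- vapply(cells, function(cc) {
    v <- traceVm(tr, cc)
    if (max(v) < 0)
      stop(sprintf(
        "no activation at cell %d at %.3g x threshold (gK1 = %g, gGj = %g)",
        cc, factor, gK1(cellParams(config)), gGj(config)))
    .activationTime(t, v)
  }, numeric(1))
  Lc <- config@cellLength * 1e-4                # um -> cm
  cv <- diff(cells) * Lc / (diff(tAct) / 1000)  # cm/s
  attr(cv, "tAct") <- tAct
  attr(cv, "threshold") <- threshold
  cv
}

#' Passive space constant of a fiber
#'
#' Applies a long (100 ms) subthreshold pulse to the first four cells,
#' takes the end-of-pulse voltage deviations from rest and fits a single
#' exponential decay \eqn{\Delta V_i = A e^{-i/\lambda}} over the cells
#' downstream of the stimulated set (the four stimulated cells and the
#' last five cells are excluded; the sealed far end distorts the profile).
#' The pulse amplitude defaults to 95 percent of the separately measured
#' 100 ms-pulse threshold, large enough for an accurate fit yet
#' subthreshold by construction (verified; an error instructs to reduce
#' the amplitude otherwise).
#'
#' @param config a [FiberConfig-class] object.
#' @param amplitude pulse amplitude (nA, negative); when NULL it is set to
#'   \code{ampFraction} times the 100 ms-pulse threshold (for a passive
#'   fiber, where no threshold exists, -1 nA is used; the response is
#'   linear in the amplitude).
#' @param ampFraction fraction of the long-pulse threshold to use.
#' @param duration pulse duration, ms (long enough to reach steady state).
#' @param onset pulse onset, ms.
#' @param thresholdResolution search grid for the long-pulse threshold, nA.
#' @param dropLast trailing cells excluded from the fit.
#' @return a [SpaceConstantFit-class] object (lambda in cell lengths).
#' @export
measureSpaceConstant <- function(config = fiberConfig(), amplitude = NULL,
                                 ampFraction = 0.95, duration = 100,
                                 onset = 5, thresholdResolution = 0.1,
                                 dropLast = 5) {
  n <- nCells(config)
  targets <- 1:4
  if (is.null(amplitude)) {
    if (config@passive) {
      amplitude <- -1
    } else {
      rest <- fiberRestingState(config)
      ## threshold criterion here: an AP anywhere in the fiber (a local,
      ## non-propagating AP already corrupts the passive profile, so the
      ## probe pulse must stay below local firing, not just below
      ## propagation)
      success <- function(amp) {
        prot <- stimulusProtocol(amplitude = amp, duration = duration,
                                 nPulses = 1, onset = onset,
                                 targetCells = targets)
        .pacingSuccess(config, prot, detectCell = NULL,
                       windowLen = duration + 300, initial = rest)
      }
      thr <- .findThreshold(success, thresholdResolution, cap = 1900)
      if (!thr@excitable)
        stop("no long-pulse threshold found below the amplitude cap")
      amplitude <- ampFraction * thr@threshold
    }
  }
  rest <- fiberRestingState(config)
  prot <- stimulusProtocol(amplitude = amplitude, duration = duration,
                           nPulses = 1, onset = onset,
                           targetCells = targets)
  tr <- runSimulation(rest, prot, config,
                      tSpan = c(0, onset + duration + 5),
                      coarseStep = 1, fineStep = 1, postStep = 1,
                      fineSpan = 0)
  if (max(traceVm(tr)) > 0)
    stop("the pulse triggered an action potential; reduce the amplitude")
  tOff <- onset + duration
  i <- which.min(abs(traceTime(tr) - tOff))
  vEnd <- traceVm(tr)[i, ]
  vRest <- rest[1 + (seq_len(n) - 1) * 22]
  dV <- abs(vEnd - vRest)

  cells <- (max(targets) + 1):(n - dropLast)
  y <- dV[cells]
  ## log-linear start values on the clearly-resolved part of the profile
  pos <- y > max(y) * 1e-4 & y > 0
  if (sum(pos) < 3) stop("steady-state deflection profile too flat to fit")
  lmfit <- stats::lm(log(y[pos]) ~ cells[pos])
  lam0 <- -1 / stats::coef(lmfit)[[2]]
  if (!is.finite(lam0) || lam0 <= 0) lam0 <- 5
  df <- data.frame(i = cells, y = y)
  fit <- stats::nls(y ~ A * exp(-(i - min(i)) / lambda), data = df,
                    start = list(A = y[1], lambda = lam0),
                    algorithm = "port",
                    lower = c(A = 0, lambda = 1e-3),
                    control = stats::nls.control(maxiter = 200,
                                                 warnOnly = FALSE))
  co <- stats::coef(fit)
  new("SpaceConstantFit", lambda = unname(co[["lambda"]]),
      amplitude = unname(co[["A"]]),
      residualNorm = sqrt(sum(stats::resid(fit)^2)),
      cells = as.integer(cells), deltaV = unname(y))
}

#' Action-potential duration
#'
#' Duration from the maximum-upstroke instant to the given repolarization
#' level (APD90 by default: 90 percent of the way from the AP peak back to
#' the pre-stimulus resting potential).  The trace must contain exactly
#' one action potential.
#'
#' @param trace a [SimulationTrace-class] object.
#' @param cell cell index.
#' @param level repolarization fraction (0.9 for APD90, 0.5 for APD50).
#' @return duration in ms.
#' @export
measureAPD <- function(trace, cell = 1, level = 0.9) {
  t <- traceTime(trace)
  v <- traceVm(trace, cell)
  up <- which(v[-1] > 0 & v[-length(v)] <= 0)
  if (length(up) == 0) stop("no action potential in the trace")
  if (length(up) > 1)
    stop("trace contains ", length(up), " action potentials; expected one")
  onset <- trace@protocol@onset
  rest <- v[max(1, max(which(t <= onset)))]
  peak <- max(v)
  tUp <- .activationTime(t, v)
  vTarget <- peak - level * (peak - rest)
  ## repolarization crossing is searched after the AP peak: mid-upstroke
  ## samples can already lie below shallow targets such as APD50
  tPeak <- t[which.max(v)]
  after <- which(t > tPeak & v < vTarget)
  if (!length(after))
    stop("no repolarization to the requested level within the trace")
  j <- min(after)
  ## linear interpolation of the downward crossing
  tCross <- if (j > 1 && v[j - 1] > vTarget)
    t[j - 1] + (v[j - 1] - vTarget) / (v[j - 1] - v[j]) * (t[j] - t[j - 1])
  else t[j]
  tCross - tUp
}
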