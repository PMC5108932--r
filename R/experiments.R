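## Parameter-sweep drivers for independent and reciprocal (tandem)
## modulation of the inward-rectifier and fast-sodium conductances.

#' SweepSpec: a conductance parameter sweep
#'
#' Describes one sweep: the modulation mode (independent G_Na, independent
#' G_K1, or reciprocal tandem modulation at a fixed G_K1:G_Na ratio), the
#' conductance grid, the gap-junction conductances to cross it with, the
#' preparation (isolated cell or fiber) and the measurements requested.
#' In reciprocal mode the grid indexes G_K1 and the sodium conductance is
#' derived from the ratio: ratio a:b means (G_K1, G_Na) = (g, g b/a).
#'
#' @slot mode one of "independent-GNa", "independent-GK1", "reciprocal".
#' @slot ratio length-2 numeric, the G_K1:G_Na weights (reciprocal mode).
#' @slot grid conductance grid, uS (G_Na grid for independent-GNa,
#'   otherwise the G_K1 grid).
#' @slot gGj gap-junction conductances to sweep, uS (ignored for cells).
#' @slot measure subset of c("threshold", "cv", "lambda").
#' @slot preparation "cell" or "fiber".
#' @slot nCells fiber length used when preparation is "fiber".
#' @export
setClass("SweepSpec", representation(
  mode = "character", ratio = "numeric", grid = "numeric",
  gGj = "numeric", measure = "character", preparation = "character",
  nCells = "integer"))

setValidity("SweepSpec", function(object) {
  if (!object@mode %in% c("independent-GNa", "independent-GK1",
                          "reciprocal"))
    return("unknown sweep mode")
  if (object@mode == "reciprocal" &&
      (length(object@ratio) != 2L || any(object@ratio <= 0)))
    return("reciprocal mode needs a positive length-2 ratio")
  if (!all(object@measure %in% c("threshold", "cv", "lambda")))
    return("measure must be a subset of threshold, cv, lambda")
  if (!object@preparation %in% c("cell", "fiber"))
    return("preparation must be 'cell' or 'fiber'")
  if (any(object@grid <= 0) || any(object@gGj < 0))
    return("conductance grids must be positive")
  TRUE
})

#' @describeIn SweepSpec-class constructor.
#' @param mode,ratio,grid,gGj,measure,preparation,nCells see slots.
#' @export
sweepSpec <- function(mode, grid, ratio = c(1, 1), gGj = 10,
                      measure = "threshold", preparation = "fiber",
                      nCells = 100) {
  new("SweepSpec", mode = mode, ratio = as.numeric(ratio),
      grid = as.numeric(grid), gGj = as.numeric(gGj), measure = measure,
      preparation = preparation, nCells = as.integer(nCells))
}

setMethod("show", "SweepSpec", function(object) {
  cat(sprintf("SweepSpec: %s (%s), %d grid point(s) x %d gGj value(s)\n",
              object@mode, object@preparation, length(object@grid),
              length(object@gGj)))
  if (object@mode == "reciprocal")
    cat("  ratio GK1:GNa =", paste(object@ratio, collapse = ":"), "\n")
  cat("  measurements:", paste(object@measure, collapse = ", "), "\n")
})

## (gK1, gNa) pair for one grid value under the sweep mode
.sweepPoint <- function(spec, g) {
  switch(spec@mode,
    "independent-GNa" = c(gK1 = 0.5, gNa = g),
    "independent-GK1" = c(gK1 = g, gNa = 0.5),
    "reciprocal" = c(gK1 = g, gNa = g * spec@ratio[2] / spec@ratio[1]))
}

#' Run a conductance sweep
#'
#' Executes the requested measurements at every (grid, gGj) combination of
#' the spec and returns one row per point.  Threshold searches are
#' warm-started from the previous grid point (the result is independent of
#' the start; only the simulation count changes).  Failures at individual
#' points are recorded in the \code{error} column and the sweep continues.
#'
#' @param spec a [SweepSpec-class] object.
#' @param cap inexcitability amplitude cap, nA.
#' @param verbose print one line per completed point.
#' @return data.frame with columns gK1, gNa, gGj, threshold (nA; NA when
#'   inexcitable), excitable, cv (cm/s), lambda (cell lengths), nSims,
#'   error.
#' @export
runSweep <- function(spec, cap = 1900, verbose = FALSE) {
  rows <- list()
  for (ggj in spec@gGj) {
    lastThr <- NULL
    for (g in spec@grid) {
      pt <- .sweepPoint(spec, g)
      params <- cellParameters(gK1 = pt[["gK1"]], gNa = pt[["gNa"]])
      row <- data.frame(gK1 = pt[["gK1"]], gNa = pt[["gNa"]], gGj = ggj,
                        threshold = NA_real_, excitable = NA,
                        cv = NA_real_, lambda = NA_real_, nSims = 0L,
                        error = NA_character_)
      res <- tryCatch({
        thr <- NULL
        if (any(c("threshold", "cv") %in% spec@measure)) {
          thr <- if (spec@preparation == "cell")
            findCellThreshold(params, cap = cap, startGuess = lastThr)
          else
            findFiberThreshold(fiberConfig(nCells = spec@nCells,
                                           gGj = ggj, params = params),
                               cap = cap, startGuess = lastThr)
          row$threshold <- thr@threshold
          row$excitable <- thr@excitable
          row$nSims <- row$nSims + thr@nSimulations
          if (thr@excitable) lastThr <- thr@threshold
        }
        if ("cv" %in% spec@measure && isTRUE(thr@excitable) &&
            spec@preparation == "fiber") {
          cv <- measureCV(fiberConfig(nCells = spec@nCells, gGj = ggj,
                                      params = params),
                          threshold = thr@threshold)
          row$cv <- as.numeric(cv)
          row$nSims <- row$nSims + 1L
        }
        if ("lambda" %in% spec@measure && spec@preparation == "fiber") {
          fit <- measureSpaceConstant(fiberConfig(nCells = spec@nCells,
                                                  gGj = ggj,
                                                  params = params))
          row$lambda <- fit@lambda
        }
        row
      }, error = function(e) {
        row$error <- conditionMessage(e)
        row
      })
      rows[[length(rows) + 1L]] <- res
      if (verbose)
        message(sprintf(
          "gK1=%g gNa=%g gGj=%g: thr=%s cv=%s lambda=%s %s",
          res$gK1, res$gNa, res$gGj, format(res$threshold),
          format(res$cv), format(res$lambda),
          if (is.na(res$error)) "" else paste("ERROR:", res$error)))
    }
  }
  do.call(rbind, rows)
}

#' Classify the shape of a response curve
#'
#' Counts sign changes of successive differences, ignoring differences
#' smaller than the noise floor (differences below the threshold-search
#' resolution are quantization artifacts).
#'
#' @param y measurement values along an ordered grid (>= 4 points).
#' @param noiseFloor magnitude below which a difference is ignored.
#' @return one of "monotone-increasing", "monotone-decreasing",
#'   "biphasic", "triphasic", "multiphasic" or "flat".
#' @export
summarizeShape <- function(y, noiseFloor = 0.5) {
  y <- y[!is.na(y)]
  if (length(y) < 4) stop("need at least 4 points to classify a shape")
  d <- diff(y)
  d <- d[abs(d) > noiseFloor]
  if (!length(d)) return("flat")
  sgn <- sign(d)
  changes <- sum(diff(sgn) != 0)
  if (changes == 0) {
    if (sgn[1] > 0) "monotone-increasing" else "monotone-decreasing"
  } else if (changes == 1) "biphasic"
  else if (changes == 2) "triphasic"
  else "multiphasic"
}
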