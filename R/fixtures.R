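## Synthetic inputs and analytic oracles: the passive (linearized-membrane)
## fiber and the closed-form discrete-cable space constant used to verify
## the measurement machinery independently of the ionic model.

#' Construct a passive fiber specification
#'
#' @param gm linear membrane conductance per cell, uS.
#' @param eRest resting potential, mV.
#' @param Cm cell capacitance, nF.
#' @param gGj coupling conductance, uS.
#' @param nCells number of cells.
#' @return a [PassiveFiberSpec-class] object.
#' @export
passiveFiberSpec <- function(gm = 0.5, eRest = -90, Cm = 0.095, gGj = 10,
                             nCells = 100) {
  new("PassiveFiberSpec", gm = gm, eRest = eRest, Cm = Cm, gGj = gGj,
      nCells = as.integer(nCells))
}

#' Build the passive fiber fixture
#'
#' Returns a [FiberConfig-class] whose membrane current is exactly
#' \eqn{g_m (V - E_{rest})} in every cell, usable by [runSimulation()] and
#' [measureSpaceConstant()] unchanged: the fiber assembly, integrator and
#' fitting code run bit-identically to the production (ionic) path, while
#' the steady response to a sustained end current is the discrete-cable
#' solution known in closed form ([analyticSpaceConstant()]).  The state
#' keeps its 22-slot-per-cell layout; the 21 non-voltage slots are frozen.
#'
#' @param spec a [PassiveFiberSpec-class] object.
#' @return a [FiberConfig-class] with \code{passive = TRUE}.
#' @export
passiveFiberFixture <- function(spec = passiveFiberSpec()) {
  validObject(spec)
  new("FiberConfig", nCells = spec@nCells, gGj = spec@gGj,
      cellLength = 74, params = cellParameters(Cm = spec@Cm),
      passive = TRUE, gm = spec@gm, eRest = spec@eRest)
}

#' Closed-form space constant of the discrete cable
#'
#' In the resistive ladder of cells with membrane conductance \eqn{g_m}
#' coupled by \eqn{G_{gj}}, the steady-state voltage deviation decays by a
#' fixed factor \eqn{1/r} per cell, where \eqn{r > 1} solves
#' \eqn{r + 1/r = 2 + g_m/G_{gj}}.  The space constant in cell lengths is
#' \eqn{\lambda = 1/\ln r}; in the continuum limit
#' \eqn{g_m/G_{gj} \to 0} it approaches \eqn{\sqrt{G_{gj}/g_m}}, the
#' classical linear-cable result.
#'
#' @param gm membrane conductance per cell, uS.
#' @param gGj coupling conductance, uS.
#' @return space constant in cell lengths.
#' @export
analyticSpaceConstant <- function(gm, gGj) {
  if (any(gm <= 0) || any(gGj <= 0)) stop("gm and gGj must be positive")
  x <- gm / gGj
  r <- ((2 + x) + sqrt(x^2 + 4 * x)) / 2
  1 / log(r)
}

#' Default conductance grids of the study
#'
#' Builds the sweep specifications for the figure-reproducing parameter
#' sweeps: independent G_Na modulation over 0.2-5 uS, independent G_K1
#' modulation over 0.3-5 uS (0.1 uS steps across the 1-1.5 uS
#' excitability boundary, 0.25 uS elsewhere), reciprocal modulation at
#' G_K1:G_Na ratios 1:2, 1:1 and 2:1, and the eight gap-junction
#' conductances spanning 0.1-20 uS.
#'
#' @param preparation "cell" or "fiber" (applied to every spec).
#' @param measure measurements requested (applied to every spec).
#' @return named list of [SweepSpec-class] objects: `independentGNa`,
#'   `independentGK1`, `reciprocal12`, `reciprocal11`, `reciprocal21`.
#' @export
buildPaperGrids <- function(preparation = "fiber", measure = "threshold") {
  gNaGrid <- c(0.2, 0.5, 1, 1.5, 2, 2.5, 3, 3.5, 4, 4.5, 5)
  gK1Grid <- sort(unique(c(0.3, seq(0.5, 5, by = 0.25),
                           seq(1, 1.5, by = 0.1))))
  gGjGrid <- c(0.1, 0.2, 0.3, 0.5, 1, 2, 10, 20)
  ratios <- list(reciprocal12 = c(1, 2), reciprocal11 = c(1, 1),
                 reciprocal21 = c(2, 1))
  out <- list(
    independentGNa = sweepSpec("independent-GNa", gNaGrid, gGj = 10,
                               measure = measure,
                               preparation = preparation),
    independentGK1 = sweepSpec("independent-GK1", gK1Grid, gGj = 10,
                               measure = measure,
                               preparation = preparation))
  for (nm in names(ratios))
    out[[nm]] <- sweepSpec("reciprocal", gK1Grid, ratio = ratios[[nm]],
                           gGj = gGjGrid, measure = measure,
                           preparation = preparation)
  out
}
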