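## Model constants for the 22-state guinea-pig ventricular myocyte.
##
## Unit system used throughout the package: mV, ms, nA, uS (micro-Siemens),
## nF, mM.  These are self-consistent (uS * mV = nA; nF * mV/ms = nA), and
## every conductance/current below is expressed per cell, not per unit area.
##
## The parameter ordering here is a binary contract with src/fiberode.c
## (enum P_GK1 .. P_NARATIOMH); do not reorder.

.paramOrder <- c(
  "gK1", "gNa", "kmK1", "Ko", "Cm", "T", "Nao", "Cao",
  "gKr1", "gKr2", "gKs", "gto", "gtos", "gpNa", "gbNa", "gbCa",
  "iNaKmax", "KmK", "KmNa",
  "kNaCa", "gammaNaCa", "nNaCa", "dNaCa", "FRANaCa",
  "FrICa", "PCaL", "PCaK", "PCaNa",
  "speed_d", "speed_f",
  "Kmf2", "Rf2", "Kmf2ds", "Rf2ds",
  "KmCaCyt", "KmCaDs", "KmRel", "KleakRate", "ActRateMax",
  "InactRateBase", "InactRateCa",
  "SpeedRelSlow", "VSpeedRel",
  "alphaUp", "betaUp", "Kcyca", "Kxcs", "Ksrca", "Ktrans",
  "radius", "length", "ViRatio", "VdsRatio", "VrelRatio", "VupRatio",
  "KdecayDs",
  "alphaCalmod", "betaCalmod", "CalmodTot", "alphaTrop", "betaTrop",
  "TropTot",
  "PkNa", "naRatioMh", "rectK1"
)

## state ordering per cell; also a binary contract with src/fiberode.c
.stateOrder <- c(
  "V", "m", "h", "d", "f", "f2", "f2ds", "s", "r", "xr1", "xr2", "xs",
  "ActFrac", "ProdFrac",
  "Nai", "Ki", "Cai", "Cads", "Caup", "Carel", "CaCalmod", "CaTrop"
)

.gateNames <- c("m", "h", "d", "f", "f2", "f2ds", "s", "r", "xr1", "xr2",
                "xs", "ActFrac", "ProdFrac")
.concNames <- c("Nai", "Ki", "Cai", "Cads", "Caup", "Carel", "CaCalmod",
                "CaTrop")

## physical constants
.RGAS <- 8314.472      # mJ mol^-1 K^-1
.FARADAY <- 96485.3415 # C mol^-1

#' Default constants of the ventricular cell model
#'
#' Returns the complete named vector of constants of the 22-state
#' guinea-pig ventricular myocyte model used by this package, at the
#' reference model's default values.  The maximal conductances of the
#' inward-rectifier potassium current (\code{gK1}) and the fast sodium
#' current (\code{gNa}) both default to 0.5 uS; the cell capacitance is
#' 0.095 nF, temperature 310 K and external potassium 5.4 mM.
#'
#' Rate constants are expressed per second (the model's native form);
#' volumes derive from a cylindrical cell of radius 12 um and length 74 um.
#'
#' @return Named numeric vector of length 65.
#' @seealso [cellParameters()] for the user-facing parameter container,
#'   [writeCellConstants()] for JSON serialization.
#' @export
defaultCellConstants <- function() {
  p <- c(
    gK1 = 0.5, gNa = 0.5, kmK1 = 10, Ko = 5.4, Cm = 9.5e-2, T = 310,
    Nao = 140, Cao = 2,
    gKr1 = 0.0021, gKr2 = 0.0013, gKs = 0.0026, gto = 0.005, gtos = 0,
    gpNa = 0.004, gbNa = 6e-4, gbCa = 2.5e-4,
    iNaKmax = 0.7, KmK = 1, KmNa = 40,
    kNaCa = 5e-4, gammaNaCa = 0.5, nNaCa = 3, dNaCa = 0, FRANaCa = 0.001,
    FrICa = 1, PCaL = 0.1, PCaK = 0.002, PCaNa = 0.01,
    speed_d = 3, speed_f = 0.3,
    Kmf2 = 2e-4, Rf2 = 1, Kmf2ds = 0.001, Rf2ds = 20,
    KmCaCyt = 5e-4, KmCaDs = 0.01, KmRel = 250, KleakRate = 0.05,
    ActRateMax = 500, InactRateBase = 60, InactRateCa = 500,
    SpeedRelSlow = 5, VSpeedRel = -50,
    alphaUp = 0.4, betaUp = 0.03, Kcyca = 3e-4, Kxcs = 0.4, Ksrca = 0.5,
    Ktrans = 50,
    radius = 0.012, length = 0.074, ViRatio = 0.49, VdsRatio = 0.1,
    VrelRatio = 0.1, VupRatio = 0.01,
    KdecayDs = 10,
    alphaCalmod = 1e5, betaCalmod = 50, CalmodTot = 0.02,
    alphaTrop = 1e5, betaTrop = 200, TropTot = 0.05,
    PkNa = 0.03, naRatioMh = 0.12,
    rectK1 = 1.25
  )
  stopifnot(identical(names(p), .paramOrder))
  p
}

## quiescent-neighbourhood starting point; restingState() refines it
.initialStateGuess <- function() {
  y <- c(
    V = -92.849333, m = 0.0016203, h = 0.9944036, d = 1.5e-8, f = 1,
    f2 = 0.9349197, f2ds = 0.9651958, s = 0.9948645, r = 1.4e-8,
    xr1 = 1.03e-5, xr2 = 2e-7, xs = 0.001302,
    ActFrac = 0.0042614, ProdFrac = 0.4068154,
    Nai = 7.3321223, Ki = 136.5644281, Cai = 1.4e-5, Cads = 1.88e-5,
    Caup = 0.4531889, Carel = 0.4481927,
    CaCalmod = 5.555e-4, CaTrop = 3.542e-4
  )
  stopifnot(identical(names(y), .stateOrder))
  y
}

#' Thermal voltage RT/F
#'
#' @param T absolute temperature (K).
#' @return RT/F in mV (about 26.71 mV at 310 K).
#' @export
thermalVoltage <- function(T = 310) .RGAS * T / .FARADAY

#' Nernst equilibrium potential
#'
#' @param cOut,cIn outer and inner concentrations (mM).
#' @param z ionic valence.
#' @param T absolute temperature (K).
#' @return equilibrium potential in mV.
#' @export
nernstPotential <- function(cOut, cIn, z = 1, T = 310) {
  if (any(cOut <= 0) || any(cIn <= 0))
    stop("Nernst potential requires positive concentrations")
  thermalVoltage(T) / z * log(cOut / cIn)
}

#' Write or read the model constants as JSON
#'
#' Serializes the full constants vector (see [defaultCellConstants()]) so a
#' run configuration can be archived alongside its results and re-read
#' exactly.
#'
#' @param params a [CellParameters-class] object (or NULL for defaults).
#' @param path file path of the JSON document.
#' @return `writeCellConstants` returns `path` invisibly;
#'   `readCellConstants` returns a [CellParameters-class] object.
#' @export
writeCellConstants <- function(params = NULL, path) {
  if (is.null(params)) params <- cellParameters()
  jsonlite::write_json(as.list(paramVector(params)), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeCellConstants
#' @export
readCellConstants <- function(path) {
  x <- unlist(jsonlite::read_json(path, simplifyVector = TRUE))
  miss <- setdiff(.paramOrder, names(x))
  if (length(miss))
    stop("constants file is missing entries: ", paste(miss, collapse = ", "))
  do.call(cellParameters, as.list(x[.paramOrder]))
}
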