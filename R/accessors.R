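#' Accessors for catchlink S4 containers
#'
#' @param object a [PmfProfile-class], [EfficiencyImage-class] or
#'   [OrientationField-class] object.
#' @name accessors
NULL

#' @describeIn accessors reaction-coordinate grid (Angstrom).
#' @export
setGeneric("pmfGrid", function(object) standardGeneric("pmfGrid"))
#' @describeIn accessors PMF values on the grid.
#' @export
setGeneric("pmfValues", function(object) standardGeneric("pmfValues"))
#' @describeIn accessors energy unit of a PMF.
#' @export
setGeneric("energyUnit", function(object) standardGeneric("energyUnit"))
#' @describeIn accessors WHAM convergence report (list).
#' @export
setGeneric("convergenceInfo", function(object) standardGeneric("convergenceInfo"))
#' @describeIn accessors clamped pixelwise efficiency map.
#' @export
setGeneric("efficiencyMap", function(object) standardGeneric("efficiencyMap"))
#' @describeIn accessors unclamped pixelwise efficiency map.
#' @export
setGeneric("rawEfficiencyMap", function(object) standardGeneric("rawEfficiencyMap"))
#' @describeIn accessors corrected FRET image Fc.
#' @export
setGeneric("correctedFret", function(object) standardGeneric("correctedFret"))
#' @describeIn accessors sensitized-emission proportionality constant G.
#' @export
setGeneric("gFactor", function(object) standardGeneric("gFactor"))
#' @describeIn accessors validity mask.
#' @export
setGeneric("validityMask", function(object) standardGeneric("validityMask"))
#' @describeIn accessors per-pixel orientation (radians, axial).
#' @export
setGeneric("orientationMap", function(object) standardGeneric("orientationMap"))
#' @describeIn accessors dominant structure-tensor eigenvalue image.
#' @export
setGeneric("tensorEnergy", function(object) standardGeneric("tensorEnergy"))

setMethod("pmfGrid", "PmfProfile", function(object) object@xi)
setMethod("pmfValues", "PmfProfile", function(object) object@pmf)
setMethod("energyUnit", "PmfProfile", function(object) object@unit)
setMethod("convergenceInfo", "PmfProfile", function(object) object@convergence)
setMethod("validityMask", "PmfProfile", function(object) object@reliable)

setMethod("efficiencyMap", "EfficiencyImage", function(object) object@E)
setMethod("rawEfficiencyMap", "EfficiencyImage", function(object) object@rawE)
setMethod("correctedFret", "EfficiencyImage", function(object) object@Fc)
setMethod("gFactor", "EfficiencyImage", function(object) object@G)
setMethod("validityMask", "EfficiencyImage", function(object) object@mask)

setMethod("orientationMap", "OrientationField", function(object) object@theta)
setMethod("tensorEnergy", "OrientationField", function(object) object@l1)
setMethod("validityMask", "OrientationField", function(object) object@valid)
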