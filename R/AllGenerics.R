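#' @rdname AirwayTree-accessors
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' @rdname AirwayTree-accessors
#' @export
setGeneric("nBranches", function(x) standardGeneric("nBranches"))

#' @rdname AirwayTree-accessors
#' @export
setGeneric("nTerminals", function(x) standardGeneric("nTerminals"))

#' @rdname AirwayTree-accessors
#' @export
setGeneric("terminalNodes", function(x) standardGeneric("terminalNodes"))

#' @rdname AirwayTree-accessors
#' @export
setGeneric("internalNodes", function(x) standardGeneric("internalNodes"))

#' @rdname AirwayTree-accessors
#' @export
setGeneric("branchTable", function(x) standardGeneric("branchTable"))

#' @rdname AirwayTree-accessors
#' @export
setGeneric("resistances", function(x) standardGeneric("resistances"))

#' @rdname AirwayTree-accessors
#' @export
setGeneric("radii", function(x) standardGeneric("radii"))

#' @rdname AirwayTree-accessors
#' @export
setGeneric("branchLengths", function(x) standardGeneric("branchLengths"))

#' @rdname blockPartition
#' @export
setGeneric("blockPartition", function(x) standardGeneric("blockPartition"))

#' @rdname incidenceMatrix
#' @export
setGeneric("incidenceMatrix", function(x) standardGeneric("incidenceMatrix"))

#' @rdname subtreeTerminalSets
#' @export
setGeneric("subtreeTerminalSets", function(x) standardGeneric("subtreeTerminalSets"))

#' @rdname subtreeMaps
#' @export
setGeneric("subtreeMaps", function(x) standardGeneric("subtreeMaps"))

#' @rdname buildLaplacian
#' @export
setGeneric("buildLaplacian", function(x) standardGeneric("buildLaplacian"))

#' @rdname solveFixedPressure
#' @export
setGeneric("solveFixedPressure", function(x, dPTerminal, ...)
  standardGeneric("solveFixedPressure"))

#' @rdname SpectralDecomposition-accessors
#' @export
setGeneric("eigenValues", function(x) standardGeneric("eigenValues"))

#' @rdname SpectralDecomposition-accessors
#' @export
setGeneric("eigenVectors", function(x) standardGeneric("eigenVectors"))
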