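# Generics. Statistic generics live with their methods in statistics.R.

#' @export
setGeneric("canonicalKey", function(x) standardGeneric("canonicalKey"))

#' @export
setGeneric("nLeaves", function(x) standardGeneric("nLeaves"))

#' @export
setGeneric("shapeKeys", function(x) standardGeneric("shapeKeys"))

#' @export
setGeneric("nShapes", function(x) standardGeneric("nShapes"))

#' @export
setGeneric("writeNewick", function(x, ...) standardGeneric("writeNewick"))

#' @export
setGeneric("nniNeighbors", function(x, ...) standardGeneric("nniNeighbors"))

#' @export
setGeneric("shapeSpace", function(x) standardGeneric("shapeSpace"))

#' @export
setGeneric("adjacencyMatrix", function(x) standardGeneric("adjacencyMatrix"))

#' @export
setGeneric("nodeDegrees", function(x) standardGeneric("nodeDegrees"))

#' @export
setGeneric("laplacianMatrix", function(x) standardGeneric("laplacianMatrix"))

#' @export
setGeneric("distanceMatrix",
           function(x, ...) standardGeneric("distanceMatrix"))

#' @export
setGeneric("spectralBounds",
           function(x, kind, ...) standardGeneric("spectralBounds"))
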