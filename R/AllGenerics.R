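#' Accessors for the package's S4 classes
#'
#' Slot accessors: \code{elementVector}/\code{siteMatrix}/\code{rnaSequence}
#' for \linkS4class{TernaryVector}; \code{siteCoordinates}/
#' \code{siteCharges}/\code{structureLabel}/\code{torusRadius} for
#' \linkS4class{TorusStructure}; \code{latticePoints}/\code{latticeBounds}
#' for \linkS4class{TorusLattice}; \code{scoreValues}/\code{scoreMethod}
#' for \linkS4class{ScoreVector}; \code{slopeEstimate}/\code{slopeSE}/
#' \code{pValue}/\code{signedFit}/\code{axisPair} for
#' \linkS4class{AxisRegression}.
#'
#' @param x an object of one of the package's classes.
#' @return The accessed component.
#' @name accessors
#' @rdname accessors
#' @export
setGeneric("elementVector", function(x) standardGeneric("elementVector"))

#' @rdname accessors
#' @export
setGeneric("siteMatrix", function(x) standardGeneric("siteMatrix"))

#' @rdname accessors
#' @export
setGeneric("rnaSequence", function(x) standardGeneric("rnaSequence"))

#' @rdname accessors
#' @export
setGeneric("siteCoordinates", function(x) standardGeneric("siteCoordinates"))

#' @rdname accessors
#' @export
setGeneric("siteCharges", function(x) standardGeneric("siteCharges"))

#' @rdname accessors
#' @export
setGeneric("structureLabel", function(x) standardGeneric("structureLabel"))

#' @rdname accessors
#' @export
setGeneric("torusRadius", function(x) standardGeneric("torusRadius"))

#' @rdname accessors
#' @export
setGeneric("latticePoints", function(x) standardGeneric("latticePoints"))

#' @rdname accessors
#' @export
setGeneric("latticeBounds", function(x) standardGeneric("latticeBounds"))

#' @rdname accessors
#' @export
setGeneric("scoreValues", function(x) standardGeneric("scoreValues"))

#' @rdname accessors
#' @export
setGeneric("scoreMethod", function(x) standardGeneric("scoreMethod"))

#' @rdname accessors
#' @export
setGeneric("slopeEstimate", function(x) standardGeneric("slopeEstimate"))

#' @rdname accessors
#' @export
setGeneric("slopeSE", function(x) standardGeneric("slopeSE"))

#' @rdname accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname accessors
#' @export
setGeneric("signedFit", function(x) standardGeneric("signedFit"))

#' @rdname accessors
#' @export
setGeneric("axisPair", function(x) standardGeneric("axisPair"))
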