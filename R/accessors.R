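#' Accessors for dgspect classes
#'
#' Slot access for the S4 containers. \code{activity} and \code{lesionMask}
#' return the 5-D (x,y,z,R,K) arrays of a \linkS4class{GatedPhantom};
#' \code{attenuation} the 4-D per-respiratory-phase attenuation maps;
#' \code{counts} / \code{expectedCounts} the gated sinograms of a
#' \linkS4class{ProjectionSet}; \code{volumes} the cardiac-gated volumes of a
#' \linkS4class{GatedReconstruction}; \code{displacement} the (x,y,z,3)
#' vector field of a \linkS4class{DVFField}; \code{az} the ROC area of an
#' \linkS4class{ObserverResult}.
#'
#' @param object an object of the corresponding class.
#' @return the slot content (see description).
#' @name accessors
#' @aliases activity attenuation lesionMask counts expectedCounts volumes
#'   displacement az objectiveTrace
NULL

#' @rdname accessors
#' @export
setGeneric("activity", function(object) standardGeneric("activity"))
#' @rdname accessors
#' @export
setMethod("activity", "GatedPhantom", function(object) object@activity)

#' @rdname accessors
#' @export
setGeneric("attenuation", function(object) standardGeneric("attenuation"))
#' @rdname accessors
#' @export
setMethod("attenuation", "GatedPhantom", function(object) object@attenuation)

#' @rdname accessors
#' @export
setGeneric("lesionMask", function(object) standardGeneric("lesionMask"))
#' @rdname accessors
#' @export
setMethod("lesionMask", "GatedPhantom", function(object) object@lesionMask)

#' @rdname accessors
#' @export
setGeneric("counts", function(object) standardGeneric("counts"))
#' @rdname accessors
#' @export
setMethod("counts", "ProjectionSet", function(object) object@counts)

#' @rdname accessors
#' @export
setGeneric("expectedCounts", function(object) standardGeneric("expectedCounts"))
#' @rdname accessors
#' @export
setMethod("expectedCounts", "ProjectionSet", function(object) object@expected)

#' @rdname accessors
#' @export
setGeneric("volumes", function(object) standardGeneric("volumes"))
#' @rdname accessors
#' @export
setMethod("volumes", "GatedReconstruction", function(object) object@volumes)

#' @rdname accessors
#' @export
setGeneric("objectiveTrace", function(object) standardGeneric("objectiveTrace"))
#' @rdname accessors
#' @export
setMethod("objectiveTrace", "GatedReconstruction",
          function(object) object@objective)

#' @rdname accessors
#' @export
setGeneric("displacement", function(object) standardGeneric("displacement"))
#' @rdname accessors
#' @export
setMethod("displacement", "DVFField", function(object) object@displacement)

#' @rdname accessors
#' @export
setGeneric("az", function(object) standardGeneric("az"))
#' @rdname accessors
#' @export
setMethod("az", "ObserverResult", function(object) object@az)
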