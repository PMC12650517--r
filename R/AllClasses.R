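#' @useDynLib dgspect, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' GatedPhantom: dual-gated ground-truth activity and attenuation
#'
#' Holds one activity volume per (respiratory gate r, cardiac gate k), one
#' attenuation map per respiratory gate, and the lesion voxel masks.
#' Activity is relative uptake (arbitrary units), attenuation is the linear
#' attenuation coefficient at 140 keV in cm^-1.
#'
#' @slot activity 5-D numeric array (nx, ny, nz, R, K), nonnegative.
#' @slot attenuation 4-D numeric array (nx, ny, nz, R), nonnegative, cm^-1.
#' @slot lesionMask 5-D logical array (nx, ny, nz, R, K).
#' @slot config the \code{\link{phantomConfig}} list used to generate it.
#' @exportClass GatedPhantom
setClass("GatedPhantom",
  representation(activity = "array", attenuation = "array",
                 lesionMask = "array", config = "list"),
  validity = function(object) {
    msg <- character()
    da <- dim(object@activity)
    dm <- dim(object@attenuation)
    if (length(da) != 5L) msg <- c(msg, "activity must be a 5-D array (x,y,z,R,K)")
    if (length(dm) != 4L) msg <- c(msg, "attenuation must be a 4-D array (x,y,z,R)")
    if (length(da) == 5L && length(dm) == 4L) {
      if (!all(da[1:4] == dm)) msg <- c(msg, "activity/attenuation grid or gate mismatch")
      if (!identical(dim(object@lesionMask), da))
        msg <- c(msg, "lesionMask must match activity dimensions")
    }
    if (any(object@activity < 0)) msg <- c(msg, "activity must be nonnegative")
    if (any(object@attenuation < 0)) msg <- c(msg, "attenuation must be nonnegative")
    if (length(msg)) msg else TRUE
  })

#' SystemModel: acquisition geometry plus attenuation handling
#'
#' Encapsulates the projector H of the imaging model: parallel-beam geometry
#' with depth-dependent Gaussian blur, and the attenuation mode used inside
#' the system matrix (matched per respiratory phase, averaged over phases,
#' or none).
#'
#' @slot geometry a \code{\link{systemGeometry}} list.
#' @slot attenuationMode one of "matched", "averaged", "none".
#' @slot attenuationMaps 4-D array (x,y,z,R) for "matched", 3-D array for
#'   "averaged", NULL for "none".
#' @slot scatterTerm optional expected-scatter sinogram set added to the
#'   forward model (NULL means zero).
#' @exportClass SystemModel
setClass("SystemModel",
  representation(geometry = "list", attenuationMode = "character",
                 attenuationMaps = "ANY", scatterTerm = "ANY"),
  validity = function(object) {
    msg <- character()
    mode <- object@attenuationMode
    if (!mode %in% c("matched", "averaged", "none"))
      msg <- c(msg, "attenuationMode must be matched, averaged or none")
    m <- object@attenuationMaps
    if (mode == "matched" && (is.null(m) || length(dim(m)) != 4L))
      msg <- c(msg, "matched mode requires a 4-D (x,y,z,R) attenuation array")
    if (mode == "averaged" && (is.null(m) || length(dim(m)) != 3L))
      msg <- c(msg, "averaged mode requires a single 3-D attenuation map")
    if (mode == "none" && !is.null(m))
      msg <- c(msg, "attenuation mode 'none' must not carry attenuation maps")
    if (length(msg)) msg else TRUE
  })

#' ProjectionSet: gated sinograms
#'
#' Counts indexed by (transaxial bin, axial slice, view, respiratory gate,
#' cardiac gate). \code{counts} holds the Poisson realization, \code{expected}
#' the noise-free expectations on the same scale.
#'
#' @slot counts 5-D numeric array (nbin_t, nbin_z, n_views, R, K).
#' @slot expected 5-D numeric array, same shape.
#' @slot geometry the \code{\link{systemGeometry}} used.
#' @slot totalCounts expected photons summed over all gates.
#' @slot scaleFactor counts-per-activity scaling applied so the summed
#'   expectation equals \code{totalCounts}; divide reconstructions by it to
#'   return to activity units.
#' @slot seed integer RNG seed used for the Poisson draw.
#' @exportClass ProjectionSet
setClass("ProjectionSet",
  representation(counts = "array", expected = "array", geometry = "list",
                 totalCounts = "numeric", scaleFactor = "numeric",
                 seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@counts)) != 5L)
      msg <- c(msg, "counts must be a 5-D array (t, z, view, R, K)")
    if (!identical(dim(object@counts), dim(object@expected)))
      msg <- c(msg, "counts and expected must have identical dimensions")
    if (any(object@counts < 0)) msg <- c(msg, "counts must be nonnegative")
    if (length(msg)) msg else TRUE
  })

#' GatedReconstruction: cardiac-gated volumes for one respiratory phase
#'
#' @slot volumes 4-D array (nx, ny, nz, K) of nonnegative voxel values.
#' @slot respPhase respiratory gate index the reconstruction belongs to.
#' @slot params the \code{\link{reconParams}} used.
#' @slot objective penalized log-likelihood trace, one value per iteration.
#' @exportClass GatedReconstruction
setClass("GatedReconstruction",
  representation(volumes = "array", respPhase = "integer", params = "list",
                 objective = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@volumes)) != 4L)
      msg <- c(msg, "volumes must be a 4-D array (x,y,z,K)")
    if (any(object@volumes < 0)) msg <- c(msg, "volumes must be nonnegative")
    if (length(object@objective) && any(!is.finite(object@objective)))
      msg <- c(msg, "objective trace must be finite")
    if (length(msg)) msg else TRUE
  })

#' DVFField: deformation vector field between two respiratory phases
#'
#' Per-voxel displacement (in voxels) mapping the content of the source
#' phase into the frame of the target phase.
#'
#' @slot displacement 4-D array (nx, ny, nz, 3): x, y, z components.
#' @slot sourcePhase source respiratory gate i.
#' @slot targetPhase target respiratory gate j.
#' @exportClass DVFField
setClass("DVFField",
  representation(displacement = "array", sourcePhase = "integer",
                 targetPhase = "integer"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@displacement)
    if (length(d) != 4L || d[4] != 3L)
      msg <- c(msg, "displacement must be (nx, ny, nz, 3)")
    if (any(!is.finite(object@displacement)))
      msg <- c(msg, "displacement must be finite everywhere")
    if (length(msg)) msg else TRUE
  })

#' RespSummedImage: cardiac-summed image for one respiratory phase
#'
#' @slot volume 3-D nonnegative array, the sum over cardiac gates.
#' @slot respPhase respiratory gate index.
#' @exportClass RespSummedImage
setClass("RespSummedImage",
  representation(volume = "array", respPhase = "integer"),
  validity = function(object) {
    if (any(object@volume < 0)) "volume must be nonnegative" else TRUE
  })

#' ObserverResult: channelized Hotelling observer output
#'
#' @slot decisionPresent decision variables for lesion-present realizations.
#' @slot decisionAbsent decision variables for lesion-absent realizations.
#' @slot az area under the ROC curve (rank-sum estimator).
#' @slot channelMatrix n x 4 matrix of channel responses (present then absent).
#' @slot internalNoiseLevel internal-noise variance scale.
#' @slot seed RNG seed used for the internal noise.
#' @exportClass ObserverResult
setClass("ObserverResult",
  representation(decisionPresent = "numeric", decisionAbsent = "numeric",
                 az = "numeric", channelMatrix = "matrix",
                 internalNoiseLevel = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@az < 0 || object@az > 1) msg <- c(msg, "az must lie in [0,1]")
    if (!length(object@decisionPresent) || !length(object@decisionAbsent))
      msg <- c(msg, "both decision ensembles must be nonempty")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "GatedPhantom", function(object) {
  d <- dim(object@activity)
  cat("GatedPhantom:", paste(d[1:3], collapse = "x"), "voxels,",
      d[4], "respiratory x", d[5], "cardiac gates\n")
  cat("  voxel size:", object@config$voxel_size, "cm;",
      "lesion:", if (is.null(object@config$lesion)) "none"
                 else object@config$lesion$location, "\n")
})

setMethod("show", "SystemModel", function(object) {
  g <- object@geometry
  cat("SystemModel:", g$n_views, "views /", g$arc_degrees, "deg, bins",
      paste(g$detector_bins, collapse = "x"), "\n")
  cat("  attenuation mode:", object@attenuationMode,
      "; blur:", if (g$blur_enabled) "on" else "off", "\n")
})

setMethod("show", "ProjectionSet", function(object) {
  d <- dim(object@counts)
  cat("ProjectionSet:", d[3], "views,", d[4], "resp x", d[5], "cardiac gates,",
      "bins", d[1], "x", d[2], "\n")
  cat("  total counts (realized):", sum(object@counts), "\n")
})

setMethod("show", "GatedReconstruction", function(object) {
  d <- dim(object@volumes)
  cat("GatedReconstruction: resp phase", object@respPhase, ",", d[4],
      "cardiac gates,", paste(d[1:3], collapse = "x"), "voxels\n")
})

setMethod("show", "DVFField", function(object) {
  cat("DVFField:", object@targetPhase, "<-", object@sourcePhase,
      "; max |d| =", signif(max(abs(object@displacement)), 4), "voxels\n")
})

setMethod("show", "ObserverResult", function(object) {
  cat("ObserverResult: Az =", signif(object@az, 4), "(",
      length(object@decisionPresent), "present /",
      length(object@decisionAbsent), "absent )\n")
})
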