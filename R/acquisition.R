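#' Acquisition geometry
#'
#' Parallel-beam circular-orbit geometry. The default blur calibration
#' (intercept 0.20 cm, slope 0.039 cm per cm depth) gives a system
#' resolution of about 1.3 cm FWHM at the 28.5 cm rotation radius, typical
#' of a low-energy high-resolution collimator.
#'
#' The projector assumes detector bins congruent with the voxel grid: the
#' transaxial bin count equals the transaxial grid size, the axial bin count
#' the number of slices, and \code{bin_size} equals the voxel size.
#'
#' @param n_views number of projection views.
#' @param arc_degrees orbit arc (360 for a full circle).
#' @param detector_bins integer pair (transaxial, axial).
#' @param bin_size detector bin size in cm (= voxel size).
#' @param rotation_radius orbit radius in cm; must exceed the phantom's
#'   transaxial half-extent.
#' @param blur_fwhm_intercept,blur_fwhm_slope depth-dependent resolution
#'   model: FWHM(depth) = intercept + slope * depth, in cm.
#' @param blur_enabled logical; disable for idealized ray sums.
#' @return a list of class \code{SystemGeometry}.
#' @export
systemGeometry <- function(n_views = 64L, arc_degrees = 360,
                           detector_bins = c(64L, 64L), bin_size = 0.634,
                           rotation_radius = 28.5,
                           blur_fwhm_intercept = 0.20,
                           blur_fwhm_slope = 0.039,
                           blur_enabled = TRUE) {
  stopifnot(n_views >= 1L, bin_size > 0, rotation_radius > 0,
            length(detector_bins) == 2L)
  if (rotation_radius <= detector_bins[1] * bin_size / 2)
    stop("rotation_radius must exceed the transaxial half-extent")
  g <- list(n_views = as.integer(n_views), arc_degrees = arc_degrees,
            detector_bins = as.integer(detector_bins), bin_size = bin_size,
            rotation_radius = rotation_radius,
            blur_fwhm_intercept = blur_fwhm_intercept,
            blur_fwhm_slope = blur_fwhm_slope,
            blur_enabled = isTRUE(blur_enabled))
  class(g) <- "SystemGeometry"
  g
}

#' Construct a system model
#'
#' Binds a geometry to an attenuation-correction mode: "matched" carries one
#' attenuation map per respiratory phase (MAC), "averaged" a single
#' phase-averaged map (AAC), "none" no attenuation.
#'
#' @param geometry a \code{\link{systemGeometry}}.
#' @param attenuationMode "matched", "averaged" or "none".
#' @param attenuationMaps 4-D (x,y,z,R) array, 3-D volume, or NULL,
#'   according to the mode.
#' @param scatterTerm optional expected scatter sinogram set (NULL = zero).
#' @return a \linkS4class{SystemModel}.
#' @export
systemModel <- function(geometry, attenuationMode = c("matched", "averaged",
                                                      "none"),
                        attenuationMaps = NULL, scatterTerm = NULL) {
  attenuationMode <- match.arg(attenuationMode)
  methods::new("SystemModel", geometry = unclass(geometry),
               attenuationMode = attenuationMode,
               attenuationMaps = attenuationMaps, scatterTerm = scatterTerm)
}

viewAngles <- function(geometry) {
  (seq_len(geometry$n_views) - 1) * geometry$arc_degrees /
    geometry$n_views * pi / 180
}

# attenuation map used inside H for one respiratory phase (may be zeros)
selectMu <- function(system, resp_phase, dim3) {
  switch(system@attenuationMode,
    matched = {
      dm <- dim(system@attenuationMaps)
      if (resp_phase < 1 || resp_phase > dm[4])
        stop("resp_phase out of range for matched attenuation maps")
      m <- system@attenuationMaps[, , , resp_phase, drop = FALSE]
      dim(m) <- dm[1:3]
      m
    },
    averaged = system@attenuationMaps,
    none = array(0, dim3))
}

# Precomputed per-view attenuation survival factors (rotated frame); NULL
# for attenuation mode "none". Reused across iterations by the solvers.
attenCache <- function(system, resp_phase, dim3) {
  if (system@attenuationMode == "none") return(NULL)
  mu <- selectMu(system, resp_phase, dim3)
  if (!all(dim(mu) == dim3)) stop("attenuation map shape mismatch")
  g <- system@geometry
  lapply(viewAngles(g), function(a)
    cpp_atten_view(mu, as.integer(dim3), a, g$bin_size))
}

# forward/backprojection over a view subset with a prebuilt cache
projectViewsC <- function(vol, system, views, cache) {
  g <- system@geometry
  d <- dim(vol)
  ang <- viewAngles(g)
  out <- array(0, c(d[1], d[3], length(views)))
  for (i in seq_along(views)) {
    A <- if (is.null(cache)) NULL else cache[[views[i]]]
    out[, , i] <- cpp_project_view(vol, A, as.integer(d), ang[views[i]],
                                   g$bin_size, g$rotation_radius,
                                   g$blur_fwhm_intercept, g$blur_fwhm_slope,
                                   g$blur_enabled)
  }
  out
}

backprojectViewsC <- function(sino_sub, system, views, cache, dim3) {
  g <- system@geometry
  ang <- viewAngles(g)
  out <- array(0, dim3)
  nb <- dim(sino_sub)[1:2]
  for (i in seq_along(views)) {
    A <- if (is.null(cache)) NULL else cache[[views[i]]]
    m <- sino_sub[, , i]
    dim(m) <- nb
    out <- out + cpp_backproject_view(m, A, as.integer(dim3),
                                      ang[views[i]], g$bin_size,
                                      g$rotation_radius,
                                      g$blur_fwhm_intercept,
                                      g$blur_fwhm_slope, g$blur_enabled)
  }
  out
}

#' Forward projection (the system operator H)
#'
#' For each view the volume is rotated to the view angle about the body
#' axis; each constant-depth plane is attenuated (half-voxel
#' self-attenuation convention) and blurred with a Gaussian whose FWHM grows
#' linearly with distance to the detector, then accumulated into the
#' detector plane and scaled by the voxel length. Linear in the activity and
#' exactly matched to \code{\link{backProject}}.
#'
#' @param activity nonnegative 3-D volume (x,y,z).
#' @param system a \linkS4class{SystemModel}.
#' @param resp_phase respiratory gate selecting the matched attenuation map
#'   (ignored for "averaged"/"none").
#' @return sinogram array (transaxial bin, axial slice, view).
#' @export
forwardProject <- function(activity, system, resp_phase = 1L) {
  g <- system@geometry
  d <- dim(activity)
  if (any(is.na(activity))) stop("activity contains NaN/NA")
  if (is.null(d) || length(d) != 3L) stop("activity must be a 3-D array")
  if (d[1] != g$detector_bins[1] || d[3] != g$detector_bins[2])
    stop("volume dimensions do not match detector bins")
  cache <- attenCache(system, resp_phase, d)
  projectViewsC(activity, system, seq_len(g$n_views), cache)
}

#' Backprojection (the adjoint operator)
#'
#' Exact adjoint of \code{\link{forwardProject}} under the same attenuation
#' mode and respiratory phase: the inner-product identity
#' \code{<Hx, y> == <x, H'y>} holds to floating-point accuracy.
#'
#' @param sinogram array (transaxial bin, axial slice, view).
#' @param system a \linkS4class{SystemModel}.
#' @param resp_phase respiratory gate selecting the matched attenuation map.
#' @return a 3-D volume.
#' @export
backProject <- function(sinogram, system, resp_phase = 1L) {
  g <- system@geometry
  d <- dim(sinogram)
  if (any(is.na(sinogram))) stop("sinogram contains NaN/NA")
  if (is.null(d) || length(d) != 3L || d[3] != g$n_views)
    stop("sinogram shape does not match geometry")
  dim3 <- as.integer(c(d[1], d[1], d[2]))
  cache <- attenCache(system, resp_phase, dim3)
  backprojectViewsC(sinogram, system, seq_len(g$n_views), cache, dim3)
}

#' Add a kernel-based scatter estimate to a sinogram
#'
#' Models scatter as a broad Gaussian redistribution in the detector plane:
#' \code{(1-f) * P + f * G(P)} per view, where the kernel columns are
#' normalized so every source bin redistributes exactly its own counts
#' (per-view totals are conserved).
#'
#' @param sinogram array (transaxial, axial, view) or a single view matrix.
#' @param scatter_fraction scatter-to-total fraction f in [0, 1).
#' @param kernel_fwhm_cm FWHM of the scatter kernel in cm.
#' @param bin_size detector bin size in cm.
#' @return sinogram of the same shape.
#' @export
addKernelScatter <- function(sinogram, scatter_fraction, kernel_fwhm_cm = 10,
                             bin_size = 0.634) {
  if (scatter_fraction < 0 || scatter_fraction >= 1)
    stop("scatter_fraction must lie in [0, 1)")
  if (scatter_fraction == 0) return(sinogram)
  convMat <- function(n) {
    sigma <- kernel_fwhm_cm / 2.354820045 / bin_size
    W <- exp(-0.5 * outer(seq_len(n), seq_len(n), "-")^2 / sigma^2)
    sweep(W, 2, colSums(W), "/")  # column-normalized: mass-preserving
  }
  one <- function(p, Kt, Kz)
    (1 - scatter_fraction) * p + scatter_fraction * (Kt %*% p %*% t(Kz))
  d <- dim(sinogram)
  if (length(d) == 2L) return(one(sinogram, convMat(d[1]), convMat(d[2])))
  Kt <- convMat(d[1]); Kz <- convMat(d[2])
  out <- sinogram
  for (v in seq_len(d[3])) out[, , v] <- one(sinogram[, , v], Kt, Kz)
  out
}

#' Simulate a dual-gated Poisson acquisition
#'
#' Computes noise-free sinograms for every (respiratory, cardiac) gate with
#' the phase-matched attenuation maps (the ground-truth physics always uses
#' the matched map), optionally adds a kernel scatter estimate, scales the
#' ensemble so the summed expectation equals \code{total_counts}, and draws
#' independent Poisson counts.
#'
#' @param phantom a \linkS4class{GatedPhantom}.
#' @param geometry a \code{\link{systemGeometry}}.
#' @param total_counts expected photons over all gates (default 8e6).
#' @param seed integer RNG seed for the Poisson draw.
#' @param scatter_fraction scatter-to-total fraction (0 disables scatter).
#' @param scatter_fwhm_cm scatter kernel FWHM in cm.
#' @return a \linkS4class{ProjectionSet} with both noisy counts and the
#'   scaled noise-free expectations.
#' @export
simulateAcquisition <- function(phantom, geometry, total_counts = 8e6,
                                seed = 1L, scatter_fraction = 0.3,
                                scatter_fwhm_cm = 10) {
  if (total_counts <= 0) stop("total_counts must be positive")
  act <- phantom@activity
  d <- dim(act)
  R <- d[4]; K <- d[5]
  sys <- systemModel(geometry, "matched", phantom@attenuation)
  g <- unclass(geometry)
  E <- array(0, c(g$detector_bins[1], g$detector_bins[2], g$n_views, R, K))
  for (r in seq_len(R)) {
    cache <- attenCache(sys, r, d[1:3])
    for (k in seq_len(K)) {
      p <- projectViewsC(act[, , , r, k], sys, seq_len(g$n_views), cache)
      if (scatter_fraction > 0)
        p <- addKernelScatter(p, scatter_fraction, scatter_fwhm_cm,
                              g$bin_size)
      E[, , , r, k] <- p
    }
  }
  s <- sum(E)
  scale <- if (s > 0) total_counts / s else 1
  E <- E * scale
  set.seed(as.integer(seed))
  cnt <- array(stats::rpois(length(E), E), dim(E))
  methods::new("ProjectionSet", counts = cnt, expected = E,
               geometry = unclass(geometry), totalCounts = total_counts,
               scaleFactor = scale, seed = as.integer(seed))
}
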