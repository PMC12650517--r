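#' Sum reconstructed cardiac gates for one respiratory phase
#'
#' Voxelwise sum of all K cardiac-gated volumes, used to raise the count
#' level before respiratory motion estimation (the per-bin dual-gated count
#' is too low for reliable optical flow).
#'
#' @param volumes 4-D array (x, y, z, K) or a \linkS4class{GatedReconstruction}.
#' @param resp_phase respiratory gate label carried on the result.
#' @return a \linkS4class{RespSummedImage}.
#' @export
sumCardiac <- function(volumes, resp_phase = 1L) {
  if (methods::is(volumes, "GatedReconstruction")) {
    resp_phase <- volumes@respPhase
    volumes <- volumes@volumes
  }
  d <- dim(volumes)
  if (length(d) != 4L) stop("expected a 4-D (x,y,z,K) array")
  s <- slice4(volumes, 1L)
  if (d[4] > 1) for (k in 2:d[4]) s <- s + slice4(volumes, k)
  methods::new("RespSummedImage", volume = s,
               respPhase = as.integer(resp_phase))
}

# central-difference gradient, one-sided at the borders
gradient3 <- function(x) {
  d <- dim(x)
  g <- vector("list", 3)
  for (ax in 1:3) {
    n <- d[ax]
    if (n == 1L) {  # flat axis: no gradient
      g[[ax]] <- array(0, d)
      next
    }
    fwd <- lapply(d, seq_len); bwd <- fwd
    fwd[[ax]] <- pmin(seq_len(n) + 1L, n)
    bwd[[ax]] <- pmax(seq_len(n) - 1L, 1L)
    step <- (pmin(seq_len(n) + 1L, n) - pmax(seq_len(n) - 1L, 1L))
    num <- do.call(`[`, c(list(x), fwd, list(drop = FALSE))) -
      do.call(`[`, c(list(x), bwd, list(drop = FALSE)))
    dim(num) <- d
    stepArr <- aperm(array(step, c(n, d[-ax])),
                     order(c(ax, seq_along(d)[-ax])))
    g[[ax]] <- num / stepArr
  }
  g
}

# one-step optical-flow displacement field mapping phase i into phase j:
# d = (Img_j - Img_i) grad(Img_i) / (|grad Img_i|^2 + (Img_j - Img_i)^2)
dvfEq5 <- function(img_j, img_i) {
  if (!identical(dim(img_j), dim(img_i))) stop("image shape mismatch")
  delta <- img_j - img_i
  g <- gradient3(img_i)
  denom <- g[[1]]^2 + g[[2]]^2 + g[[3]]^2 + delta^2
  out <- array(0, c(dim(img_i), 3))
  ok <- denom > 0
  for (c in 1:3) {
    comp <- array(0, dim(img_i))
    comp[ok] <- delta[ok] * g[[c]][ok] / denom[ok]
    out[, , , c] <- comp
  }
  out
}

#' Estimate the respiratory deformation field between two phases
#'
#' Single-step optical-flow (demons-type) estimator on cardiac-summed
#' images: the displacement that maps the content of phase i into the frame
#' of phase j. The 0/0 voxel is set to zero; when i = j the field is zero.
#'
#' @param img_i source-phase image (\linkS4class{RespSummedImage} or 3-D
#'   array).
#' @param img_j target-phase image, same shape.
#' @return a \linkS4class{DVFField} with displacement in voxels.
#' @export
estimateDVF <- function(img_i, img_j) {
  si <- if (methods::is(img_i, "RespSummedImage")) img_i@respPhase else NA_integer_
  sj <- if (methods::is(img_j, "RespSummedImage")) img_j@respPhase else NA_integer_
  vi <- if (methods::is(img_i, "RespSummedImage")) img_i@volume else img_i
  vj <- if (methods::is(img_j, "RespSummedImage")) img_j@volume else img_j
  if (any(vi < 0) || any(vj < 0)) stop("images must be nonnegative")
  disp <- if (!is.na(si) && !is.na(sj) && si == sj)
    array(0, c(dim(vi), 3)) else dvfEq5(vj, vi)
  methods::new("DVFField", displacement = disp,
               sourcePhase = if (is.na(si)) 0L else si,
               targetPhase = if (is.na(sj)) 0L else sj)
}

#' Warp a volume with a deformation field
#'
#' Trilinear resampling at positions displaced by the field (displacement
#' in voxels), with border replication outside the grid. A zero field is
#' the exact identity; interpolation weights are nonnegative so warping
#' preserves nonnegativity.
#'
#' @param volume 3-D array.
#' @param dvf a \linkS4class{DVFField} or an (x,y,z,3) displacement array.
#' @return the warped 3-D array.
#' @export
warpVolume <- function(volume, dvf) {
  disp <- if (methods::is(dvf, "DVFField")) dvf@displacement else dvf
  if (!all(dim(disp)[1:3] == dim(volume)) || dim(disp)[4] != 3L)
    stop("DVF shape does not match the volume")
  if (any(!is.finite(disp))) stop("DVF must be finite")
  cpp_warp(volume, disp, as.integer(dim(volume)), FALSE)
}

# cyclic phase distance on 1..R
cyclicDist <- function(i, j, R) pmin(abs(i - j), R - abs(i - j))

temporalWeights <- function(j, R, weight_scheme) {
  i <- seq_len(R)
  if (weight_scheme == "literal") 1 - 2 * abs(i - j) / R
  else 1 - 2 * cyclicDist(i, j, R) / R
}

#' Weighted temporal fusion of warped respiratory phases
#'
#' Combines the R phase-warped copies of a cardiac gate into the target
#' phase j with weights decreasing in phase distance, w = 1 - 2 d(i,j)/R.
#' The default scheme uses the cyclic distance min(|i-j|, R-|i-j|) and
#' normalizes by the weight sum, so a stack of identical inputs is returned
#' unchanged and per-phase intensity is preserved; "literal" uses the
#' linear distance |i-j| without normalization.
#'
#' @param warped_stack 4-D array (x, y, z, R): input i is the image of
#'   respiratory phase i warped into the target phase frame.
#' @param target_phase j in 1..R.
#' @param weight_scheme "cyclic_normalized" (default) or "literal".
#' @return the fused 3-D volume.
#' @export
temporalFilter <- function(warped_stack, target_phase,
                           weight_scheme = c("cyclic_normalized",
                                             "literal")) {
  weight_scheme <- match.arg(weight_scheme)
  d <- dim(warped_stack)
  if (length(d) != 4L) stop("warped_stack must be (x,y,z,R)")
  R <- d[4]
  if (target_phase < 1 || target_phase > R)
    stop("target_phase out of range 1..", R)
  w <- temporalWeights(target_phase, R, weight_scheme)
  out <- array(0, d[1:3])
  for (i in seq_len(R)) out <- out + w[i] * slice4(warped_stack, i)
  if (weight_scheme == "cyclic_normalized") out <- out / sum(w)
  out
}

#' Respiratory motion-compensated post-filtering (RMC)
#'
#' Full post-reconstruction stage: for every target respiratory phase j,
#' the cardiac-summed images drive a deformation estimate from each phase i,
#' each cardiac gate of phase i is warped into the frame of phase j, and
#' the warped copies are fused with distance-decreasing weights. Returns
#' the filtered set for all phases and gates.
#'
#' @param all_recons 5-D array (x, y, z, R, K) of reconstructed volumes, or
#'   a list of R \linkS4class{GatedReconstruction} objects.
#' @param weight_scheme see \code{\link{temporalFilter}}.
#' @return 5-D array of filtered volumes, same shape.
#' @export
rmc <- function(all_recons, weight_scheme = c("cyclic_normalized",
                                              "literal")) {
  weight_scheme <- match.arg(weight_scheme)
  if (is.list(all_recons)) {
    R <- length(all_recons)
    vols <- lapply(all_recons, function(x)
      if (methods::is(x, "GatedReconstruction")) x@volumes else x)
    d4 <- dim(vols[[1]])
    all_recons <- array(0, c(d4[1:3], R, d4[4]))
    for (r in seq_len(R)) all_recons[, , , r, ] <- vols[[r]]
  }
  d <- dim(all_recons)
  if (length(d) != 5L) stop("expected a complete (x,y,z,R,K) set")
  R <- d[4]; K <- d[5]
  if (any(is.na(all_recons))) stop("missing gates (NA) in reconstruction set")
  summed <- lapply(seq_len(R), function(r) {
    v <- array(all_recons[, , , r, ], c(d[1:3], K))
    sumCardiac(v, r)@volume
  })
  out <- array(0, d)
  for (j in seq_len(R)) {
    dvfs <- lapply(seq_len(R), function(i) {
      if (i == j) array(0, c(d[1:3], 3)) else dvfEq5(summed[[j]], summed[[i]])
    })
    for (k in seq_len(K)) {
      stack <- array(0, c(d[1:3], R))
      for (i in seq_len(R)) {
        v <- all_recons[, , , i, k]
        stack[, , , i] <- if (i == j) v
          else cpp_warp(v, dvfs[[i]], as.integer(d[1:3]), FALSE)
      }
      out[, , , j, k] <- temporalFilter(stack, j, weight_scheme)
    }
  }
  out
}
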