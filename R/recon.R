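#' Reconstruction parameters
#'
#' Parameters for OSEM and the 4D MAP (BSREM) reconstruction. The
#' relaxation schedule is alpha_n = alpha0 / (1 + decay * n) with n the
#' 0-based iteration index; with \code{beta_s = beta_t = 0}, one subset and
#' unit relaxation the BSREM update reduces exactly to MLEM.
#'
#' @param n_iterations number of full iterations.
#' @param n_subsets number of angularly interleaved view subsets; must
#'   divide the number of views.
#' @param beta_s,beta_t spatial and temporal Gibbs-prior weights (>= 0).
#' @param alpha0,decay relaxation schedule parameters.
#' @param nonneg_floor small positive clamp applied after each update.
#' @param cardiac_dvf_source "from_initial_osem" estimates the cardiac
#'   deformation fields once from a short initial OSEM reconstruction;
#'   "identity" uses zero fields.
#' @param track_objective record the penalized log-likelihood per iteration.
#' @return a list of class \code{ReconParams}.
#' @export
reconParams <- function(n_iterations = 30L, n_subsets = 8L, beta_s = 0,
                        beta_t = 0, alpha0 = 1, decay = 0.05,
                        nonneg_floor = 1e-8,
                        cardiac_dvf_source = c("from_initial_osem",
                                               "identity"),
                        track_objective = TRUE) {
  stopifnot(n_iterations >= 1L, n_subsets >= 1L, beta_s >= 0, beta_t >= 0,
            alpha0 > 0, decay >= 0, nonneg_floor > 0)
  p <- list(n_iterations = as.integer(n_iterations),
            n_subsets = as.integer(n_subsets), beta_s = beta_s,
            beta_t = beta_t, alpha0 = alpha0, decay = decay,
            nonneg_floor = nonneg_floor,
            cardiac_dvf_source = match.arg(cardiac_dvf_source),
            track_objective = isTRUE(track_objective))
  class(p) <- "ReconParams"
  p
}

# angularly interleaved subset view indices
subsetViews <- function(n_views, n_subsets) {
  if (n_views %% n_subsets != 0)
    stop("n_subsets must divide the number of views")
  lapply(seq_len(n_subsets), function(s) seq(s, n_views, by = n_subsets))
}

# gate slice of a 4-D array without dropping singleton spatial dims
slice4 <- function(a, k) {
  d <- dim(a)
  m <- a[, , , k, drop = FALSE]
  dim(m) <- d[1:3]
  m
}

# Poisson log-likelihood sum(p log q - q), with 0 log 0 = 0
poissonLogLik <- function(p, q) {
  pos <- q > 0
  sum(p[pos] * log(q[pos])) - sum(q)
}

osemOne <- function(proj, system, resp_phase, n_iterations, n_subsets,
                    nonneg_floor, cache = NULL) {
  g <- system@geometry
  d3 <- c(dim(proj)[1], dim(proj)[1], dim(proj)[2])
  if (is.null(cache) && system@attenuationMode != "none")
    cache <- attenCache(system, resp_phase, d3)
  subs <- subsetViews(g$n_views, n_subsets)
  sens <- lapply(subs, function(v) {
    ones <- array(1, c(d3[1], d3[3], length(v)))
    backprojectViewsC(ones, system, v, cache, d3)
  })
  x <- array(1, d3)
  for (it in seq_len(n_iterations)) {
    for (s in seq_along(subs)) {
      v <- subs[[s]]
      q <- projectViewsC(x, system, v, cache)
      ratio <- array(0, dim(q))
      pos <- q > 0
      ratio[pos] <- proj[, , v, drop = FALSE][pos] / q[pos]
      bp <- backprojectViewsC(ratio, system, v, cache, d3)
      upd <- array(1, d3)  # zero-sensitivity voxels carry no data: no update
      spos <- sens[[s]] > 0
      upd[spos] <- bp[spos] / sens[[s]][spos]
      x <- x * upd
      if (nonneg_floor > 0) x <- pmax(x, nonneg_floor)
    }
  }
  x
}

#' Ordered-subsets expectation maximization (OSEM)
#'
#' Standard multiplicative OSEM with angularly interleaved subsets, using
#' the package's matched projector pair. With one subset this is MLEM.
#'
#' @param projections sinogram array (t, z, view) or (t, z, view, K) for K
#'   cardiac gates (reconstructed independently).
#' @param system a \linkS4class{SystemModel}.
#' @param resp_phase respiratory gate for attenuation-map selection.
#' @param n_iterations,n_subsets iteration and subset counts (defaults 10
#'   and 16, the ideal-image setting).
#' @param nonneg_floor optional positive clamp (0 disables).
#' @return a 3-D volume, or a 4-D (x,y,z,K) array for gated input.
#' @export
osem <- function(projections, system, resp_phase = 1L, n_iterations = 10L,
                 n_subsets = 16L, nonneg_floor = 0) {
  d <- dim(projections)
  if (length(d) == 3L)
    return(osemOne(projections, system, resp_phase, n_iterations, n_subsets,
                   nonneg_floor))
  if (length(d) != 4L) stop("projections must be 3-D or 4-D")
  d3 <- c(d[1], d[1], d[2])
  cache <- if (system@attenuationMode != "none")
    attenCache(system, resp_phase, d3) else NULL
  out <- array(0, c(d[1], d[1], d[2], d[4]))
  for (k in seq_len(d[4]))
    out[, , , k] <- osemOne(slice4(projections, k), system, resp_phase,
                            n_iterations, n_subsets, nonneg_floor, cache)
  out
}

#' Ideal (ground-truth) reconstructions
#'
#' Forward-projects every (respiratory, cardiac) gate of the phantom with
#' depth-dependent blur only (no attenuation, no scatter, no noise) and
#' reconstructs with OSEM; these serve as the reference for RMSE/SSIM and
#' for locating the lesion in the observer study.
#'
#' @param phantom a \linkS4class{GatedPhantom}.
#' @param geometry a \code{\link{systemGeometry}}.
#' @param n_iterations,n_subsets OSEM setting (default 10 x 16).
#' @return 5-D array (x, y, z, R, K) of ideal volumes.
#' @export
idealReconstruction <- function(phantom, geometry, n_iterations = 10L,
                                n_subsets = 16L) {
  act <- phantom@activity
  d <- dim(act)
  sys <- systemModel(geometry, "none")
  out <- array(0, d)
  for (r in seq_len(d[4])) for (k in seq_len(d[5])) {
    p <- forwardProject(act[, , , r, k], sys, r)
    out[, , , r, k] <- osemOne(p, sys, r, n_iterations, n_subsets, 0)
  }
  out
}

# shift-difference along one axis: I - I_shifted(+1), zero at the far border
axisDiff <- function(x, axis) {
  d <- dim(x)
  n <- d[axis]
  idx1 <- lapply(d, seq_len); idx2 <- idx1
  idx1[[axis]] <- seq_len(n - 1); idx2[[axis]] <- 2:n
  do.call(`[`, c(list(x), idx1)) - do.call(`[`, c(list(x), idx2))
}

#' Spatiotemporal Gibbs prior energy and gradient
#'
#' Quadratic 6-neighbor spatial energy within each cardiac gate,
#' \code{U_s = sum_gates sum_v sum_{u in N6(v)} (I(v)-I(u))^2 / 2}, plus a
#' temporal energy along the cardiac motion trajectory,
#' \code{U_t = sum_k sum_v (I_k(v) - W_k I_{k+1}(v))^2 / 2} with cyclic gate
#' pairing, where \code{W_k} warps the next gate into gate k using the
#' supplied cardiac deformation fields.
#'
#' @param volumes 4-D array (x, y, z, K).
#' @param beta_s,beta_t prior weights.
#' @param cardiac_dvfs NULL (identity fields) or a list of K displacement
#'   arrays (x,y,z,3); element k maps gate k+1 (cyclic) into gate k.
#' @return list with \code{energy} (scalar \code{beta_s*U_s + beta_t*U_t}),
#'   \code{gradient} (4-D array), and the unweighted \code{U_s}, \code{U_t}.
#' @export
gibbsEnergy <- function(volumes, beta_s, beta_t, cardiac_dvfs = NULL) {
  d <- dim(volumes)
  stopifnot(length(d) == 4L)
  K <- d[4]
  d3 <- d[1:3]
  U_s <- 0
  grad_s <- array(0, d)
  for (k in seq_len(K)) {
    I <- slice4(volumes, k)
    g <- array(0, d3)
    for (ax in which(d3 > 1)) {
      dv <- axisDiff(I, ax)
      U_s <- U_s + sum(dv^2)  # each unordered pair twice with weight 1/2
      idx1 <- lapply(d3, seq_len); idx2 <- idx1
      idx1[[ax]] <- seq_len(d3[ax] - 1); idx2[[ax]] <- 2:d3[ax]
      g1 <- do.call(`[`, c(list(g), idx1)) + 2 * dv
      g <- do.call(`[<-`, c(list(g), idx1, list(g1)))
      g2 <- do.call(`[`, c(list(g), idx2)) - 2 * dv
      g <- do.call(`[<-`, c(list(g), idx2, list(g2)))
    }
    grad_s[, , , k] <- g
  }
  U_t <- 0
  grad_t <- array(0, d)
  if (K > 1) {
    for (k in seq_len(K)) {
      k2 <- if (k == K) 1L else k + 1L
      dvf <- if (is.null(cardiac_dvfs)) NULL else cardiac_dvfs[[k]]
      if (!is.null(dvf) && !all(dim(dvf) == c(d3, 3)))
        stop("cardiac DVF shape mismatch at gate ", k)
      wnext <- if (is.null(dvf)) slice4(volumes, k2)
               else cpp_warp(slice4(volumes, k2), dvf, as.integer(d3), FALSE)
      res <- slice4(volumes, k) - wnext
      U_t <- U_t + sum(res^2) / 2
      grad_t[, , , k] <- slice4(grad_t, k) + res
      back <- if (is.null(dvf)) res
              else cpp_warp(res, dvf, as.integer(d3), TRUE)
      grad_t[, , , k2] <- slice4(grad_t, k2) - back
    }
  }
  list(energy = beta_s * U_s + beta_t * U_t,
       gradient = beta_s * grad_s + beta_t * grad_t, U_s = U_s, U_t = U_t)
}

# cardiac DVFs from a short OSEM reconstruction of each gate
estimateCardiacDVFs <- function(projections, system, resp_phase, n_subsets) {
  d <- dim(projections)
  K <- d[4]
  init <- osem(projections, system, resp_phase, n_iterations = 3L,
               n_subsets = n_subsets, nonneg_floor = 0)
  lapply(seq_len(K), function(k) {
    k2 <- if (k == K) 1L else k + 1L
    dvfEq5(slice4(init, k), slice4(init, k2))  # maps gate k+1 into gate k
  })
}

#' 4D MAP reconstruction by modified BSREM
#'
#' Cardiac motion-compensated reconstruction of all K cardiac gates of one
#' respiratory phase: block-sequential relaxed updates combine the subset
#' Poisson-likelihood gradient with the scaled Gibbs-prior gradient,
#'
#' \code{x <- x + alpha_n * (x / sens_s) * (grad_loglik_s - grad_prior / M)},
#'
#' with relaxation \code{alpha_n = alpha0/(1 + decay n)}, a positivity floor
#' and angularly interleaved subsets. Scatter is treated as zero in the
#' forward model. The attenuation map inside H follows the system's mode:
#' matched (MAC) selects the phase-r map, averaged (AAC) the mean map.
#'
#' @param projections sinogram array (t, z, view, K) for one respiratory
#'   phase.
#' @param system a \linkS4class{SystemModel} in "matched" or "averaged"
#'   mode (or "none").
#' @param resp_phase the respiratory gate being reconstructed.
#' @param params a \code{\link{reconParams}}.
#' @return a \linkS4class{GatedReconstruction}.
#' @export
bsrem4d <- function(projections, system, resp_phase = 1L,
                    params = reconParams()) {
  d <- dim(projections)
  stopifnot(length(d) == 4L)
  K <- d[4]
  d3 <- c(d[1], d[1], d[2])
  g <- system@geometry
  cache <- if (system@attenuationMode != "none")
    attenCache(system, resp_phase, d3) else NULL
  subs <- subsetViews(g$n_views, params$n_subsets)
  M <- length(subs)
  sens <- lapply(subs, function(v) {
    ones <- array(1, c(d3[1], d3[3], length(v)))
    backprojectViewsC(ones, system, v, cache, d3)
  })
  dvfs <- NULL
  prior_active <- params$beta_s > 0 || params$beta_t > 0
  if (params$beta_t > 0 && params$cardiac_dvf_source == "from_initial_osem")
    dvfs <- estimateCardiacDVFs(projections, system, resp_phase,
                                params$n_subsets)
  # with an active prior, bound the iterates (modified-BSREM safeguard):
  # a short ML probe sets the image scale
  xmax <- Inf
  if (prior_active) {
    probe <- osem(projections, system, resp_phase, n_iterations = 1L,
                  n_subsets = params$n_subsets, nonneg_floor = 0)
    xmax <- 10 * max(probe)
  }
  x <- array(1, c(d3, K))
  objective <- numeric(0)
  for (it in seq_len(params$n_iterations)) {
    alpha <- params$alpha0 / (1 + params$decay * (it - 1))
    # the scaled prior gradient is refreshed once per full iteration
    prior <- if (prior_active)
      gibbsEnergy(x, params$beta_s, params$beta_t, dvfs)$gradient
    else NULL
    for (s in seq_along(subs)) {
      v <- subs[[s]]
      for (k in seq_len(K)) {
        q <- projectViewsC(slice4(x, k), system, v, cache)
        ratio <- array(0, dim(q))
        pos <- q > 0
        pk <- projections[, , v, k, drop = FALSE]
        dim(pk) <- dim(q)
        ratio[pos] <- pk[pos] / q[pos]
        gradL <- backprojectViewsC(ratio, system, v, cache, d3) -
          sens[[s]]
        if (!is.null(prior)) gradL <- gradL - slice4(prior, k) / M
        step <- array(0, d3)
        spos <- sens[[s]] > 0
        xk <- slice4(x, k)
        step[spos] <- xk[spos] / sens[[s]][spos] * gradL[spos]
        x[, , , k] <- pmin(pmax(xk + alpha * step, params$nonneg_floor),
                           xmax)
      }
    }
    if (params$track_objective) {
      ll <- 0
      for (k in seq_len(K)) {
        q <- projectViewsC(slice4(x, k), system, seq_len(g$n_views), cache)
        ll <- ll + poissonLogLik(projections[, , , k], q)
      }
      pen <- if (prior_active)
        gibbsEnergy(x, params$beta_s, params$beta_t, dvfs)$energy else 0
      obj <- ll - pen
      if (!is.finite(obj))
        stop("BSREM objective became non-finite at iteration ", it)
      objective <- c(objective, obj)
    }
  }
  methods::new("GatedReconstruction", volumes = x,
               respPhase = as.integer(resp_phase), params = unclass(params),
               objective = objective)
}

#' Auto-scale for the prior weights
#'
#' Matches the prior-gradient magnitude to the likelihood-gradient magnitude
#' at an early iterate (one full OSEM iteration), giving a data-adaptive
#' unit for \code{beta_s} and \code{beta_t}.
#'
#' @param projections sinogram array (t, z, view, K).
#' @param system a \linkS4class{SystemModel}.
#' @param resp_phase respiratory gate.
#' @param n_subsets subsets for the probe OSEM iteration.
#' @return named numeric \code{c(beta_s =, beta_t =)} scales.
#' @export
betaAutoScale <- function(projections, system, resp_phase = 1L,
                          n_subsets = 8L) {
  d <- dim(projections)
  K <- d[4]
  d3 <- c(d[1], d[1], d[2])
  x1 <- osem(projections, system, resp_phase, n_iterations = 1L,
             n_subsets = n_subsets, nonneg_floor = 0)
  cache <- if (system@attenuationMode != "none")
    attenCache(system, resp_phase, d3) else NULL
  allv <- seq_len(system@geometry$n_views)
  sens <- backprojectViewsC(array(1, c(d3[1], d3[3], length(allv))),
                            system, allv, cache, d3)
  gradL_mag <- 0
  for (k in seq_len(K)) {
    q <- projectViewsC(slice4(x1, k), system, allv, cache)
    ratio <- array(0, dim(q)); pos <- q > 0
    ratio[pos] <- projections[, , , k][pos] / q[pos]
    gradL_mag <- gradL_mag +
      sum(abs(backprojectViewsC(ratio, system, allv, cache, d3) - sens))
  }
  gb <- gibbsEnergy(x1, 1, 1, NULL)
  gs <- gibbsEnergy(x1, 1, 0, NULL)$gradient
  gt <- gibbsEnergy(x1, 0, 1, NULL)$gradient
  c(beta_s = gradL_mag / max(sum(abs(gs)), .Machine$double.eps),
    beta_t = gradL_mag / max(sum(abs(gt)), .Machine$double.eps))
}

#' Select prior weights by RMSE against the ideal images
#'
#' Reconstructs the reference respiratory phase once for every grid point
#' and returns the \code{(beta_s, beta_t)} pair minimizing the mean relative
#' RMSE over the LV region of interest against the ideal volumes. Ties are
#' broken toward the larger pair (stronger smoothing).
#'
#' @param beta_grid data.frame with columns \code{beta_s}, \code{beta_t}.
#' @param projections sinograms (t, z, view, K) for the reference phase.
#' @param system a \linkS4class{SystemModel}.
#' @param ideal_volumes 4-D array (x,y,z,K) of ideal images for the phase.
#' @param roi a \code{\link{roiSpec}} or NULL for the full volume.
#' @param params a \code{\link{reconParams}} (its beta fields are
#'   overridden per grid point).
#' @param resp_phase the reference respiratory gate (default 1).
#' @return list with \code{beta_s}, \code{beta_t}, and the searched
#'   \code{table} of RMSE values.
#' @export
selectBeta <- function(beta_grid, projections, system, ideal_volumes,
                       roi = NULL, params = reconParams(),
                       resp_phase = 1L) {
  if (is.null(dim(beta_grid)) || nrow(beta_grid) == 0)
    stop("beta_grid must be a nonempty data.frame")
  K <- dim(projections)[4]
  rmse <- numeric(nrow(beta_grid))
  for (i in seq_len(nrow(beta_grid))) {
    p <- params
    p$beta_s <- beta_grid$beta_s[i]
    p$beta_t <- beta_grid$beta_t[i]
    rec <- bsrem4d(projections, system, resp_phase, p)
    vals <- vapply(seq_len(K), function(k)
      relativeRMSE(slice4(rec@volumes, k), slice4(ideal_volumes, k), roi),
      numeric(1))
    rmse[i] <- mean(vals)
  }
  ord <- order(rmse, -beta_grid$beta_s, -beta_grid$beta_t)
  best <- ord[1]
  list(beta_s = beta_grid$beta_s[best], beta_t = beta_grid$beta_t[best],
       table = cbind(beta_grid, rmse = rmse))
}
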