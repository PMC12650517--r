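#' Region-of-interest specification
#'
#' Axis-aligned box in voxel coordinates. The default extent (28 x 28 x 10)
#' covers the majority of the LV on the full-size grid; for the observer
#' study a single transverse slice is used.
#'
#' @param origin integer triple, 1-based corner voxel.
#' @param extent integer triple, box size in voxels.
#' @return a list of class \code{RoiSpec}.
#' @export
roiSpec <- function(origin, extent = c(28L, 28L, 10L)) {
  origin <- as.integer(origin); extent <- as.integer(extent)
  stopifnot(length(origin) == 3L, length(extent) == 3L, all(origin >= 1L),
            all(extent >= 1L))
  structure(list(origin = origin, extent = extent), class = "RoiSpec")
}

extractROI <- function(volume, roi) {
  if (is.null(roi)) return(volume)
  o <- roi$origin; e <- roi$extent
  d <- dim(volume)
  if (any(o + e - 1L > d)) stop("ROI extends outside the volume")
  volume[o[1]:(o[1] + e[1] - 1), o[2]:(o[2] + e[2] - 1),
         o[3]:(o[3] + e[3] - 1), drop = FALSE]
}

#' Relative root-mean-square error over an ROI
#'
#' \code{sqrt(sum((recon - ideal)^2)) / sqrt(sum(ideal^2))} over the ROI
#' (the L2-ratio normalization: RMS error relative to the RMS of the
#' reference).
#'
#' @param recon,ideal volumes of identical shape.
#' @param roi a \code{\link{roiSpec}} or NULL for the whole volume.
#' @return nonnegative scalar; 0 iff the images agree on the ROI.
#' @export
relativeRMSE <- function(recon, ideal, roi = NULL) {
  if (!identical(dim(recon), dim(ideal))) stop("image shape mismatch")
  a <- extractROI(recon, roi); b <- extractROI(ideal, roi)
  nb <- sqrt(sum(b^2))
  if (nb == 0) stop("reference is identically zero on the ROI")
  sqrt(sum((a - b)^2)) / nb
}

# sums over all valid wxw windows of a matrix, via banded ones-matrices
winSum <- function(m, w) {
  n1 <- nrow(m); n2 <- ncol(m)
  A <- matrix(0, n1 - w + 1, n1)
  for (i in seq_len(n1 - w + 1)) A[i, i:(i + w - 1)] <- 1
  B <- matrix(0, n2 - w + 1, n2)
  for (i in seq_len(n2 - w + 1)) B[i, i:(i + w - 1)] <- 1
  A %*% m %*% t(B)
}

#' Mean structural similarity (SSIM) over an ROI
#'
#' Mean local SSIM computed per transverse slice with a uniform square
#' window and the standard stability constants \code{C1 = (0.01 L)^2},
#' \code{C2 = (0.03 L)^2}, with L the maximum of either image over the ROI
#' (so the index is symmetric in its arguments).
#'
#' @param recon,ideal volumes of identical shape.
#' @param roi a \code{\link{roiSpec}} or NULL.
#' @param window odd window side in pixels (default 7).
#' @return scalar <= 1, equal to 1 iff the images agree on the ROI.
#' @export
ssimIndex <- function(recon, ideal, roi = NULL, window = 7L) {
  if (!identical(dim(recon), dim(ideal))) stop("image shape mismatch")
  a <- extractROI(recon, roi); b <- extractROI(ideal, roi)
  d <- dim(a)
  if (d[1] < window || d[2] < window)
    stop("ROI smaller than the SSIM window")
  L <- max(max(a), max(b))
  if (L <= 0) L <- 1
  C1 <- (0.01 * L)^2; C2 <- (0.03 * L)^2
  N <- window^2
  vals <- numeric(0)
  for (z in seq_len(d[3])) {
    x <- a[, , z]; y <- b[, , z]
    mx <- winSum(x, window) / N
    my <- winSum(y, window) / N
    vx <- winSum(x^2, window) / N - mx^2
    vy <- winSum(y^2, window) / N - my^2
    cxy <- winSum(x * y, window) / N - mx * my
    s <- ((2 * mx * my + C1) * (2 * cxy + C2)) /
      ((mx^2 + my^2 + C1) * (vx + vy + C2))
    vals <- c(vals, as.numeric(s))
  }
  mean(vals)
}

#' Intensity profile along a transaxial line
#'
#' Samples a transverse slice along a horizontal line (fixed anterior-
#' posterior row), the standard way of inspecting the two LV wall crossings
#' through a perfusion defect.
#'
#' @param volume 3-D array.
#' @param slice_index transverse slice (z index).
#' @param row_index y index of the line.
#' @param column_range x indices to sample (default: full width).
#' @return numeric vector of samples.
#' @export
intensityProfile <- function(volume, slice_index, row_index,
                             column_range = NULL) {
  d <- dim(volume)
  if (is.null(column_range)) column_range <- seq_len(d[1])
  if (slice_index < 1 || slice_index > d[3] || row_index < 1 ||
      row_index > d[2] || any(column_range < 1) || any(column_range > d[1]))
    stop("profile indices out of range")
  volume[column_range, row_index, slice_index]
}

#' Bilinear image resize
#'
#' Corner-aligned bilinear interpolation of a 2-D image to a new square
#' size, used to bring the LV ROI to the observer's working resolution.
#'
#' @param img 2-D matrix.
#' @param out_n output side length.
#' @return \code{out_n x out_n} matrix.
#' @export
bilinearResize <- function(img, out_n = 140L) {
  mkW <- function(n_in, n_out) {
    pos <- (seq_len(n_out) - 1) * (n_in - 1) / (n_out - 1) + 1
    lo <- pmin(floor(pos), n_in - 1)
    f <- pos - lo
    W <- matrix(0, n_out, n_in)
    for (i in seq_len(n_out)) {
      W[i, lo[i]] <- 1 - f[i]
      W[i, lo[i] + 1] <- W[i, lo[i] + 1] + f[i]
    }
    W
  }
  Wx <- mkW(nrow(img), out_n); Wy <- mkW(ncol(img), out_n)
  Wx %*% img %*% t(Wy)
}

# spatial-domain templates of the 4 annular frequency channels (octave
# bands (1/64,1/32], (1/32,1/16], (1/16,1/8], (1/8,1/4] cycles/pixel),
# centered on the image center
choTemplates <- function(n = 140L, bands = NULL) {
  if (is.null(bands))
    bands <- cbind(lo = c(1 / 64, 1 / 32, 1 / 16, 1 / 8),
                   hi = c(1 / 32, 1 / 16, 1 / 8, 1 / 4))
  f <- (seq_len(n) - 1) / n
  f[f > 0.5] <- f[f > 0.5] - 1
  rho <- sqrt(outer(f^2, f^2, "+"))
  shift <- function(m, s) {
    i <- ((seq_len(n) - 1 + s) %% n) + 1
    m[i, i]
  }
  lapply(seq_len(nrow(bands)), function(c) {
    B <- (rho > bands[c, "lo"]) & (rho <= bands[c, "hi"])
    t_c <- Re(stats::fft(B + 0i, inverse = TRUE)) / n^2
    shift(t_c, n / 2)  # center the template on the lesion location
  })
}

#' Channel responses of the rotationally symmetric CHO channels
#'
#' Inner products of a 140 x 140 image with four rotationally symmetric,
#' non-overlapping annular frequency-band templates (octave bands starting
#' at 1/64 cycles/pixel), centered on the image (lesion) center.
#'
#' @param image_140 a 140 x 140 matrix (the interpolated LV ROI).
#' @param templates optional precomputed \code{choTemplates()}.
#' @return numeric vector of 4 channel responses.
#' @export
choChannels <- function(image_140, templates = NULL) {
  if (!is.matrix(image_140) || nrow(image_140) != 140L ||
      ncol(image_140) != 140L)
    stop("expected a 140 x 140 image")
  if (is.null(templates)) templates <- choTemplates(140L)
  vapply(templates, function(t_c) sum(image_140 * t_c), numeric(1))
}

#' Area under the ROC curve by the rank-sum estimator
#'
#' Fraction of (present, absent) score pairs with the present score higher,
#' counting ties one half (the Wilcoxon/Mann-Whitney statistic).
#'
#' @param scores_present,scores_absent nonempty numeric score sets.
#' @return Az in [0, 1].
#' @export
rocAz <- function(scores_present, scores_absent) {
  np <- length(scores_present); na <- length(scores_absent)
  if (np == 0 || na == 0) stop("score sets must be nonempty")
  r <- rank(c(scores_present, scores_absent), ties.method = "average")
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * na)
}

#' Channelized Hotelling observer study with internal noise
#'
#' Channelizes equal-sized lesion-present and lesion-absent ensembles,
#' adds internal noise to the channel outputs (zero-mean Gaussian with
#' variance \code{internal_noise_level} times the diagonal of the pooled
#' channel covariance), forms the Hotelling template \code{w = S^-1 dmu}
#' from the noisy outputs, and scores every image. Training and testing use
#' the same realizations (signal-known-exactly / background-known-exactly
#' design). Reproducible bit-for-bit given the seed.
#'
#' @param present_images,absent_images lists of 140 x 140 matrices, or
#'   140 x 140 x n arrays, or precomputed n x 4 channel-response matrices.
#' @param internal_noise_level variance scale of the internal noise
#'   (default 0.5; 0 disables).
#' @param seed integer RNG seed for the internal noise.
#' @param template optional fixed channel template (length-4 vector), e.g.
#'   \code{solve(Sigma, dmu)} when the class moments are known a priori;
#'   when NULL (default) the template is estimated from the (noisy) channel
#'   outputs themselves.
#' @param signal optional known channel-signal vector (length 4): the
#'   signal-known-exactly design, where the class-mean difference comes
#'   from the noise-free ideal images and only the covariance is estimated
#'   from the ensembles. Ignored when \code{template} is given.
#' @return an \linkS4class{ObserverResult}.
#' @export
choStudy <- function(present_images, absent_images,
                     internal_noise_level = 0.5, seed = 1L,
                     template = NULL, signal = NULL) {
  chan <- function(x) {
    if (is.matrix(x) && ncol(x) == 4L) return(x)  # already channelized
    tpl <- choTemplates(140L)
    if (is.array(x) && length(dim(x)) == 3L)
      x <- lapply(seq_len(dim(x)[3]), function(i) x[, , i])
    t(vapply(x, choChannels, numeric(4), templates = tpl))
  }
  vp <- chan(present_images); va <- chan(absent_images)
  if (ncol(vp) != 4L || ncol(va) != 4L) stop("expected 4 channel responses")
  np <- nrow(vp); na <- nrow(va)
  pooledCov <- function(a, b) {
    ((nrow(a) - 1) * stats::cov(a) + (nrow(b) - 1) * stats::cov(b)) /
      (nrow(a) + nrow(b) - 2)
  }
  set.seed(as.integer(seed))
  if (internal_noise_level > 0) {
    S0 <- pooledCov(vp, va)
    sd_c <- sqrt(internal_noise_level * pmax(diag(S0), 0))
    vp <- vp + matrix(stats::rnorm(np * 4, 0, rep(sd_c, each = np)), np, 4)
    va <- va + matrix(stats::rnorm(na * 4, 0, rep(sd_c, each = na)), na, 4)
  }
  if (is.null(template)) {
    dmu <- if (is.null(signal)) colMeans(vp) - colMeans(va)
           else as.numeric(signal)
    S <- pooledCov(vp, va)
    w <- tryCatch(solve(S, dmu), error = function(e)
      stop("singular channel covariance; use more realizations or ",
           "regularize", call. = FALSE))
  } else {
    w <- as.numeric(template)
    if (length(w) != ncol(vp)) stop("template length mismatch")
  }
  tp <- as.numeric(vp %*% w); ta <- as.numeric(va %*% w)
  methods::new("ObserverResult", decisionPresent = tp, decisionAbsent = ta,
               az = rocAz(tp, ta), channelMatrix = rbind(vp, va),
               internalNoiseLevel = internal_noise_level,
               seed = as.integer(seed))
}

#' Bootstrap comparison of two observer results
#'
#' Paired nonparametric bootstrap over case indices: present and absent
#' cases are resampled with replacement (the same indices applied to both
#' methods), the Az difference is recomputed per replicate, and a two-tailed
#' p-value for the null of equal Az is the doubled smaller tail fraction of
#' replicates crossing zero, capped at 1.
#'
#' @param result_a,result_b \linkS4class{ObserverResult} objects with
#'   equal-sized ensembles.
#' @param n_boot bootstrap replicates (default 2000).
#' @param seed integer RNG seed.
#' @return list with \code{delta_az} (Az_a - Az_b), \code{p_value}, and the
#'   replicate differences \code{boot}.
#' @export
bootstrapCompare <- function(result_a, result_b, n_boot = 2000L, seed = 1L) {
  pa <- result_a@decisionPresent; aa <- result_a@decisionAbsent
  pb <- result_b@decisionPresent; ab <- result_b@decisionAbsent
  if (length(pa) != length(pb) || length(aa) != length(ab))
    stop("ensemble sizes must match for a paired comparison")
  np <- length(pa); na <- length(aa)
  set.seed(as.integer(seed))
  d <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    ip <- sample.int(np, np, replace = TRUE)
    ia <- sample.int(na, na, replace = TRUE)
    d[b] <- rocAz(pa[ip], aa[ia]) - rocAz(pb[ip], ab[ia])
  }
  list(delta_az = rocAz(pa, aa) - rocAz(pb, ab),
       p_value = min(1, 2 * min(mean(d <= 0), mean(d >= 0))),
       boot = d)
}
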