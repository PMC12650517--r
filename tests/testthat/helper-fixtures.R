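# Shared small-scale fixtures, generated in code.

# tiny dual-gated phantom: 16^3 grid at 2.5 cm voxels so the torso fits
tinyPhantomConfig <- function(R = 2L, K = 2L, lesion = "default", ...) {
  if (identical(lesion, "default"))
    lesion <- list(location = "anterior", uptake_reduction = 0.20,
                   long_axis_extent = 40, circumferential_extent = 120)
  phantomConfig(grid_shape = c(16L, 16L, 16L), voxel_size = 2.5,
                n_resp_gates = R, n_card_gates = K, lesion = lesion,
                lv_geometry = list(center = c(3.0, 3.0, 2.5),
                                   outer = c(6.5, 6.5, 8.0),
                                   wall_thickness = 2.6,
                                   base_fraction = 0.55,
                                   lesion_z_offset = -1.0),
                torso = list(semi_x = 15, semi_y = 12),
                lungs = list(semi = c(5, 7, 11),
                             center_left = c(9, 1, 2),
                             center_right = c(-9, 1, 2)),
                liver = list(center = c(-5, 0.5, -10),
                             semi = c(8, 7, 6)), ...)
}

tinyGeometry <- function(n_views = 16L, n = 16L, vox = 2.5, blur = TRUE) {
  systemGeometry(n_views = n_views, detector_bins = c(n, n), bin_size = vox,
                 rotation_radius = 28.5, blur_enabled = blur)
}

# desk-scale setting used by the qualitative-replication checks
deskPhantomConfig <- function(...) {
  args <- utils::modifyList(list(grid_shape = c(32L, 32L, 32L),
                                 voxel_size = 1.268, n_resp_gates = 4L,
                                 n_card_gates = 4L), list(...))
  do.call(phantomConfig, args)
}

deskGeometry <- function() {
  systemGeometry(n_views = 32L, detector_bins = c(32L, 32L),
                 bin_size = 1.268)
}

# dense system matrix on a small grid, built column-by-column from the
# package projector; used to drive independent textbook MLEM oracles
denseH <- function(system, d3, resp_phase = 1L) {
  nvox <- prod(d3)
  g <- system@geometry
  nbin <- d3[1] * d3[3] * g$n_views
  H <- matrix(0, nbin, nvox)
  for (j in seq_len(nvox)) {
    e <- array(0, d3); e[j] <- 1
    H[, j] <- as.numeric(forwardProject(e, system, resp_phase))
  }
  H
}

# textbook MLEM on a dense matrix, uniform start
mlemOracle <- function(H, p, n_iter) {
  x <- rep(1, ncol(H))
  sens <- colSums(H)
  for (it in seq_len(n_iter)) {
    q <- as.numeric(H %*% x)
    r <- ifelse(q > 0, p / q, 0)
    upd <- as.numeric(crossprod(H, r))
    x <- ifelse(sens > 0, x * upd / sens, x)
  }
  x
}
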