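#' Phantom configuration
#'
#' Builds the configuration for the geometric moving-torso phantom: an
#' ellipsoidal torso, two lung ellipsoids, a liver ellipsoid riding on the
#' diaphragm, and a half-ellipsoid left-ventricular (LV) shell with a blood
#' pool, dual-gated over respiratory and cardiac cycles. Respiratory motion
#' translates the heart (and lesion) along the superior-inferior (SI) and
#' anterior-posterior (AP) axes and the liver along SI, following a
#' \code{(1 - cos)/2} trajectory sampled at R equally spaced phase centers;
#' phase 1 is end-expiration. Cardiac gates contract the LV inner surface
#' radially with wall-volume preservation; gate 1 is end-diastole.
#'
#' Coordinates: volumes are X x Y x Z arrays, 1-based in R, with Z the body
#' long (SI) axis, +Y anterior, +X the patient's left. Lesion location
#' labels map to circumferential angles in the transaxial plane about the LV
#' axis: lateral 0 deg (+X), anterior 90 deg (+Y), septal 180 deg (-X),
#' inferior 270 deg (-Y).
#'
#' @param grid_shape integer triple, voxels per axis (transaxial plane must
#'   be square).
#' @param voxel_size isotropic voxel size in cm.
#' @param n_resp_gates,n_card_gates number of respiratory (R) and cardiac
#'   (K) gates.
#' @param resp_amplitude_si,resp_amplitude_ap peak-to-peak heart translation
#'   in cm along SI and AP.
#' @param diaphragm_amplitude_si peak-to-peak SI excursion of the
#'   liver/diaphragm in cm.
#' @param card_contraction fractional reduction of the LV inner radius at
#'   end-systole.
#' @param lv_geometry list: \code{center} (cm, relative to grid center),
#'   \code{outer} semi-axes (cm), \code{wall_thickness} (cm),
#'   \code{base_fraction} (the shell is kept below
#'   \code{base_fraction * outer_z} above the LV center, leaving the basal
#'   opening), \code{lesion_z_offset} (cm, lesion center along the long
#'   axis relative to the LV center).
#' @param organ_uptake named relative activities: \code{lv_wall},
#'   \code{blood}, \code{lung}, \code{liver}, \code{background}.
#' @param lesion NULL for a healthy phantom, or a list with
#'   \code{location} in \code{c("anterior","inferior","lateral","septal")},
#'   \code{uptake_reduction} (fraction in [0,1]),
#'   \code{long_axis_extent} (mm), \code{circumferential_extent} (degrees).
#' @param mu_values attenuation coefficients at 140 keV in cm^-1:
#'   \code{soft}, \code{lung}.
#' @param torso,lungs,liver geometry of the static/moving organs (cm).
#' @param seed integer carried along for downstream noise generation.
#' @return a validated list of class \code{PhantomConfig}.
#' @export
phantomConfig <- function(grid_shape = c(64L, 64L, 64L),
                          voxel_size = 0.634,
                          n_resp_gates = 8L,
                          n_card_gates = 8L,
                          resp_amplitude_si = 1.59,
                          resp_amplitude_ap = 0.95,
                          diaphragm_amplitude_si = 2.0,
                          card_contraction = 0.25,
                          lv_geometry = list(center = c(3.0, 3.0, 2.5),
                                             outer = c(3.4, 3.4, 4.4),
                                             wall_thickness = 1.1,
                                             base_fraction = 0.55,
                                             lesion_z_offset = -0.5),
                          organ_uptake = c(lv_wall = 1.0, blood = 0.12,
                                           lung = 0.05, liver = 0.6,
                                           background = 0.10),
                          lesion = list(location = "anterior",
                                        uptake_reduction = 0.20,
                                        long_axis_extent = 20,
                                        circumferential_extent = 100),
                          mu_values = c(soft = 0.154, lung = 0.04),
                          torso = list(semi_x = 12.5, semi_y = 9.5),
                          lungs = list(semi = c(4.0, 5.5, 9.0),
                                       center_left = c(7.0, 1.0, 2.0),
                                       center_right = c(-7.0, 1.0, 2.0)),
                          liver = list(center = c(-4.5, 0.5, -8.0),
                                       semi = c(6.5, 6.0, 4.5)),
                          seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 4L),
            grid_shape[1] == grid_shape[2], voxel_size > 0,
            n_resp_gates >= 1L, n_card_gates >= 1L,
            resp_amplitude_si >= 0, resp_amplitude_ap >= 0,
            card_contraction >= 0, card_contraction < 1,
            all(mu_values >= 0), all(organ_uptake >= 0))
  if (!is.null(lesion)) {
    if (!lesion$location %in% c("anterior", "inferior", "lateral", "septal"))
      stop("unknown lesion location: ", lesion$location)
    if (lesion$uptake_reduction < 0 || lesion$uptake_reduction > 1)
      stop("lesion uptake_reduction must lie in [0,1]")
  }
  half_extent <- grid_shape[1] * voxel_size / 2
  if (torso$semi_x >= half_extent || torso$semi_y >= half_extent)
    stop("grid too small to contain the torso ellipse")
  cfg <- list(grid_shape = grid_shape, voxel_size = voxel_size,
              n_resp_gates = as.integer(n_resp_gates),
              n_card_gates = as.integer(n_card_gates),
              resp_amplitude_si = resp_amplitude_si,
              resp_amplitude_ap = resp_amplitude_ap,
              diaphragm_amplitude_si = diaphragm_amplitude_si,
              card_contraction = card_contraction,
              lv_geometry = lv_geometry, organ_uptake = organ_uptake,
              lesion = lesion, mu_values = mu_values, torso = torso,
              lungs = lungs, liver = liver, seed = as.integer(seed))
  class(cfg) <- "PhantomConfig"
  cfg
}

# respiratory phase fraction in [0,1]; phase 1 = end-expiration
respPhaseFraction <- function(r, R) (1 - cos(2 * pi * (r - 1) / R)) / 2

#' Heart displacement at a respiratory phase
#'
#' Offset of the heart center at respiratory gate \code{resp_phase} relative
#' to end-expiration (gate 1), following the cyclic \code{(1-cos)/2}
#' trajectory. With the default even gate count the extreme phases differ by
#' exactly the configured peak-to-peak amplitudes. The heart moves
#' inferiorly (negative SI) and anteriorly (positive AP) with inspiration.
#'
#' @param config a \code{\link{phantomConfig}}.
#' @param resp_phase respiratory gate index in 1..R.
#' @return named numeric \code{c(dSI=, dAP=)} in cm.
#' @export
heartDisplacement <- function(config, resp_phase) {
  R <- config$n_resp_gates
  if (resp_phase < 1 || resp_phase > R)
    stop("resp_phase out of range 1..", R)
  f <- respPhaseFraction(resp_phase, R)
  c(dSI = -config$resp_amplitude_si * f, dAP = config$resp_amplitude_ap * f)
}

# voxel-center coordinate arrays in cm, origin at grid center
gridCoords <- function(grid_shape, voxel_size) {
  ax <- function(n) (seq_len(n) - (n + 1) / 2) * voxel_size
  list(x = ax(grid_shape[1]), y = ax(grid_shape[2]), z = ax(grid_shape[3]))
}

# 3-D logical mask of an axis-aligned ellipsoid
ellipsoidMask <- function(co, center, semi) {
  qx <- ((co$x - center[1]) / semi[1])^2
  qy <- ((co$y - center[2]) / semi[2])^2
  qz <- ((co$z - center[3]) / semi[3])^2
  outer(outer(qx, qy, "+"), qz, "+") <= 1
}

# LV shell geometry at one (resp, cardiac) gate: semi-axes after contraction
# with wall-volume preservation, plus shifted center
lvGateGeometry <- function(config, resp_phase, card_phase) {
  lv <- config$lv_geometry
  disp <- heartDisplacement(config, resp_phase)
  center <- lv$center + c(0, disp["dAP"], disp["dSI"])
  outer0 <- lv$outer
  inner0 <- pmax(outer0 - lv$wall_thickness, 0.1)
  g <- respPhaseFraction(card_phase, config$n_card_gates)  # same cyclic shape
  s_in <- 1 - config$card_contraction * g
  v_o0 <- prod(outer0); v_i0 <- prod(inner0)
  v_ik <- v_i0 * s_in^3
  s_out <- ((v_o0 - v_i0 + v_ik) / v_o0)^(1 / 3)
  list(center = unname(center), outer = outer0 * s_out, inner = inner0 * s_in,
       base_cut = lv$base_fraction * outer0[3] * s_out)
}

# angular distance in degrees on the circle
angDist <- function(a, b) {
  d <- abs(((a - b) %% 360 + 360) %% 360)
  pmin(d, 360 - d)
}

lesionAngles <- c(lateral = 0, anterior = 90, septal = 180, inferior = 270)

# lesion mask inside a wall mask for one gate (transmural wedge)
lesionMaskGate <- function(co, wall, geom, lesion, lesion_z_offset) {
  phi0 <- lesionAngles[[lesion$location]]
  nx <- length(co$x); ny <- length(co$y); nz <- length(co$z)
  dx <- outer(co$x - geom$center[1], rep(1, ny))
  dy <- outer(rep(1, nx), co$y - geom$center[2])
  phi <- atan2(dy, dx) * 180 / pi
  angok <- angDist(phi, phi0) <= lesion$circumferential_extent / 2
  zc <- geom$center[3] + lesion_z_offset
  zok <- abs(co$z - zc) <= lesion$long_axis_extent / 20  # mm -> cm half-extent
  wall & array(angok, c(nx, ny, nz)) &
    array(rep(zok, each = nx * ny), c(nx, ny, nz))
}

#' Generate the dual-gated ground-truth phantom
#'
#' Evaluates the phantom geometry analytically at every (respiratory,
#' cardiac) gate: organs are re-rendered at their phase-shifted positions
#' (no interpolation), so wall activity is conserved across phases up to
#' voxelization. Returns the per-gate activity, the per-respiratory-phase
#' attenuation maps, and the lesion masks. Generation is deterministic.
#'
#' @param config a \code{\link{phantomConfig}}.
#' @return a \linkS4class{GatedPhantom}.
#' @export
generatePhantom <- function(config) {
  stopifnot(inherits(config, "PhantomConfig"))
  gs <- config$grid_shape
  R <- config$n_resp_gates; K <- config$n_card_gates
  co <- gridCoords(gs, config$voxel_size)
  up <- config$organ_uptake; mu <- config$mu_values

  torso <- ellipsoidMask(co, c(0, 0, 0),
                         c(config$torso$semi_x, config$torso$semi_y,
                           gs[3] * config$voxel_size))  # full z extent
  lungL <- ellipsoidMask(co, config$lungs$center_left, config$lungs$semi)
  lungR <- ellipsoidMask(co, config$lungs$center_right, config$lungs$semi)
  lungs <- (lungL | lungR) & torso

  act <- array(0, c(gs, R, K))
  att <- array(0, c(gs, R))
  les <- array(FALSE, c(gs, R, K))

  for (r in seq_len(R)) {
    f <- respPhaseFraction(r, R)
    liver_c <- config$liver$center +
      c(0, 0, -config$diaphragm_amplitude_si * f)
    liver <- ellipsoidMask(co, liver_c, config$liver$semi) & torso

    # attenuation: tissue classes only (LV wall/blood/liver are soft tissue)
    mu_r <- array(0, gs)
    mu_r[torso] <- mu[["soft"]]
    mu_r[lungs] <- mu[["lung"]]
    mu_r[liver] <- mu[["soft"]]
    # the heart displaces lung at its phase-shifted position (use ED shape)
    geom_ed <- lvGateGeometry(config, r, 1L)
    heart_env <- ellipsoidMask(co, geom_ed$center, geom_ed$outer)
    mu_r[heart_env] <- mu[["soft"]]
    att[, , , r] <- mu_r

    for (k in seq_len(K)) {
      geom <- lvGateGeometry(config, r, k)
      outer_m <- ellipsoidMask(co, geom$center, geom$outer)
      inner_m <- ellipsoidMask(co, geom$center, geom$inner)
      below_base <- array(rep(co$z <= geom$center[3] + geom$base_cut,
                              each = gs[1] * gs[2]), gs)
      wall <- outer_m & !inner_m & below_base
      pool <- inner_m & below_base

      a <- array(0, gs)
      a[torso] <- up[["background"]]
      a[lungs] <- up[["lung"]]
      a[liver] <- up[["liver"]]
      a[heart_env & !wall & !pool] <- up[["background"]]
      a[pool] <- up[["blood"]]
      a[wall] <- up[["lv_wall"]]

      if (!is.null(config$lesion)) {
        lm <- lesionMaskGate(co, wall, geom, config$lesion,
                             config$lv_geometry$lesion_z_offset)
        if (!any(lm))
          stop("lesion extends outside the LV wall at gate (r=", r,
               ", k=", k, ")")
        a[lm] <- up[["lv_wall"]] * (1 - config$lesion$uptake_reduction)
        les[, , , r, k] <- lm
      }
      act[, , , r, k] <- a
    }
  }
  methods::new("GatedPhantom", activity = act, attenuation = att,
               lesionMask = les, config = unclass(config))
}

#' Average attenuation map over respiratory phases
#'
#' Voxelwise arithmetic mean of the per-respiratory-phase attenuation maps,
#' the map used by averaged attenuation correction (AAC).
#'
#' @param attenuation a 4-D (x,y,z,R) array or a list of 3-D volumes.
#' @return a 3-D volume, bounded voxelwise by the min and max over phases.
#' @export
averageAttenuation <- function(attenuation) {
  if (is.list(attenuation)) {
    d <- dim(attenuation[[1]])
    if (!all(vapply(attenuation, function(v) identical(dim(v), d), logical(1))))
      stop("attenuation maps must share a common shape")
    attenuation <- array(unlist(attenuation), c(d, length(attenuation)))
  }
  if (length(dim(attenuation)) != 4L)
    stop("expected a 4-D (x,y,z,R) array or list of equal-shape volumes")
  out <- apply(attenuation, 1:3, mean)
  array(out, dim(attenuation)[1:3])
}
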