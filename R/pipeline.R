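#' Experiment configuration
#'
#' Bundles phantom, geometry, reconstruction and evaluation settings for a
#' full comparison of the three method arms: "4d-mac" (4D reconstruction
#' with matched attenuation, no respiratory post-filtering), "4d-rmc-mac"
#' and "4d-rmc-aac" (4D plus respiratory motion-compensated filtering, with
#' matched or averaged attenuation). Two profiles ship: "paper" is the
#' full-size setting (64^3 grid, 64 views, 8 x 8 gates, 30 realizations);
#' "desk" is a reduced setting for interactive use (32^3 grid at doubled
#' voxel size so the torso still fits, 32 views, 4 x 4 gates, 5
#' realizations).
#'
#' @param profile "desk" or "paper".
#' @param lesion_locations subset of anterior/inferior/lateral/septal.
#' @param arms subset of the three method arms.
#' @param n_noise_realizations noise realizations per lesion.
#' @param total_counts expected photons over all gates; NULL selects the
#'   profile default: 8e6 at paper scale, scaled at desk scale so the
#'   expected counts per detector bin (the photon-starvation level of the
#'   dual-gated data) match the paper-scale setting.
#' @param base_seed integer; realization i uses seed base_seed + i, so all
#'   arms share identical noise (paired comparisons).
#' @param scatter_fraction simulated scatter-to-total fraction (never
#'   corrected in reconstruction).
#' @param beta_rel_s,beta_rel_t prior weights as fractions of the
#'   data-adaptive \code{\link{betaAutoScale}} unit.
#' @param internal_noise_level CHO internal-noise variance scale.
#' @param weight_scheme temporal fusion scheme, see
#'   \code{\link{temporalFilter}}.
#' @param cho_ref_resp_gate reference respiratory gate for the observer
#'   study (end-expiration by default).
#' @param run_observer run the CHO study and bootstrap comparisons (needs
#'   enough realizations for a nonsingular 4-channel covariance).
#' @param ... overrides stored into the config (phantom, geometry, recon).
#' @return a list of class \code{ExperimentConfig}.
#' @export
experimentConfig <- function(profile = c("desk", "paper"),
                             lesion_locations = "anterior",
                             arms = c("4d-mac", "4d-rmc-mac", "4d-rmc-aac"),
                             n_noise_realizations = NULL,
                             total_counts = NULL, base_seed = 1L,
                             scatter_fraction = 0.3,
                             beta_rel_s = 1e-3, beta_rel_t = 1e-3,
                             internal_noise_level = 0.5,
                             weight_scheme = "cyclic_normalized",
                             cho_ref_resp_gate = 1L,
                             run_observer = TRUE, ...) {
  profile <- match.arg(profile)
  stopifnot(length(arms) >= 1L,
            all(arms %in% c("4d-mac", "4d-rmc-mac", "4d-rmc-aac")),
            all(lesion_locations %in% c("anterior", "inferior", "lateral",
                                        "septal")))
  if (profile == "desk") {
    phantom <- phantomConfig(grid_shape = c(32L, 32L, 32L),
                             voxel_size = 1.268, n_resp_gates = 4L,
                             n_card_gates = 4L)
    geometry <- systemGeometry(n_views = 32L, detector_bins = c(32L, 32L),
                               bin_size = 1.268)
    recon <- reconParams(n_iterations = 16L, n_subsets = 8L,
                         track_objective = FALSE)
    if (is.null(n_noise_realizations)) n_noise_realizations <- 5L
    # preserve the paper-scale expected counts per detector bin:
    # 8e6 / (64 gates x 64 views x 64 x 64 bins) ~ 0.48 counts/bin
    if (is.null(total_counts))
      total_counts <- 8e6 * (32^3 * 16) / (64^3 * 64)
    ideal_subsets <- 16L
  } else {
    phantom <- phantomConfig()
    geometry <- systemGeometry()
    recon <- reconParams(n_iterations = 30L, n_subsets = 8L,
                         track_objective = FALSE)
    if (is.null(n_noise_realizations)) n_noise_realizations <- 30L
    if (is.null(total_counts)) total_counts <- 8e6
    ideal_subsets <- 16L
  }
  cfg <- list(profile = profile, phantom = phantom, geometry = geometry,
              recon = recon, arms = arms,
              lesion_locations = lesion_locations,
              n_noise_realizations = as.integer(n_noise_realizations),
              total_counts = total_counts, base_seed = as.integer(base_seed),
              scatter_fraction = scatter_fraction,
              beta_rel_s = beta_rel_s, beta_rel_t = beta_rel_t,
              internal_noise_level = internal_noise_level,
              weight_scheme = weight_scheme,
              cho_ref_resp_gate = as.integer(cho_ref_resp_gate),
              run_observer = isTRUE(run_observer),
              ideal_subsets = ideal_subsets)
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  stopifnot(cfg$n_noise_realizations >= 1L)
  class(cfg) <- "ExperimentConfig"
  cfg
}

# LV-centered metric ROI (scaled from 28x28x10 on the 64-grid) and the
# observer slice window, both in voxel indices
lvRoi <- function(pcfg) {
  gs <- pcfg$grid_shape
  vox <- pcfg$voxel_size
  ext <- pmax(round(c(28, 28, 10) * gs[1] / 64), 3L)
  ctr_cm <- pcfg$lv_geometry$center
  ctr <- round(ctr_cm / vox + (gs + 1) / 2)
  org <- pmax(ctr - floor(ext / 2), 1L)
  org <- pmin(org, gs - ext + 1L)
  roiSpec(org, ext)
}

choWindow <- function(pcfg) {
  gs <- pcfg$grid_shape
  vox <- pcfg$voxel_size
  n <- max(8L, round(28 * gs[1] / 64))
  ctr_cm <- pcfg$lv_geometry$center
  zles <- ctr_cm[3] + pcfg$lv_geometry$lesion_z_offset
  ctr <- round(c(ctr_cm[1:2], zles) / vox + (gs + 1) / 2)
  org <- pmax(ctr[1:2] - floor(n / 2), 1L)
  org <- pmin(org, gs[1:2] - n + 1L)
  list(x = org[1]:(org[1] + n - 1), y = org[2]:(org[2] + n - 1),
       z = min(max(ctr[3], 1L), gs[3]))
}

armUsesRmc <- function(arm) arm %in% c("4d-rmc-mac", "4d-rmc-aac")
armMode <- function(arm)
  ifelse(arm == "4d-rmc-aac", "averaged", "matched")

# reconstruct all R respiratory phases for one attenuation mode; volumes
# returned in activity units (count scaling divided out)
reconAllPhases <- function(proj, system, params) {
  d <- dim(counts(proj))
  out <- array(0, c(d[1], d[1], d[2], d[4], d[5]))
  for (r in seq_len(d[4])) {
    rec <- bsrem4d(array(counts(proj)[, , , r, ], c(d[1], d[2], d[3], d[5])),
                   system, r, params)
    out[, , , r, ] <- rec@volumes
  }
  out / proj@scaleFactor
}

#' Run the full method-comparison experiment
#'
#' For every lesion location and noise realization: simulates the dual-gated
#' acquisition, reconstructs all gates under matched and (if requested)
#' averaged attenuation, applies respiratory motion-compensated filtering
#' for the RMC arms, computes relative RMSE and SSIM per (respiratory,
#' cardiac) gate against the ideal images, and finally runs the channelized
#' Hotelling observer study at the end-diastole gate of the reference
#' respiratory phase with pairwise bootstrap comparisons between arms.
#' Deterministic given the configuration (including \code{base_seed}).
#'
#' @param config an \code{\link{experimentConfig}}.
#' @param verbose print per-stage progress to stderr.
#' @return a list of class \code{ResultsTable}: \code{metrics} (long-format
#'   data.frame), \code{observer} (Az per arm and lesion),
#'   \code{comparisons} (pairwise bootstrap results), \code{call_log}, and
#'   the \code{config}.
#' @export
runExperiment <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "ExperimentConfig"))
  say <- function(...) if (verbose) message(...)
  arms <- config$arms
  needMAC <- any(armMode(arms) == "matched")
  needAAC <- any(armMode(arms) == "averaged")
  geom <- config$geometry
  metrics <- list(); observer <- list(); comparisons <- list()
  call_log <- character(0)
  roi <- lvRoi(config$phantom)
  win <- choWindow(config$phantom)
  refr <- config$cho_ref_resp_gate
  for (loc in config$lesion_locations) {
    say("lesion: ", loc)
    pcfg <- config$phantom
    base_les <- if (!is.null(pcfg$lesion)) pcfg$lesion
      else list(uptake_reduction = 0.20, long_axis_extent = 20,
                circumferential_extent = 100)
    pcfg$lesion <- utils::modifyList(base_les, list(location = loc))
    ph_p <- generatePhantom(pcfg)
    pcfg_a <- pcfg; pcfg_a$lesion <- NULL
    ph_a <- generatePhantom(pcfg_a)
    ideal <- idealReconstruction(ph_p, geom, 10L, config$ideal_subsets)
    # known channel signal for the SKE observer: ideal present minus ideal
    # absent at the observer window
    cho_signal <- NULL
    if (config$run_observer) {
      ideal_a <- idealReconstruction(ph_a, geom, 10L, config$ideal_subsets)
      winImg <- function(v5)
        bilinearResize(v5[win$x, win$y, win$z, refr, 1], 140L)
      cho_signal <- choChannels(winImg(ideal)) - choChannels(winImg(ideal_a))
    }
    sysM <- systemModel(geom, "matched", attenuation(ph_p))
    sysA <- systemModel(geom, "averaged",
                        averageAttenuation(attenuation(ph_p)))
    R <- pcfg$n_resp_gates; K <- pcfg$n_card_gates
    # data-adaptive prior weights, fixed across arms and realizations
    probe <- simulateAcquisition(ph_p, geom, config$total_counts,
                                 config$base_seed + 1L,
                                 config$scatter_fraction)
    d <- dim(counts(probe))
    sc <- betaAutoScale(array(counts(probe)[, , , 1, ],
                              c(d[1], d[2], d[3], K)),
                        sysM, 1L, config$recon$n_subsets)
    params <- config$recon
    params$beta_s <- config$beta_rel_s * sc[["beta_s"]]
    params$beta_t <- config$beta_rel_t * sc[["beta_t"]]
    cho_p <- stats::setNames(vector("list", length(arms)), arms)
    cho_a <- stats::setNames(vector("list", length(arms)), arms)
    for (i in seq_len(config$n_noise_realizations)) {
      say("  realization ", i)
      seed_i <- config$base_seed + i
      proj_p <- simulateAcquisition(ph_p, geom, config$total_counts,
                                    seed_i, config$scatter_fraction)
      proj_a <- simulateAcquisition(ph_a, geom, config$total_counts,
                                    seed_i + 500000L,
                                    config$scatter_fraction)
      recsP <- list(); recsA <- list()
      if (needMAC) {
        recsP$matched <- reconAllPhases(proj_p, sysM, params)
        recsA$matched <- reconAllPhases(proj_a, sysM, params)
      }
      if (needAAC) {
        recsP$averaged <- reconAllPhases(proj_p, sysA, params)
        recsA$averaged <- reconAllPhases(proj_a, sysA, params)
      }
      for (arm in arms) {
        mode <- armMode(arm)
        volP <- recsP[[mode]]; volA <- recsA[[mode]]
        if (armUsesRmc(arm)) {
          call_log <- c(call_log, paste0("rmc:", arm, ":real", i))
          volP <- rmc(volP, config$weight_scheme)
          volA <- rmc(volA, config$weight_scheme)
        }
        for (r in seq_len(R)) for (k in seq_len(K)) {
          metrics[[length(metrics) + 1]] <- data.frame(
            arm = arm, lesion = loc, resp_gate = r, card_gate = k,
            realization = i,
            rmse = relativeRMSE(volP[, , , r, k], ideal[, , , r, k], roi),
            ssim = ssimIndex(volP[, , , r, k], ideal[, , , r, k], roi))
        }
        toCho <- function(vol5) {
          sl <- vol5[win$x, win$y, win$z, refr, 1]
          bilinearResize(sl, 140L)
        }
        cho_p[[arm]] <- c(cho_p[[arm]], list(toCho(volP)))
        cho_a[[arm]] <- c(cho_a[[arm]], list(toCho(volA)))
      }
    }
    if (!config$run_observer) next
    obs <- lapply(arms, function(arm)
      choStudy(cho_p[[arm]], cho_a[[arm]], config$internal_noise_level,
               seed = config$base_seed + 909L, signal = cho_signal))
    names(obs) <- arms
    for (arm in arms)
      observer[[length(observer) + 1]] <- data.frame(
        arm = arm, lesion = loc, az = az(obs[[arm]]))
    if (length(arms) > 1) {
      prs <- utils::combn(arms, 2, simplify = FALSE)
      for (pr in prs) {
        bc <- bootstrapCompare(obs[[pr[1]]], obs[[pr[2]]], 2000L,
                               seed = config$base_seed + 4242L)
        comparisons[[length(comparisons) + 1]] <- data.frame(
          arm_a = pr[1], arm_b = pr[2], lesion = loc,
          delta_az = bc$delta_az, p_value = bc$p_value)
      }
    }
  }
  res <- list(metrics = do.call(rbind, metrics),
              observer = do.call(rbind, observer),
              comparisons = if (length(comparisons))
                do.call(rbind, comparisons) else NULL,
              call_log = call_log, config = config)
  class(res) <- "ResultsTable"
  res
}

#' Summarize a results table
#'
#' Per (arm, lesion, respiratory gate): mean and standard deviation of each
#' metric over cardiac gates and noise realizations, plus pairwise percent
#' improvements between arms on the gate-averaged means,
#' \code{(a - b)/b * 100}.
#'
#' @param table a \code{ResultsTable} from \code{\link{runExperiment}}.
#' @return list with \code{by_gate} and \code{improvements} data.frames.
#' @export
summarizeResults <- function(table) {
  m <- table$metrics
  if (is.null(m) || nrow(m) == 0) stop("empty results table")
  key <- interaction(m$arm, m$lesion, m$resp_gate, drop = FALSE)
  full <- expand.grid(arm = unique(m$arm), lesion = unique(m$lesion),
                      resp_gate = unique(m$resp_gate))
  have <- unique(m[c("arm", "lesion", "resp_gate")])
  miss <- setdiff(do.call(paste, full), do.call(paste, have))
  if (length(miss)) stop("missing cells: ", paste(miss, collapse = "; "))
  agg <- function(metric) {
    a <- stats::aggregate(m[[metric]],
                          m[c("arm", "lesion", "resp_gate")],
                          function(v) c(mean = mean(v),
                                        sd = if (length(v) > 1)
                                          stats::sd(v) else 0))
    data.frame(a[1:3], metric = metric, mean = a$x[, "mean"],
               sd = a$x[, "sd"])
  }
  by_gate <- rbind(agg("rmse"), agg("ssim"))
  arms <- unique(m$arm)
  imps <- list()
  for (metric in c("rmse", "ssim"))
    for (loc in unique(m$lesion))
      for (a1 in arms) for (a2 in arms) {
        sub <- by_gate[by_gate$metric == metric & by_gate$lesion == loc, ]
        m1 <- mean(sub$mean[sub$arm == a1])
        m2 <- mean(sub$mean[sub$arm == a2])
        imps[[length(imps) + 1]] <- data.frame(
          metric = metric, lesion = loc, arm_a = a1, arm_b = a2,
          pct_improvement = (m1 - m2) / m2 * 100)
      }
  list(by_gate = by_gate[order(by_gate$metric, by_gate$arm,
                               by_gate$lesion, by_gate$resp_gate), ],
       improvements = do.call(rbind, imps))
}

#' Export / read a results table
#'
#' Writes the long-format metric records and observer summaries as CSV or
#' JSON with stable ordering; \code{readResults} round-trips them.
#'
#' @param table a \code{ResultsTable}.
#' @param dir output directory (created if missing).
#' @param format "csv" or "json".
#' @return invisibly, the written file paths.
#' @export
exportResults <- function(table, dir, format = c("csv", "json")) {
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ord <- function(df) df[do.call(order, df[seq_len(min(5, ncol(df)))]), ,
                         drop = FALSE]
  parts <- list(metrics = table$metrics, observer = table$observer,
                comparisons = table$comparisons)
  parts <- lapply(Filter(Negate(is.null), parts), ord)
  paths <- character(0)
  for (nm in names(parts)) {
    if (format == "csv") {
      p <- file.path(dir, paste0(nm, ".csv"))
      utils::write.csv(parts[[nm]], p, row.names = FALSE)
    } else {
      p <- file.path(dir, paste0(nm, ".json"))
      jsonlite::write_json(parts[[nm]], p, digits = NA, dataframe = "rows")
    }
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' @rdname exportResults
#' @export
readResults <- function(dir, format = c("csv", "json")) {
  format <- match.arg(format)
  rd <- function(nm) {
    p <- file.path(dir, paste0(nm, ".", format))
    if (!file.exists(p)) return(NULL)
    if (format == "csv") utils::read.csv(p, stringsAsFactors = FALSE)
    else as.data.frame(jsonlite::read_json(p, simplifyVector = TRUE))
  }
  res <- list(metrics = rd("metrics"), observer = rd("observer"),
              comparisons = rd("comparisons"))
  class(res) <- "ResultsTable"
  res
}
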