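# small single-slice instance shared across the solver tests
reconFixture <- local({
  fix <- NULL
  function() {
    if (!is.null(fix)) return(fix)
    n <- 8L
    g <- systemGeometry(n_views = 8L, detector_bins = c(n, 1L), bin_size = 1,
                        rotation_radius = 12, blur_enabled = TRUE)
    co <- seq_len(n) - (n + 1) / 2
    act1 <- array(exp(-outer(co^2, co^2, "+") / 8), c(n, n, 1)) * 10
    act2 <- act1 * 1.2
    mu <- array(0.05, c(n, n, 1, 1))
    s <- systemModel(g, "matched", mu)
    p1 <- forwardProject(act1, s, 1L)
    p2 <- forwardProject(act2, s, 1L)
    set.seed(4)
    noisy <- array(stats::rpois(length(p1) * 2, c(p1, p2) * 30),
                   c(n, 1, 8, 2))
    fix <<- list(n = n, g = g, s = s, act = list(act1, act2),
                 clean = array(c(p1, p2) * 30, c(n, 1, 8, 2)),
                 noisy = noisy)
    fix
  }
})

test_that("one-subset OSEM matches an independent dense-matrix MLEM oracle", {
  fx <- reconFixture()
  d3 <- c(fx$n, fx$n, 1L)
  H <- denseH(fx$s, d3)
  p <- fx$noisy[, , , 1]
  x_oracle <- mlemOracle(H, as.numeric(p), 5L)
  x_pkg <- osem(array(p, c(fx$n, 1, 8)), fx$s, 1L, n_iterations = 5L,
                n_subsets = 1L, nonneg_floor = 0)
  expect_lt(max(abs(as.numeric(x_pkg) - x_oracle)) / max(x_oracle), 1e-8)
})

test_that("MLEM log-likelihood is non-decreasing", {
  fx <- reconFixture()
  p <- array(fx$noisy[, , , 1], c(fx$n, 1, 8))
  ll <- numeric(6)
  for (it in 1:6) {
    x <- osem(p, fx$s, 1L, n_iterations = it, n_subsets = 1L)
    q <- forwardProject(x, fx$s, 1L)
    pos <- q > 0
    ll[it] <- sum(p[pos] * log(q[pos])) - sum(q)
  }
  expect_true(all(diff(ll) >= -1e-8))
})

test_that("prior-free single-subset BSREM reduces exactly to MLEM", {
  fx <- reconFixture()
  pp <- reconParams(n_iterations = 5L, n_subsets = 1L, beta_s = 0,
                    beta_t = 0, alpha0 = 1, decay = 0,
                    track_objective = FALSE)
  rec <- bsrem4d(fx$noisy, fx$s, 1L, pp)
  H <- denseH(fx$s, c(fx$n, fx$n, 1L))
  for (k in 1:2) {
    x_oracle <- mlemOracle(H, as.numeric(fx$noisy[, , , k]), 5L)
    err <- abs(as.numeric(rec@volumes[, , , k]) - x_oracle)
    # the MLEM oracle has no positivity floor; compare where it matters
    expect_lt(max(err) / max(x_oracle), 1e-6)
  }
})

test_that("penalized objective is non-decreasing over the late iterations", {
  fx <- reconFixture()
  sc <- betaAutoScale(fx$noisy, fx$s, 1L, 1L)
  pp <- reconParams(n_iterations = 30L, n_subsets = 1L,
                    beta_s = 0.05 * sc[["beta_s"]],
                    beta_t = 0.05 * sc[["beta_t"]], alpha0 = 1, decay = 0.3,
                    cardiac_dvf_source = "identity")
  rec <- bsrem4d(fx$noisy, fx$s, 1L, pp)
  ob <- objectiveTrace(rec)
  expect_length(ob, 30L)
  expect_true(all(diff(ob[7:30]) >= -1e-8))
  expect_true(all(rec@volumes >= 0))
  expect_false(any(is.na(rec@volumes)))
})

test_that("stronger spatial smoothing lowers within-support variance", {
  fx <- reconFixture()
  sc <- betaAutoScale(fx$noisy, fx$s, 1L, 1L)
  supp <- fx$act[[1]] > 0.5
  vars <- vapply(c(0, 0.01, 0.1, 1), function(b) {
    pp <- reconParams(n_iterations = 30L, n_subsets = 1L,
                      beta_s = b * sc[["beta_s"]], beta_t = 0, alpha0 = 1,
                      decay = 0.3, cardiac_dvf_source = "identity",
                      track_objective = FALSE)
    r <- bsrem4d(fx$noisy, fx$s, 1L, pp)
    stats::var(r@volumes[, , , 1][supp])
  }, numeric(1))
  expect_true(all(diff(vars) < 0))
})

test_that("Gibbs energy matches trivial cases and a brute-force enumeration", {
  u <- array(3, c(4, 4, 2, 2))
  gb <- gibbsEnergy(u, 1, 1, NULL)
  expect_equal(gb$U_s, 0)
  expect_equal(gb$U_t, 0)  # identical gates, identity fields
  expect_equal(gb$energy, 0)
  # 2x2x1 checkerboard, one gate
  cb <- array(c(0, 1, 1, 0), c(2, 2, 1, 1))
  # brute force: sum over voxels and their in-grid 6-neighbors of half the
  # squared difference
  brute <- 0
  for (i in 1:2) for (j in 1:2)
    for (nb in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      ii <- i + nb[1]; jj <- j + nb[2]
      if (ii >= 1 && ii <= 2 && jj >= 1 && jj <= 2)
        brute <- brute + 0.5 * (cb[i, j, 1, 1] - cb[ii, jj, 1, 1])^2
    }
  expect_equal(gibbsEnergy(cb, 1, 0, NULL)$U_s, brute)
  # analytic gradient agrees with central finite differences
  set.seed(5)
  x <- array(runif(4 * 4 * 2 * 2), c(4, 4, 2, 2))
  dvfs <- lapply(1:2, function(k)
    array(runif(4 * 4 * 2 * 3, -0.3, 0.3), c(4, 4, 2, 3)))
  gb <- gibbsEnergy(x, 0.7, 1.3, dvfs)
  idx <- sample(length(x), 10)
  eps <- 1e-6
  num <- vapply(idx, function(i) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    (gibbsEnergy(xp, 0.7, 1.3, dvfs)$energy -
       gibbsEnergy(xm, 0.7, 1.3, dvfs)$energy) / (2 * eps)
  }, numeric(1))
  expect_equal(num, gb$gradient[idx], tolerance = 1e-4)
  bad <- list(array(0, c(3, 3, 3, 3)), array(0, c(3, 3, 3, 3)))
  expect_error(gibbsEnergy(x, 0, 1, bad), "shape mismatch")
})

test_that("zero respiratory motion makes MAC and AAC reconstructions agree", {
  cfg <- tinyPhantomConfig(R = 2L, K = 2L, resp_amplitude_si = 0,
                           resp_amplitude_ap = 0,
                           diaphragm_amplitude_si = 0)
  ph <- generatePhantom(cfg)
  g <- tinyGeometry(n_views = 8L)
  proj <- simulateAcquisition(ph, g, 2e5, seed = 3L, scatter_fraction = 0)
  sysM <- systemModel(g, "matched", attenuation(ph))
  sysA <- systemModel(g, "averaged", averageAttenuation(attenuation(ph)))
  d <- dim(counts(proj))
  p1 <- array(counts(proj)[, , , 1, ], c(d[1], d[2], d[3], d[5]))
  pp <- reconParams(n_iterations = 4L, n_subsets = 4L,
                    track_objective = FALSE)
  recM <- bsrem4d(p1, sysM, 1L, pp)
  recA <- bsrem4d(p1, sysA, 1L, pp)
  rel <- max(abs(recM@volumes - recA@volumes)) / max(recM@volumes)
  expect_lt(rel, 1e-6)
})

test_that("ideal reconstruction conserves activity and is zero for zero", {
  cfg <- tinyPhantomConfig(R = 1L, K = 1L, lesion = NULL)
  ph <- generatePhantom(cfg)
  g <- tinyGeometry(n_views = 16L)
  ideal <- idealReconstruction(ph, g, n_iterations = 10L, n_subsets = 16L)
  tot_true <- sum(activity(ph)[, , , 1, 1])
  expect_lt(abs(sum(ideal) - tot_true) / tot_true, 0.01)
  ph0 <- ph
  ph0@activity[] <- 0
  expect_equal(max(idealReconstruction(ph0, g, 2L, 4L)), 0)
})

test_that("selectBeta returns the exhaustive-grid argmin deterministically", {
  fx <- reconFixture()
  # ideal volumes: the ML solution of the clean data
  pp <- reconParams(n_iterations = 6L, n_subsets = 1L,
                    track_objective = FALSE)
  ideal <- osem(fx$clean, fx$s, 1L, n_iterations = 6L, n_subsets = 1L)
  sc <- betaAutoScale(fx$noisy, fx$s, 1L, 1L)
  grid <- expand.grid(beta_s = c(0, 0.05, 0.5) * sc[["beta_s"]],
                      beta_t = c(0, 0.05) * sc[["beta_t"]])
  sel <- selectBeta(grid, fx$noisy, fx$s, ideal, roi = NULL, params = pp)
  expect_equal(min(sel$table$rmse),
               sel$table$rmse[sel$table$beta_s == sel$beta_s &
                              sel$table$beta_t == sel$beta_t][1])
  sel2 <- selectBeta(grid, fx$noisy, fx$s, ideal, roi = NULL, params = pp)
  expect_identical(sel$table, sel2$table)  # fixed input, fixed outcome
  # noise-free data: maximum likelihood is exact, beta = 0 wins
  sel0 <- selectBeta(grid, fx$clean, fx$s, ideal, roi = NULL, params = pp)
  expect_equal(sel0$beta_s, 0)
  expect_equal(sel0$beta_t, 0)
  expect_error(selectBeta(grid[0, ], fx$noisy, fx$s, ideal), "nonempty")
})

test_that("ten-fold more counts lowers the reconstruction error", {
  cfg <- tinyPhantomConfig(R = 1L, K = 2L)
  ph <- generatePhantom(cfg)
  g <- tinyGeometry(n_views = 8L)
  ideal <- idealReconstruction(ph, g, n_iterations = 6L, n_subsets = 8L)
  pp <- reconParams(n_iterations = 6L, n_subsets = 4L,
                    track_objective = FALSE)
  sysM <- systemModel(g, "matched", attenuation(ph))
  err <- vapply(c(2e5, 2e6), function(tc) {
    proj <- simulateAcquisition(ph, g, tc, seed = 10L, scatter_fraction = 0)
    d <- dim(counts(proj))
    p1 <- array(counts(proj)[, , , 1, ], c(d[1], d[2], d[3], d[5]))
    rec <- bsrem4d(p1, sysM, 1L, pp)
    vols <- rec@volumes / proj@scaleFactor
    mean(vapply(1:2, function(k)
      relativeRMSE(vols[, , , k], ideal[, , , 1, k]), numeric(1)))
  }, numeric(1))
  expect_lt(err[2], err[1])
})
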