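test_that("relative RMSE matches closed forms and a brute-force loop", {
  set.seed(1)
  a <- array(runif(6 * 6 * 4), c(6, 6, 4))
  expect_equal(relativeRMSE(a, a), 0)
  expect_equal(relativeRMSE(1.1 * a, a), 0.1, tolerance = 1e-12)
  b <- array(runif(6 * 6 * 4), c(6, 6, 4))
  num <- den <- 0
  for (i in seq_along(a)) {
    num <- num + (a[i] - b[i])^2
    den <- den + b[i]^2
  }
  expect_equal(relativeRMSE(a, b), sqrt(num) / sqrt(den),
               tolerance = 1e-12)
  roi <- roiSpec(c(2, 2, 2), c(3, 3, 2))
  expect_gt(relativeRMSE(a, b, roi), 0)
  expect_error(relativeRMSE(a, array(0, c(6, 6, 4))), "identically zero")
  expect_error(relativeRMSE(a, b[1:5, , ]), "shape")
})

test_that("SSIM is 1 for identical images, symmetric, and matches an oracle", {
  set.seed(2)
  a <- array(runif(10 * 10 * 2), c(10, 10, 2))
  b <- a + array(rnorm(200, 0, 0.1), c(10, 10, 2))
  b <- pmax(b, 0)
  expect_equal(ssimIndex(a, a), 1)
  expect_equal(ssimIndex(a, b), ssimIndex(b, a), tolerance = 1e-12)
  # independent windowed-statistics oracle (7x7 uniform window, per slice)
  L <- max(a, b)
  C1 <- (0.01 * L)^2; C2 <- (0.03 * L)^2
  vals <- c()
  for (z in 1:2) for (i in 1:4) for (j in 1:4) {
    wx <- a[i:(i + 6), j:(j + 6), z]
    wy <- b[i:(i + 6), j:(j + 6), z]
    mx <- mean(wx); my <- mean(wy)
    vx <- mean(wx^2) - mx^2; vy <- mean(wy^2) - my^2
    cxy <- mean(wx * wy) - mx * my
    vals <- c(vals, ((2 * mx * my + C1) * (2 * cxy + C2)) /
                ((mx^2 + my^2 + C1) * (vx + vy + C2)))
  }
  expect_equal(ssimIndex(a, b), mean(vals), tolerance = 1e-10)
  expect_error(ssimIndex(a[1:5, 1:5, , drop = FALSE],
                         b[1:5, 1:5, , drop = FALSE]), "window")
})

test_that("intensity profiles index the volume and cross the wall twice", {
  v <- array(7, c(5, 5, 5))
  expect_equal(intensityProfile(v, 3, 3), rep(7, 5))
  set.seed(3)
  w <- array(runif(125), c(5, 5, 5))
  expect_equal(intensityProfile(w, 2, 4, 2:4), w[2:4, 4, 2])
  expect_error(intensityProfile(w, 6, 1), "out of range")
  # a line through the LV shows two wall crossings
  cfg <- tinyPhantomConfig(R = 1L, K = 1L, lesion = NULL)
  ph <- generatePhantom(cfg)
  ctr <- round(cfg$lv_geometry$center / cfg$voxel_size +
                 (cfg$grid_shape + 1) / 2)
  prof <- intensityProfile(activity(ph)[, , , 1, 1], ctr[3], ctr[2])
  wall <- cfg$organ_uptake[["lv_wall"]]
  runs <- rle(prof == wall)
  expect_equal(sum(runs$values), 2)
})

test_that("CHO channels are linear, non-overlapping, and band-selective", {
  expect_equal(choChannels(matrix(0, 140, 140)), rep(0, 4))
  tpl <- dgspect:::choTemplates(140L)
  for (a in 1:3) for (b in (a + 1):4)
    expect_lt(abs(sum(tpl[[a]] * tpl[[b]])), 1e-12)
  # pure radial-frequency sinusoid lands in exactly one passband
  f <- 10 / 140  # 0.0714 cycles/pixel, inside (1/16, 1/8]
  x <- outer(cos(2 * pi * f * (0:139)), rep(1, 140))
  r <- choChannels(x)
  expect_gt(abs(r[3]) / sum(abs(r)), 0.9)
  # direct spectral check of the band bounds
  expect_true(f > 1 / 16 && f <= 1 / 8)
  expect_error(choChannels(matrix(0, 100, 100)), "140")
})

test_that("bilinear resize is exact on affine images", {
  img <- outer(1:8, 1:8, function(i, j) 2 * i + 3 * j)
  out <- bilinearResize(img, 29L)
  # corner alignment and linear interpolation reproduce the affine ramp
  expect_equal(out[1, 1], img[1, 1])
  expect_equal(out[29, 29], img[8, 8])
  pos <- (seq_len(29) - 1) * 7 / 28 + 1
  expect_equal(out, outer(pos, pos, function(i, j) 2 * i + 3 * j),
               tolerance = 1e-12)
})

test_that("rank-sum Az matches exhaustive pair enumeration", {
  expect_equal(rocAz(c(3, 4, 5), c(0, 1, 2)), 1)
  expect_equal(rocAz(c(1, 2), c(1, 2)), 0.5)
  set.seed(4)
  sp <- rnorm(5); sa <- rnorm(5)
  brute <- 0
  for (i in 1:5) for (j in 1:5)
    brute <- brute + (sp[i] > sa[j]) + 0.5 * (sp[i] == sa[j])
  expect_equal(rocAz(sp, sa), brute / 25)
  expect_error(rocAz(numeric(0), sa), "nonempty")
  # invariance under strictly monotone transforms
  expect_equal(rocAz(exp(sp), exp(sa)), rocAz(sp, sa))
  expect_equal(rocAz(sp^3, sa^3), rocAz(sp, sa))
})

test_that("observer study handles null, perfect and reproducible cases", {
  set.seed(5)
  v <- matrix(rnorm(30 * 4), 30, 4)
  # identical ensembles, no internal noise: zero mean difference, all ties
  expect_equal(az(choStudy(v, v, 0, seed = 7L)), 0.5)
  # identical ensembles with internal noise, fixed template: chance level
  null_az <- mean(vapply(1:20, function(s)
    az(choStudy(v, v, 0.5, seed = s, template = c(1, 1, 1, 1))),
    numeric(1)))
  expect_lt(abs(null_az - 0.5), 0.05)
  sep <- choStudy(v + 100, v, internal_noise_level = 0, seed = 1L)
  expect_equal(az(sep), 1)
  a1 <- choStudy(v + 0.5, v, internal_noise_level = 0.5, seed = 3L)
  a2 <- choStudy(v + 0.5, v, internal_noise_level = 0.5, seed = 3L)
  expect_identical(a1@decisionPresent, a2@decisionPresent)
  expect_identical(az(a1), az(a2))
})

test_that("internal noise never increases the expected Az", {
  set.seed(6)
  dmu <- c(1, 0.5, 0.25, 0.1) * 0.8
  vp <- matrix(rnorm(30 * 4), 30, 4) + matrix(dmu, 30, 4, byrow = TRUE)
  va <- matrix(rnorm(30 * 4), 30, 4)
  azm <- vapply(c(0, 0.5, 2, 5), function(lvl)
    mean(vapply(1:40, function(s) az(choStudy(vp, va, lvl, seed = s)),
                numeric(1))), numeric(1))
  expect_true(all(diff(azm) <= 0.005))
})

test_that("estimated-template Az sits at or slightly above the ideal value", {
  # resubstitution training is known to be mildly optimistic; the estimated
  # observer should track the known-moments observer from above
  dA <- 1.2
  dmu <- c(1, 0.5, 0.25, 0.1)
  dmu <- dmu * dA / sqrt(sum(dmu^2))  # identity covariance
  set.seed(8)
  d_est <- d_true <- numeric(60)
  for (r in 1:60) {
    vp <- matrix(rnorm(30 * 4), 30, 4) + matrix(dmu, 30, 4, byrow = TRUE)
    va <- matrix(rnorm(30 * 4), 30, 4)
    d_est[r] <- az(choStudy(vp, va, 0, seed = r))
    d_true[r] <- az(choStudy(vp, va, 0, seed = r, template = dmu))
  }
  target <- pnorm(dA / sqrt(2))
  expect_gt(mean(d_est), target - 0.01)
  expect_lt(mean(d_est) - target, 0.06)
  expect_lt(abs(mean(d_true) - target), 3 * stats::sd(d_true) / sqrt(60))
})

test_that("bootstrap comparison is null for self and powered for separation", {
  set.seed(9)
  v <- matrix(rnorm(30 * 4), 30, 4)
  res <- choStudy(v + 0.7, v, 0.5, seed = 2L)
  self <- bootstrapCompare(res, res, n_boot = 500L, seed = 1L)
  expect_equal(self$delta_az, 0)
  expect_equal(self$p_value, 1)
  # Az 0.95 vs 0.55: significant in at least 95% of seeded runs
  d95 <- sqrt(2) * qnorm(0.95)
  d55 <- sqrt(2) * qnorm(0.55)
  hits <- 0L
  n_runs <- 100L
  for (run in seq_len(n_runs)) {
    set.seed(1000L + run)
    ra <- methods::new("ObserverResult",
                       decisionPresent = rnorm(30, d95),
                       decisionAbsent = rnorm(30), az = 0.95,
                       channelMatrix = matrix(0, 1, 1),
                       internalNoiseLevel = 0, seed = 1L)
    rb <- methods::new("ObserverResult",
                       decisionPresent = rnorm(30, d55),
                       decisionAbsent = rnorm(30), az = 0.55,
                       channelMatrix = matrix(0, 1, 1),
                       internalNoiseLevel = 0, seed = 1L)
    bc <- bootstrapCompare(ra, rb, n_boot = 2000L, seed = run)
    if (bc$p_value < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / n_runs, 0.95)
})
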