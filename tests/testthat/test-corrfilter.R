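test_that("frequency-domain correlation matches the spatial double loop", {
  set.seed(20)
  for (rep in 1:10) {
    x <- matrix(rnorm(64), 8, 8)
    m <- matrix(rnorm(64), 8, 8)
    expect_equal(correlate(x, m), brute_circcorr(x, m), tolerance = 1e-10)
  }
  # multi-channel: sum over channels
  x2 <- list(matrix(rnorm(64), 8, 8), matrix(rnorm(64), 8, 8))
  m2 <- list(matrix(rnorm(64), 8, 8), matrix(rnorm(64), 8, 8))
  expect_equal(correlate(x2, m2),
               brute_circcorr(x2[[1]], m2[[1]]) + brute_circcorr(x2[[2]], m2[[2]]),
               tolerance = 1e-10)
  expect_error(correlate(x, matrix(0, 4, 4)), "shapes")
})

test_that("correlation with a unit impulse at zero shift is the identity", {
  set.seed(21)
  x <- matrix(rnorm(48), 6, 8)
  imp <- matrix(0, 6, 8); imp[1, 1] <- 1
  expect_equal(correlate(x, imp), x, tolerance = 1e-10)
  auto <- correlate(x, x)
  expect_equal(unname(which(auto == max(auto), arr.ind = TRUE)[1, ]), c(1, 1))
})

test_that("Gaussian kernel correlation has its self-match limits", {
  set.seed(22)
  x <- matrix(rnorm(16), 4, 4)
  k <- gaussian_kernel_correlation(x, x, 0.5)
  expect_equal(k[1, 1], 1)                       # zero distance at zero shift
  expect_equal(unname(which(k == max(k), arr.ind = TRUE)[1, ]), c(1, 1))
  k_inf <- gaussian_kernel_correlation(x, matrix(rnorm(16), 4, 4), 1e6)
  expect_true(all(abs(k_inf - 1) < 1e-6))        # sigma -> Inf: all ones
  expect_error(gaussian_kernel_correlation(x, x, -1), "positive")
})

test_that("kernel correlation equals direct evaluation over all shifts", {
  set.seed(23)
  x <- matrix(rnorm(16), 4, 4)
  z <- matrix(rnorm(16), 4, 4)
  expect_equal(gaussian_kernel_correlation(x, z, 0.7),
               brute_kernel_corr(x, z, 0.7), tolerance = 1e-8)
})

test_that("the position filter self-detects at zero displacement", {
  p <- shifted_pair(dx = 0, dy = 0)
  pf <- pf_init(p$f1, p$box, run_config(use_scale = FALSE))
  det <- pf_detect(pf, p$f1, c(p$box[[1]] + p$box[[3]] / 2,
                               p$box[[2]] + p$box[[4]] / 2))
  expect_lt(sqrt(sum(det$disp^2)), 0.5)
})

test_that("a pure translation is recovered by the position filter", {
  for (cfgname in c("gray", "gray+hog")) {
    p <- shifted_pair(dx = 4, dy = 1)
    cfg <- run_config(features = cfgname)
    pf <- pf_init(p$f1, p$box, cfg)
    ctr <- c(p$box[[1]] + p$box[[3]] / 2, p$box[[2]] + p$box[[4]] / 2)
    det <- pf_detect(pf, p$f2, ctr)
    expect_lt(abs(det$disp[1] - 4), 1.2)
    expect_lt(abs(det$disp[2] - 1), 1.2)
  }
})

test_that("detection is equivariant under cyclic shifts of the window", {
  set.seed(24)
  f <- matrix(runif(80 * 80) * 255, 80, 80)
  box <- bbox(30, 30, 16, 16)
  pf <- pf_init(f, box, run_config(features = "gray"))
  ctr <- bbox_center(box)
  for (shift in list(c(3, 0), c(0, 2), c(4, 3))) {
    det <- pf_detect(pf, f, ctr - shift)   # moving the window moves the peak
    expect_lt(abs(det$disp[1] - shift[1]), 1)
    expect_lt(abs(det$disp[2] - shift[2]), 1)
  }
})

test_that("the template update is a convex combination with exact endpoints", {
  p <- shifted_pair()
  cfg <- run_config()
  pf <- pf_init(p$f1, p$box, cfg)
  ctr <- c(p$box[[1]] + p$box[[3]] / 2, p$box[[2]] + p$box[[4]] / 2)
  pf0 <- pf_update(pf, p$f2, ctr, theta = 0)
  expect_identical(pf0$alphaf, pf$alphaf)
  expect_identical(pf0$z, pf$z)
  pf1 <- pf_update(pf, p$f2, ctr, theta = 1)
  pf_fresh <- pf_init(p$f2, p$box, cfg)   # full replacement reference
  expect_equal(pf1$alphaf, pf_fresh$alphaf, tolerance = 1e-8)
  pf_half <- pf_update(pf, p$f2, ctr, theta = 0.4)
  lo <- pmin(Re(pf$alphaf), Re(pf1$alphaf)) - 1e-9
  hi <- pmax(Re(pf$alphaf), Re(pf1$alphaf)) + 1e-9
  expect_true(all(Re(pf_half$alphaf) >= lo & Re(pf_half$alphaf) <= hi))
  lo_i <- pmin(Im(pf$alphaf), Im(pf1$alphaf)) - 1e-9
  hi_i <- pmax(Im(pf$alphaf), Im(pf1$alphaf)) + 1e-9
  expect_true(all(Im(pf_half$alphaf) >= lo_i & Im(pf_half$alphaf) <= hi_i))
  expect_error(pf_update(pf, p$f2, ctr, theta = 1.5), "\\[0, 1\\]")
})

test_that("the scale-factor set is symmetric with exactly one unit factor", {
  for (n in c(1, 17, 33)) {
    fac <- fluorotrack:::scale_factors(n, 1.02)
    expect_equal(sum(fac == 1), 1)
    expect_equal(sort(fac), sort(1 / fac), tolerance = 1e-12)
  }
})

test_that("a static target yields the unit scale factor", {
  s <- render_scene(scene_preset("occlusion_pass", 7))
  f <- s$seq$frames[[1]]
  b <- s$truth$organ$boxes[[1]]
  ctr <- bbox_center(b)
  sf <- sf_init(f, ctr, c(b[[4]], b[[3]]), run_config())
  est <- sf_estimate(sf, f, ctr, 1, update = FALSE)
  expect_equal(est$factor, 1)
})

test_that("the scale filter recovers a gradual zoom incrementally", {
  # ~1% growth per frame, one scale step at a time; the filter updated each
  # frame must follow the zoom to the final size (no watershed correction,
  # so the estimate comes from the scale filter alone)
  s <- render_scene(scene_preset("scale_change", 7))
  n <- length(s$seq$frames)
  r <- track_organ(s$seq, s$truth$organ$boxes[[1]], run_config(correction = FALSE))
  w_final <- r$trajectory$boxes[[n]][[3]]
  w_truth <- s$truth$organ$boxes[[n]][[3]]
  expect_lt(abs(w_final - w_truth) / w_truth, 0.1)
  # and the recovered widths grow rather than shrink
  w <- vapply(r$trajectory$boxes, function(b) b[[3]], numeric(1))
  expect_gt(w[n], w[1])
})

test_that("n_scales = 1 never changes the box size", {
  s <- render_scene(scene_preset("scale_change", 7))
  cfg <- run_config(n_scales = 1, correction = FALSE)
  r <- track_organ(s$seq, s$truth$organ$boxes[[1]], cfg)
  w <- vapply(r$trajectory$boxes, function(b) b[[3]], numeric(1))
  expect_true(all(w == w[1]))
})

test_that("a translating rigid patch is tracked to within 3 px mean error", {
  s <- render_scene(scene_preset("forward_lean", 15))
  r <- track_organ(s$seq, s$truth$chin$boxes[[1]], run_config())
  err <- sqrt(rowSums((r$trajectory$centroids - s$truth$chin$centroids)^2))
  expect_lte(mean(err), 3)
})

test_that("full occlusion freezes the template and the target is reacquired", {
  s <- render_scene(scene_preset("occlusion_pass", 5))
  cfg <- run_config()
  ct <- ct_init(s$seq$frames[[1]], s$truth$organ$boxes[[1]], cfg)
  occl_seen <- FALSE
  errs <- numeric(0)
  for (t in 2:length(s$seq$frames)) {
    alpha_before <- ct$pf$alphaf
    st <- ct_step(ct, s$seq$frames[[t]])
    if (st$occluded) {
      occl_seen <- TRUE
      # update suppressed on every occluded frame: the dual coefficients
      # are bit-identical to what they were before the step
      expect_identical(st$ct$pf$alphaf, alpha_before)
    }
    ct <- st$ct
    errs[t] <- sqrt(sum((bbox_center(st$box) - s$truth$organ$centroids[t, ])^2))
  }
  expect_true(occl_seen)
  n <- length(s$seq$frames)
  expect_lte(mean(errs[(n - 9):n]), 10)    # reacquired after the pass
})

test_that("MOSSE tracks a noise-free translating patch within 2 px", {
  frames <- lapply(1:12, function(t) {
    set.seed(33)
    tex <- matrix(runif(256) * 120 + 60, 16, 16)
    f <- matrix(90, 60, 90)
    x0 <- 20 + 2 * (t - 1)
    f[25:40, x0:(x0 + 15)] <- tex
    f
  })
  seq <- video_sequence(frames)
  r <- mosse_track(seq, bbox(19, 24, 17, 17), run_config())
  truth_x <- 20 + 2 * (seq_along(frames) - 1) + 7.5
  err <- abs(r$trajectory$centroids[, 1] - truth_x)
  expect_true(all(err[2:12] <= 2))
})

test_that("the first-frame MOSSE response approximates the Gaussian target", {
  set.seed(34)
  f <- matrix(runif(70 * 70) * 255, 70, 70)
  box <- bbox(25, 25, 20, 20)
  seq <- video_sequence(list(f, f))
  r <- mosse_track(seq, box, run_config())
  # training-frame self-response peaks at zero displacement
  expect_lt(sqrt(sum((r$trajectory$centroids[2, ] - bbox_center(box))^2)), 1)
})
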