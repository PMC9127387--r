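test_that("rotation by 0 degrees is the identity", {
  f <- matrix(runif(30 * 40) * 255, 30, 40)
  expect_identical(rotate_about(f, rotation_spec(c(10, 10), 0)), f)
})

test_that("90-degree rotation maps pixels per the homogeneous matrix product", {
  # bright pixel at (6,2), center (4,4): translate (2,-2), rotate cw (-2,-2),
  # translate back -> (2,2)
  f <- matrix(0, 9, 9)
  f[2 + 1, 6 + 1] <- 255
  r <- rotate_about(f, rotation_spec(c(4, 4), 90))
  idx <- which(r == max(r), arr.ind = TRUE)
  expect_equal(unname(idx[1, ]), c(2 + 1, 2 + 1))
  expect_equal(max(r), 255)
})

test_that("the translate-rotate-translate composition equals direct rotation about O", {
  set.seed(3)
  for (i in 1:100) {
    th <- runif(1, -179, 180)
    ctr <- runif(2, 5, 20)
    M <- fluorotrack:::rotation_matrix(ctr, th)
    # direct closed form: p' = R (p - O) + O, clockwise in x-right/y-down
    p <- runif(2, 0, 30)
    rad <- th * pi / 180
    R <- matrix(c(cos(rad), -sin(rad), sin(rad), cos(rad)), 2, 2)
    direct <- as.vector(R %*% (p - ctr)) + ctr
    viaM <- fluorotrack:::transform_points(M, matrix(p, 1, 2))
    expect_equal(as.vector(viaM), direct, tolerance = 1e-10)
  }
})

test_that("rotating by theta then -theta is near-lossless away from borders", {
  # smooth image: the residual is pure interpolation loss, not noise
  f <- 100 + 60 * outer(sin(seq(0, 3 * pi, length.out = 100)),
                        cos(seq(0, 4 * pi, length.out = 120)))
  spec <- rotation_spec(c(60, 50), 17)
  back <- rotate_about(rotate_about(f, spec),
                       rotation_spec(spec$center, -spec$angle))
  core <- 20:80
  expect_lt(mean(abs(back[core, core] - f[core, core])), 2)
})

test_that("rotation rejects a center outside the frame", {
  f <- matrix(0, 10, 10)
  expect_error(rotate_about(f, rotation_spec(c(50, 5), 10)), "outside")
})

test_that("contrast stretch maps the observed range onto the output limits", {
  f <- matrix(c(50, 100, 150, 75), 2, 2)
  out <- contrast_stretch(f, stretch_spec(0, 255))
  expect_equal(out[f == 50], 0)
  expect_equal(out[f == 150], 255)
  # direct arithmetic: (100-50)*(255-0)/(150-50)+0 = 127.5
  expect_equal(out[f == 100], 127.5)
})

test_that("stretch is monotone and clipped to the output limits", {
  set.seed(4)
  f <- matrix(runif(400) * 200 + 20, 20, 20)
  out <- contrast_stretch(f, stretch_spec(10, 200))
  expect_true(all(out >= 10 & out <= 200))
  o <- order(as.vector(f))
  expect_true(all(diff(as.vector(out)[o]) >= -1e-9))
})

test_that("invalid stretch limits and constant frames are handled", {
  expect_error(stretch_spec(0, 300), "\\[0, 255\\]")
  expect_error(stretch_spec(100, 50), "o_min")
  f <- matrix(77, 5, 5)
  expect_warning(out <- contrast_stretch(f, stretch_spec()), "constant")
  expect_identical(out, f)
})

test_that("local stretch amplifies low-contrast structure a global stretch cannot", {
  # faint gradient occupying a small band within a full-range frame
  f <- matrix(0, 40, 40)
  f[, 1] <- 255
  f[10:30, 10:30] <- 100 + outer(0:20, 0:20, `+`) / 8
  glob <- contrast_stretch(f, stretch_spec(0, 255, "global"))
  loc <- contrast_stretch(f, stretch_spec(0, 255, "local", window = 15))
  roi <- cbind(rep(10:30, 21) + 1, rep(10:30, each = 21) + 1)
  expect_gt(stats::sd(loc[roi]), stats::sd(glob[roi]))
})

test_that("bilateral filter is scoped to the ROI and fixes constants", {
  f <- matrix(120, 20, 20)
  roi <- bbox(5, 5, 8, 8)
  out <- bilateral_denoise(f, roi, 2, 25)
  expect_equal(out, f)
  f2 <- f
  f2[2, 2] <- 250           # outside the ROI
  out2 <- bilateral_denoise(f2, roi, 2, 25)
  expect_identical(out2[2, 2], 250)
})

test_that("bilateral filter matches the double-loop oracle on the ROI interior", {
  set.seed(5)
  f <- matrix(100 + rnorm(144, sd = 8), 12, 12)
  f[6, 6] <- 220            # salt pixel
  out <- bilateral_denoise(f, bbox(0, 0, 12, 12), 1.5, 30)
  oracle <- brute_bilateral(f, 1.5, 30)
  expect_equal(out, oracle, tolerance = 1e-10)
  expect_lt(out[6, 6], f[6, 6])   # attenuated toward the neighborhood
})

test_that("bilateral filter validates its ROI", {
  f <- matrix(0, 10, 10)
  expect_error(bilateral_denoise(f, bbox(8, 8, 10, 10), 2, 25), "inside")
})

test_that("watershed finds exactly the two dark discs", {
  f <- disc_frame(40, 60, 15, 20, 7)
  f[(col(f) - 1 - 45)^2 + (row(f) - 1 - 20)^2 <= 49] <- 40
  for (lev in c(1, 3, 4)) {
    seg <- watershed_segment(f, bbox(0, 0, 60, 40), c = lev)
    dark <- seg$stats[seg$stats$mean_gray < 120, ]
    expect_equal(nrow(dark), 2)
    # dark regions cover the discs
    m <- matrix(FALSE, 40, 60)
    for (l in dark$label)
      m <- m | fluorotrack:::segmap_region_mask(seg, l, c(40, 60))
    truth <- disc_mask(40, 60, 15, 20, 7) | disc_mask(40, 60, 45, 20, 7)
    expect_gt(sum(m & truth) / sum(truth), 0.9)
  }
})

test_that("a uniform image yields a single region", {
  f <- matrix(128, 20, 20)
  seg <- watershed_segment(f, bbox(0, 0, 20, 20), c = 4)
  expect_equal(nrow(seg$stats), 1)
})

test_that("lowering the segmentation level never decreases the region count", {
  s <- render_scene(scene_preset("side_view", 6))
  f <- s$seq$frames[[10]]
  roi <- bbox(10, 20, 80, 70)
  counts <- vapply(4:1, function(lev)
    nrow(watershed_segment(f, roi, c = lev)$stats), numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("watershed region stats partition the ROI", {
  s <- render_scene(scene_preset("side_view", 6))
  seg <- watershed_segment(s$seq$frames[[5]], bbox(20, 30, 50, 40), c = 2)
  expect_equal(sum(seg$stats$area), sum(seg$labels > 0))
  expect_equal(sum(seg$labels >= 0), 50 * 40)
  expect_error(watershed_segment(s$seq$frames[[5]], bbox(0, 0, 2, 2), c = 2),
               "3x3")
  expect_error(watershed_segment(s$seq$frames[[5]], bbox(0, 0, 20, 20), c = 0),
               ">= 1")
})
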