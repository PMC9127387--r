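test_that("classical difference applies a strict threshold", {
  f <- matrix(100, 5, 5)
  expect_false(any(classical_diff(f, f, 15)))
  g <- f; g[3, 3] <- 115               # differs by exactly m -> background
  expect_false(any(classical_diff(f, g, 15)))
  g[3, 3] <- 116
  expect_equal(sum(classical_diff(f, g, 15)), 1)
  h <- f; h[2:3, 2:3] <- f[2:3, 2:3] + 16
  expect_equal(sum(classical_diff(f, h, 15)), 4)
  expect_error(classical_diff(f, matrix(0, 4, 5), 15), "shapes")
})

test_that("residual mask marks vacated bright pixels only", {
  f_cur <- matrix(200, 6, 6)
  f_cur[1:2, ] <- 40                    # still-dark rows
  seg_p <- matrix(FALSE, 6, 6)
  expect_equal(sum(residual_mask(seg_p, f_cur, 120)), 0)
  seg_p[1:4, 1:3] <- TRUE
  d_seg <- residual_mask(seg_p, f_cur, 120)
  expect_true(all(d_seg[3:4, 1:3]))     # vacated, now bright
  expect_false(any(d_seg[1:2, ]))       # still dark -> kept
  expect_equal(sum(residual_mask(seg_p, matrix(50, 6, 6), 120)), 0)
})

test_that("a stationary target reproduces its previous ROI", {
  f <- disc_frame(40, 40, 20, 20, 8)
  seg_p <- disc_mask(40, 40, 20, 20, 8)
  # morphology disabled: the claim is about the set arithmetic
  r <- improved_diff(f, f, seg_p, bbox(10, 10, 21, 21),
                     run_config(morph_size = 1))
  expect_false(any(r$d_frame))
  expect_false(any(r$d_seg))
  expect_equal(r$seg_c, seg_p)
})

test_that("the combination follows set arithmetic on a toy instance", {
  # hand-set masks; morphology disabled (1x1 element), no fusion
  cfg <- run_config(morph_size = 1, t_diff = 15, t_p = 120,
                    bilateral_sigma_s = 0.4, expand_factor = 1)
  f_prev <- matrix(200, 8, 8)
  f_prev[3:5, 2:4] <- 40               # target at left
  f_cur <- matrix(200, 8, 8)
  f_cur[3:5, 4:6] <- 40                # moved right by 2
  seg_p <- matrix(FALSE, 8, 8); seg_p[3:5, 2:4] <- TRUE
  r <- improved_diff(f_prev, f_cur, seg_p, bbox(0, 0, 8, 8), cfg)
  # expected: union(d_frame, seg_p) minus vacated-bright pixels
  d_frame_exp <- abs(f_cur - f_prev) >= 15
  d_seg_exp <- seg_p & (f_cur > 120)
  expect_equal(r$d_frame, d_frame_exp)
  expect_equal(r$d_seg, d_seg_exp)
  expect_equal(r$seg_c, (d_frame_exp | seg_p) & !d_seg_exp)
  # and that equals the true new footprint here
  expect_equal(r$seg_c, f_cur == 40)
})

test_that("without re-growth the output is a subset of union(d_frame, seg_p)", {
  s <- render_scene(scene_preset("clean_translation", 3))
  cfg <- run_config(morph_size = 1)
  seg_p <- s$truth$bolus$masks[[4]]
  r <- improved_diff(s$seq$frames[[4]], s$seq$frames[[5]], seg_p,
                     fluorotrack:::mask_bbox(seg_p), cfg)
  expect_false(any(r$seg_c & !(r$d_frame | seg_p)))
})

test_that("a moving square is recovered at Dice >= 0.9 with residuals removed", {
  set.seed(6)
  mk <- function(x0) {
    f <- matrix(190, 50, 70) + matrix(rnorm(3500), 50, 70)
    f[20:31, x0:(x0 + 11)] <- 45
    f
  }
  f1 <- mk(20); f2 <- mk(23)
  seg_p <- matrix(FALSE, 50, 70); seg_p[20:31, 20:31] <- TRUE
  truth2 <- matrix(FALSE, 50, 70); truth2[20:31, 23:34] <- TRUE
  pts <- sample_points(seg_p, f1, 0.1, seed = 2)
  r <- improved_diff(f1, f2, seg_p, bbox(19, 19, 13, 13), run_config(),
                     points = pts)
  dice <- 2 * sum(r$seg_c & truth2) / (sum(r$seg_c) + sum(truth2))
  expect_gte(dice, 0.9)
  vacated <- seg_p & !truth2
  expect_lt(sum(r$seg_c & vacated) / sum(vacated), 0.1)
})

test_that("residual cancellation beats the classical difference on vacated areas", {
  s <- render_scene(scene_preset("clean_translation", 13))
  n <- length(s$seq$frames)
  b <- s$truth$bolus$boxes[[1]]
  init <- bbox(b[[1]] - 4, b[[2]] - 4, b[[3]] + 8, b[[4]] + 8)
  imp <- track_improved_diff(s$seq, init, run_config(), seed = 13)
  fp_imp <- 0; fp_cls <- 0
  for (t in 2:n) {
    vacated <- s$truth$bolus$masks[[t - 1]] & !s$truth$bolus$masks[[t]]
    cls <- classical_diff(s$seq$frames[[t - 1]], s$seq$frames[[t]], 15)
    fp_imp <- fp_imp + sum(imp$masks[[t]] & vacated)
    fp_cls <- fp_cls + sum(cls & vacated)
  }
  expect_lt(fp_imp, fp_cls)
})

test_that("the chained detector's persistent state is box, mask and frame only", {
  # memory contract: no background model is accumulated -- the per-step
  # inputs are exactly {previous frame, previous ROI, box}
  expect_named(formals(improved_diff),
               c("f_prev", "f_cur", "seg_p", "box", "cfg", "points"))
})

test_that("chained tracking is deterministic under a fixed seed", {
  s <- render_scene(scene_preset("elevation_view", 21))
  b <- s$truth$bolus$boxes[[1]]
  init <- bbox(b[[1]] - 4, b[[2]] - 4, b[[3]] + 8, b[[4]] + 8)
  r1 <- track_improved_diff(s$seq, init, run_config(), seed = 2)
  r2 <- track_improved_diff(s$seq, init, run_config(), seed = 2)
  expect_identical(r1$masks, r2$masks)
})
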