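test_that("point sampling respects the ratio, membership and mean gray", {
  m <- disc_mask(40, 40, 20, 20, 10)
  f <- matrix(200, 40, 40); f[m] <- 80
  ps <- sample_points(m, f, 0.1, seed = 2)
  expect_equal(nrow(ps$points), round(0.1 * sum(m)))
  expect_true(all(m[cbind(ps$points[, 2] + 1, ps$points[, 1] + 1)]))
  expect_equal(ps$g_avg, 80)
})

test_that("mean gray follows Eq-style arithmetic and tiny regions fall back", {
  m <- matrix(FALSE, 5, 5); m[cbind(1:3, 1:3)] <- TRUE
  f <- matrix(0, 5, 5); f[cbind(1:3, 1:3)] <- c(10, 20, 30)
  ps <- sample_points(m, f, 0.1, seed = 1)   # 0.1 * 3 px rounds to 0 -> fallback
  expect_equal(ps$g_avg, 20)
  expect_equal(nrow(ps$points), 1)
})

test_that("sampling is deterministic under a fixed seed", {
  m <- disc_mask(30, 30, 15, 15, 8)
  f <- matrix(60, 30, 30)
  expect_identical(sample_points(m, f, 0.1, seed = 7),
                   sample_points(m, f, 0.1, seed = 7))
})

test_that("box expansion scales about the center, rounds and clips", {
  expect_equal(unclass(expand_box(bbox(40, 40, 100, 50), 1.2, c(500, 500))),
               unclass(bbox(30, 35, 120, 60)), ignore_attr = TRUE)
  b <- bbox(10, 10, 20, 20)
  expect_equal(unclass(expand_box(b, 1, c(100, 100))), unclass(b),
               ignore_attr = TRUE)
  corner <- expand_box(bbox(0, 0, 20, 20), 1.5, c(25, 25))
  expect_true(corner[[1]] >= 0 && corner[[2]] >= 0)
  expect_true(corner[[1]] + corner[[3]] <= 25)
  expect_error(expand_box(b, 0.5, c(100, 100)), ">= 1")
})

test_that("region evaluation computes the weighted vote", {
  f <- matrix(100, 20, 20)
  region <- matrix(FALSE, 20, 20); region[1:10, 1:10] <- TRUE
  pts <- structure(list(points = cbind(c(2, 4, 6, 8, 3, 5, 7, 2, 4, 6),
                                       c(2, 4, 6, 8, 3, 5, 7, 4, 6, 8)),
                        gamma_p = 0.1, g_avg = 100),
                   class = "discrete_points")
  # all 10 points inside; theta = (0,1,0,0) -> Eva = 1
  cfg <- run_config(theta0 = 0, theta1 = 1, theta2 = 0, theta3 = 0)
  expect_equal(evaluate_region(region, pts, f, cfg), 1)
  # theta = (0,0,0,1), region gray equals g_avg -> Eva = 0
  cfg <- run_config(theta0 = 0, theta1 = 0, theta2 = 0, theta3 = 1)
  expect_equal(evaluate_region(region, pts, f, cfg), 0)
  # 5 of 10 points in a 50-px region, theta = (0,1,1,0) -> 0.5 + 5/50 = 0.6
  region2 <- matrix(FALSE, 20, 20); region2[1:10, 1:5] <- TRUE  # x 0..4, y 0..9
  pts2 <- pts; pts2$points <- cbind(c(0, 1, 2, 3, 4, 0, 1, 2, 3, 4),
                                    c(1, 1, 1, 1, 1, 15, 15, 15, 15, 15))
  cfg <- run_config(theta0 = 0, theta1 = 1, theta2 = 1, theta3 = 0)
  expect_equal(evaluate_region(region2, pts2, f, cfg), 0.5 + 5 / 50)
  # empty region always rejected
  expect_equal(evaluate_region(matrix(FALSE, 20, 20), pts, f, cfg), -Inf)
})

test_that("threshold refinement keeps exactly the in-band pixels at c_min", {
  f <- matrix(0, 5, 5)
  f[1, 1:3] <- c(40, 90, 200)
  region <- matrix(FALSE, 5, 5); region[1, 1:3] <- TRUE
  pts <- structure(list(points = cbind(0, 0), gamma_p = 0.1, g_avg = 60),
                   class = "discrete_points")
  cfg <- run_config(g0 = 30, g1 = 100, c_min = 1)
  kept <- refine_or_threshold(f, region, 1, pts, cfg)
  expect_equal(sum(kept), 2)
  expect_true(kept[1, 1] && kept[1, 2] && !kept[1, 3])
  # all pixels out of band -> empty set
  cfg2 <- run_config(g0 = 300, g1 = 400, c_min = 1)
  expect_equal(sum(refine_or_threshold(f, region, 1, pts, cfg2)), 0)
})

test_that("initialization segments a dark disc to Dice >= 0.8", {
  s <- render_scene(scene_preset("clean_translation", 5))
  truth <- s$truth$bolus$masks[[1]]
  b <- s$truth$bolus$boxes[[1]]
  st <- init_bolus(s$seq$frames[[1]], bbox(b[[1]] - 4, b[[2]] - 4,
                                           b[[3]] + 8, b[[4]] + 8),
                   run_config(), seed = 3)
  dice <- 2 * sum(st$mask & truth) / (sum(st$mask) + sum(truth))
  expect_gte(dice, 0.8)
  expect_equal(st$velocity, c(0, 0))
})

test_that("initialization on uniformly bright content reports no bolus", {
  f <- matrix(210, 60, 60) + matrix(rnorm(3600), 60, 60)
  expect_error(init_bolus(f, bbox(10, 10, 30, 30), run_config(g1 = 100)),
               "no bolus")
})

test_that("point count conservation holds after every step", {
  s <- render_scene(scene_preset("clean_translation", 8))
  cfg <- run_config()
  b <- s$truth$bolus$boxes[[1]]
  st <- init_bolus(s$seq$frames[[1]], bbox(b[[1]] - 4, b[[2]] - 4,
                                           b[[3]] + 8, b[[4]] + 8), cfg, 1)
  for (t in 2:8) {
    st <- step_bolus(st, s$seq$frames[[t]], cfg, seed = t)
    expect_equal(nrow(st$points$points), round(cfg$gamma_p * sum(st$mask)))
  }
})

test_that("a static blob is held within 1 px over 10 frames", {
  frames <- lapply(1:10, function(t) {
    set.seed(100 + t)
    disc_frame(60, 60, 30, 30, 9) + matrix(rnorm(3600, sd = 1.5), 60, 60)
  })
  seq <- video_sequence(frames)
  r <- track_bolus(seq, bbox(18, 18, 24, 24), run_config(), seed = 4)
  expect_false(any(r$lost))
  drift <- sqrt(rowSums((r$trajectory$centroids -
                           matrix(30, 10, 2, byrow = TRUE))^2))
  expect_true(all(drift <= 1.5))
  v <- diff(r$trajectory$centroids[8:10, ])
  expect_true(all(abs(v) <= 1))
})

test_that("constant translation velocity is recovered within 1 px/frame", {
  frames <- lapply(1:8, function(t) {
    set.seed(200 + t)
    disc_frame(60, 90, 18 + 3 * (t - 1), 30, 9) +
      matrix(rnorm(5400, sd = 1.5), 60, 90)
  })
  seq <- video_sequence(frames)
  r <- track_bolus(seq, bbox(6, 18, 24, 24), run_config(), seed = 4)
  for (t in 4:8) {
    v <- r$trajectory$centroids[t, ] - r$trajectory$centroids[t - 1, ]
    expect_lt(abs(v[1] - 3), 1)
    expect_lt(abs(v[2] - 0), 1)
  }
})

test_that("a vanished bolus flags the state lost and coasts the box", {
  frames <- c(lapply(1:3, function(t) disc_frame(50, 50, 25, 25, 8)),
              list(matrix(200, 50, 50), matrix(200, 50, 50)))
  seq <- video_sequence(frames)
  r <- track_bolus(seq, bbox(14, 14, 22, 22), run_config(), seed = 1)
  expect_false(any(r$lost[1:3]))
  expect_true(all(r$lost[4:5]))
  expect_equal(r$trajectory$scores[4], 0)
})

test_that("bolus tracking is deterministic under a fixed seed", {
  s <- render_scene(scene_preset("elevation_view", 9))
  b <- s$truth$bolus$boxes[[1]]
  init <- bbox(b[[1]] - 4, b[[2]] - 4, b[[3]] + 8, b[[4]] + 8)
  r1 <- track_bolus(s$seq, init, run_config(), seed = 12)
  r2 <- track_bolus(s$seq, init, run_config(), seed = 12)
  expect_identical(r1$trajectory$centroids, r2$trajectory$centroids)
  expect_identical(r1$masks, r2$masks)
})
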