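# Discrete-point tracking of the barium bolus. The bolus flows and deforms,
# so no appearance template is stable; instead a set of random points sampled
# inside the current bolus mask votes, frame to frame, on which watershed
# regions of the (velocity-predicted, expanded) search box still belong to
# the bolus. Regions failing the vote are recursively re-segmented at lower
# levels and finally resolved by gray-band thresholding.

#' Sample discrete points from a bolus region
#'
#' Draws `round(gamma_p * |S_p|)` pixels uniformly at random without
#' replacement from the region and records the region's mean gray `g_avg`.
#' Regions too small to support the ratio fall back to a single point at the
#' region centroid.
#'
#' @param mask Logical matrix: the bolus region `S_p`.
#' @param f Frame the region was segmented from (for `g_avg`).
#' @param gamma_p Sampling ratio (default 0.1).
#' @param seed Integer seed for the draw.
#' @return A `discrete_points` list: `points` (n x 2 matrix of 0-based
#'   (x, y)), `gamma_p`, `g_avg`.
#' @export
sample_points <- function(mask, f, gamma_p = 0.1, seed = 1) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("cannot sample points from an empty region")
  n_target <- round(gamma_p * nrow(idx))
  pts <- if (n_target < 1) {
    ctr <- mask_centroid(mask)
    matrix(round(ctr), 1, 2)
  } else {
    sel <- withr::with_seed(seed, sample.int(nrow(idx), n_target))
    cbind(idx[sel, 2] - 1, idx[sel, 1] - 1)   # (x, y)
  }
  structure(list(points = pts, gamma_p = gamma_p, g_avg = mean(f[mask])),
            class = "discrete_points")
}

#' Expand a box about its center
#'
#' @param box [bbox()].
#' @param factor Scale factor >= 1 (the tracker default is 1.2).
#' @param frame_dim `c(height, width)` for clipping.
#' @return Expanded, integer-rounded, clipped [bbox()].
#' @export
expand_box <- function(box, factor = 1.2, frame_dim) {
  if (factor < 1) stop("expansion factor must be >= 1")
  ctr <- bbox_center(box)
  w <- box[[3]] * factor; h <- box[[4]] * factor
  b <- bbox(round(ctr[1] - w / 2), round(ctr[2] - h / 2), round(w), round(h))
  bbox_clip(b, frame_dim)
}

#' Evaluate a candidate watershed region against the discrete points
#'
#' Weighted vote
#' `Eva = theta0 + theta1 * n_in/n_total + theta2 * n_in/area +
#'  theta3 * |mean_gray - g_avg|`,
#' where `n_in` is the number of discrete points falling in the region. The
#' region is accepted when `Eva` lies in the band `[e0, e1]`.
#'
#' @param region_mask Full-frame logical mask of the candidate region.
#' @param points A `discrete_points` set (see [sample_points()]).
#' @param f Frame (for the region's mean gray).
#' @param cfg A [run_config()] supplying `theta0..theta3`.
#' @return The scalar `Eva`; `-Inf` for an empty region (always rejected).
#' @export
evaluate_region <- function(region_mask, points, f, cfg = run_config()) {
  area <- sum(region_mask)
  if (area == 0) return(-Inf)
  pts <- points$points
  n_in <- sum(region_mask[cbind(pts[, 2] + 1, pts[, 1] + 1)])
  cfg$theta0 + cfg$theta1 * n_in / nrow(pts) + cfg$theta2 * n_in / area +
    cfg$theta3 * abs(mean(f[region_mask]) - points$g_avg)
}

g_band <- function(cfg, g_avg) {
  g1 <- if (is.na(cfg$g1)) g_avg + cfg$g1_offset else cfg$g1
  c(cfg$g0, g1)
}

#' Refine a rejected region or resolve it by thresholding
#'
#' A region rejected by [evaluate_region()] is re-segmented at level `c - 1`
#' (restricted to its own pixels) and its sub-regions re-evaluated,
#' recursively. Once the level would drop below `c_min`, gray-band
#' threshold segmentation is applied instead: a pixel is kept iff its gray
#' value lies in `[g0, g1]`.
#'
#' @param f Frame.
#' @param region_mask Full-frame logical mask of the rejected region.
#' @param c Current segmentation level (refinement proceeds at `c - 1`).
#' @param points `discrete_points` driving the evaluation.
#' @param cfg [run_config()].
#' @return Full-frame logical mask of accepted pixels (possibly empty).
#' @export
refine_or_threshold <- function(f, region_mask, c, points, cfg = run_config()) {
  gb <- g_band(cfg, points$g_avg)
  if (c - 1 < cfg$c_min || sum(region_mask) < 9) {
    keep <- region_mask & f >= gb[1] & f <= gb[2]
    return(keep)
  }
  rb <- mask_bbox(region_mask)
  if (is.null(rb) || rb[[3]] < 3 || rb[[4]] < 3) {
    return(region_mask & f >= gb[1] & f <= gb[2])
  }
  seg <- watershed_segment(f, rb, c = c - 1, h_base = cfg$h_base)
  acc <- matrix(FALSE, nrow(f), ncol(f))
  for (l in seg$stats$label) {
    rm <- segmap_region_mask(seg, l, dim(f)) & region_mask
    if (!any(rm)) next
    eva <- evaluate_region(rm, points, f, cfg)
    if (!is.na(eva) && eva >= cfg$e0 && eva <= cfg$e1) {
      acc <- acc | rm
    } else {
      acc <- acc | refine_or_threshold(f, rm, c - 1, points, cfg)
    }
  }
  acc
}

open_close <- function(mask, size = 3) {
  if (!any(mask)) return(mask)
  k <- EBImage::makeBrush(size, shape = "box")
  m <- EBImage::closing(EBImage::opening(mask * 1, k), k)
  m > 0.5
}

#' Initialize the bolus tracker
#'
#' Segments the first-frame box by watershed at level `c_init` and keeps the
#' regions whose mean gray lies in the dark band `[g0, g1]` (by default
#' `g1` is the Otsu threshold of the box, the bolus being darker than the
#' anatomy); samples discrete points from the union.
#'
#' @param f First frame.
#' @param box Initial [bbox()] around the bolus.
#' @param cfg [run_config()].
#' @param seed Integer seed for point sampling.
#' @return A `bolus_state`: `box`, `mask`, `points`, `velocity`, `level`,
#'   `lost`.
#' @export
init_bolus <- function(f, box, cfg = run_config(), seed = 1) {
  d <- dim(f)
  box <- bbox_clip(box, d)
  seg <- watershed_segment(f, box, c = cfg$c_init, h_base = cfg$h_base)
  g1 <- if (is.na(cfg$g1)) {
    crop <- bbox_crop(f, box)
    EBImage::otsu(crop / 255, range = c(0, 1)) * 255
  } else cfg$g1
  keep <- seg$stats$label[seg$stats$mean_gray >= cfg$g0 &
                            seg$stats$mean_gray <= g1]
  if (length(keep) == 0)
    stop("no bolus found: no watershed region in the gray band [",
         cfg$g0, ", ", round(g1, 1), "]")
  mask <- matrix(FALSE, d[1], d[2])
  for (l in keep) mask <- mask | segmap_region_mask(seg, l, d)
  mask <- open_close(mask, cfg$morph_size)
  if (!any(mask)) stop("no bolus found: mask empty after morphology")
  pts <- sample_points(mask, f, cfg$gamma_p, seed)
  structure(list(box = mask_bbox(mask), mask = mask, points = pts,
                 velocity = c(0, 0), level = cfg$c_init, lost = FALSE),
            class = "bolus_state")
}

#' Advance the bolus tracker by one frame
#'
#' Predicts the box by the last velocity, expands it, watershed-segments the
#' expanded box at the current level, accepts/refines regions via the
#' discrete-point vote, applies an open-close, and re-derives centroid,
#' velocity, box and a fresh point sample from the new mask. An oversized
#' rejected region (area ratio above `beta_img`) triggers a global
#' re-segmentation of the box at the next lower level. An empty final mask
#' flags the state `lost`; the box then coasts on the frozen velocity.
#'
#' @param state A `bolus_state`.
#' @param f_next Next frame.
#' @param cfg [run_config()].
#' @param seed Integer seed for point resampling.
#' @return Updated `bolus_state`.
#' @export
step_bolus <- function(state, f_next, cfg = run_config(), seed = 1) {
  d <- dim(f_next)
  pred <- bbox(state$box[[1]] + state$velocity[1],
               state$box[[2]] + state$velocity[2],
               state$box[[3]], state$box[[4]])
  ebox <- expand_box(bbox_clip(pred, d), cfg$expand_factor, d)
  box_area <- ebox[[3]] * ebox[[4]]
  c_cur <- cfg$c_init
  accepted <- NULL
  repeat {
    seg <- watershed_segment(f_next, ebox, c = c_cur, h_base = cfg$h_base)
    acc <- matrix(FALSE, d[1], d[2])
    restart <- FALSE
    for (l in seg$stats$label) {
      rm <- segmap_region_mask(seg, l, d)
      eva <- evaluate_region(rm, state$points, f_next, cfg)
      if (!is.na(eva) && eva >= cfg$e0 && eva <= cfg$e1) {
        acc <- acc | rm
      } else if (sum(rm) / box_area > cfg$beta_img && c_cur > cfg$c_min) {
        c_cur <- c_cur - 1
        restart <- TRUE
        break
      } else {
        acc <- acc | refine_or_threshold(f_next, rm, c_cur, state$points, cfg)
      }
    }
    if (!restart) { accepted <- acc; break }
  }
  mask <- open_close(accepted, cfg$morph_size)
  if (!any(mask)) {
    state$box <- bbox_clip(bbox(pred[[1]], pred[[2]], pred[[3]], pred[[4]]), d)
    state$lost <- TRUE
    return(state)
  }
  old_ctr <- bbox_center(state$box)
  new_ctr <- mask_centroid(mask)
  state$velocity <- if (state$lost) state$velocity else new_ctr - old_ctr
  if (state$lost) state$lost <- FALSE
  state$mask <- mask
  state$box <- mask_bbox(mask)
  state$points <- sample_points(mask, f_next, cfg$gamma_p, seed)
  state
}

#' Track a bolus through a sequence
#'
#' @param seq [video_sequence()].
#' @param box Initial [bbox()] on frame 1.
#' @param cfg [run_config()].
#' @param seed Integer seed (point sampling).
#' @return List with `trajectory` (a [trajectory()]; score 1 on tracked
#'   frames, 0 on lost frames), `masks` (per-frame logical), `lost`
#'   (logical vector).
#' @export
track_bolus <- function(seq, box, cfg = run_config(), seed = 1) {
  n <- length(seq$frames)
  state <- init_bolus(seq$frames[[1]], box, cfg, derive_seed(seed, "bolus-1"))
  masks <- vector("list", n)
  boxes <- vector("list", n)
  cents <- matrix(NA_real_, n, 2)
  lost <- logical(n)
  masks[[1]] <- state$mask
  boxes[[1]] <- state$box
  cents[1, ] <- mask_centroid(state$mask)
  for (t in 2:n) {
    state <- step_bolus(state, seq$frames[[t]], cfg,
                        derive_seed(seed, paste0("bolus-", t)))
    masks[[t]] <- if (state$lost) matrix(FALSE, nrow(seq$frames[[t]]),
                                         ncol(seq$frames[[t]])) else state$mask
    boxes[[t]] <- state$box
    cents[t, ] <- if (state$lost) bbox_center(state$box) else
      mask_centroid(state$mask)
    lost[t] <- state$lost
  }
  list(trajectory = trajectory("bolus", seq_len(n), boxes, cents,
                               as.numeric(!lost)),
       masks = masks, lost = lost)
}
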