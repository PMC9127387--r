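# Classical and improved inter-frame differencing. The improved method keeps
# only {previous ROI mask, previous frame, tracking box} as state and cancels
# the residual image a moving target leaves behind: previous-ROI pixels that
# now look like bright background are subtracted from the union of the
# difference mask and the previous ROI.

#' Classical inter-frame difference
#'
#' A pixel is foreground iff `|f_cur - f_prev| > m` (strict inequality).
#'
#' @param f_prev,f_cur Frames of identical shape.
#' @param m Binarization threshold (intensity levels).
#' @return Logical foreground mask.
#' @export
classical_diff <- function(f_prev, f_cur, m = 15) {
  if (!identical(dim(f_prev), dim(f_cur))) stop("frame shapes differ")
  abs(f_cur - f_prev) > m
}

#' Background-residual mask
#'
#' Marks previous-ROI pixels that the target has vacated: `d_seg = 1` iff
#' the pixel was in `seg_p` and its current gray value exceeds `t_p`
#' (it now looks like bright background).
#'
#' @param seg_p Previous region of interest (logical).
#' @param f_cur Current frame.
#' @param t_p Background-projection threshold (intensity).
#' @return Logical residual mask.
#' @export
residual_mask <- function(seg_p, f_cur, t_p) {
  if (!identical(dim(seg_p), dim(f_cur))) stop("mask/frame shapes differ")
  seg_p & (f_cur > t_p)
}

#' Improved inter-frame difference
#'
#' Within the (expanded) tracking box: bilateral denoising, a shared
#' contrast stretch of both frames, the thresholded difference mask
#' `d_frame` (foreground iff difference >= `t_diff`), the residual mask
#' `d_seg`, and the combination `seg_c = (d_frame | seg_p) \ d_seg`
#' clipped to {0, 1}, followed by a morphological open-close. When discrete
#' points and/or a reference gray are supplied, connected components are
#' kept only if they contain a point or their mean gray is within
#' `fuse_gray_tol` of `g_avg`.
#'
#' @param f_prev,f_cur Frames.
#' @param seg_p Previous ROI mask (logical, full frame).
#' @param box Tracking [bbox()]; differencing is restricted to its
#'   `expand_factor` expansion.
#' @param cfg [run_config()]; `t_p = NA` uses the Otsu threshold of the
#'   current box.
#' @param points Optional `discrete_points` for component fusion.
#' @return List with `seg_c`, `d_frame`, `d_seg` (logical, full frame),
#'   `t_p` used, and `lost` (TRUE when `seg_c` is empty).
#' @export
improved_diff <- function(f_prev, f_cur, seg_p, box, cfg = run_config(),
                          points = NULL) {
  d <- dim(f_cur)
  ebox <- expand_box(bbox_clip(box, d), cfg$expand_factor, d)
  roi <- bbox_mask(ebox, d)
  fp <- bilateral_denoise(f_prev, ebox, cfg$bilateral_sigma_s, cfg$bilateral_sigma_r)
  fc <- bilateral_denoise(f_cur, ebox, cfg$bilateral_sigma_s, cfg$bilateral_sigma_r)
  # shared linear stretch over the box so both frames map identically; the
  # stretched copies drive the difference mask, gray-value tests stay on the
  # original 0-255 scale
  lo <- min(bbox_crop(fp, ebox), bbox_crop(fc, ebox))
  hi <- max(bbox_crop(fp, ebox), bbox_crop(fc, ebox))
  if (hi > lo) {
    sc <- 255 / (hi - lo)
    d_frame <- (abs((fc - lo) - (fp - lo)) * sc >= cfg$t_diff * sc) & roi
  } else {
    d_frame <- (abs(fc - fp) >= cfg$t_diff) & roi
  }
  t_p <- if (is.na(cfg$t_p)) {
    EBImage::otsu(pmin(pmax(bbox_crop(fc, ebox), 0), 255) / 255,
                  range = c(0, 1)) * 255
  } else cfg$t_p
  d_seg <- residual_mask(seg_p, fc, t_p) & roi
  seg_c <- ((d_frame | (seg_p & roi)) & !d_seg)
  seg_c <- open_close(seg_c, cfg$morph_size)
  if (any(seg_c) && !is.null(points)) {
    seg_c <- fuse_components(seg_c, fc, points, cfg)
    # localization by gray information: re-grow the mask to the connected
    # dark-band pixels it touches, so slight per-frame erosion of the set
    # arithmetic does not accumulate along the chain
    if (any(seg_c) && !is.null(points$g_avg)) {
      gb <- g_band(cfg, points$g_avg)
      cand <- roi & fc >= gb[1] & fc <= gb[2]
      if (any(cand)) {
        lab <- EBImage::bwlabel(cand * 1)
        lab <- matrix(as.integer(round(as.vector(lab))), d[1], d[2])
        touched <- setdiff(unique(lab[seg_c]), 0L)
        if (length(touched))
          seg_c <- seg_c | matrix(lab %in% touched, d[1], d[2])
      }
    }
  }
  list(seg_c = seg_c, d_frame = d_frame, d_seg = d_seg, t_p = t_p,
       lost = !any(seg_c))
}

# keep components holding >= 1 discrete point OR with mean gray near g_avg
fuse_components <- function(mask, f, points, cfg) {
  if (is.null(points)) return(mask)
  lab <- EBImage::bwlabel(mask * 1)
  lab <- matrix(as.integer(round(as.vector(lab))), nrow(mask), ncol(mask))
  keep <- matrix(FALSE, nrow(mask), ncol(mask))
  pts <- points$points
  for (l in seq_len(max(lab))) {
    cm <- lab == l
    has_pt <- !is.null(pts) &&
      any(cm[cbind(pmin(pmax(pts[, 2] + 1, 1), nrow(cm)),
                   pmin(pmax(pts[, 1] + 1, 1), ncol(cm)))])
    gray_ok <- !is.null(points$g_avg) &&
      abs(mean(f[cm]) - points$g_avg) <= cfg$fuse_gray_tol
    if (has_pt || gray_ok) keep <- keep | cm
  }
  keep
}

#' Run the improved inter-frame difference detector over a sequence
#'
#' Bootstraps the ROI and discrete points from [init_bolus()] on frame 1,
#' then chains [improved_diff()] frame to frame, advancing the tracking box
#' by the ROI centroid velocity. The detector's persistent state is exactly
#' {previous ROI, previous frame, box} — no background model is stored.
#'
#' @param seq [video_sequence()].
#' @param box Initial [bbox()] on frame 1.
#' @param cfg [run_config()].
#' @param seed Integer seed (initial point sampling).
#' @return List with per-frame `masks`, `trajectory`, `lost`.
#' @export
track_improved_diff <- function(seq, box, cfg = run_config(), seed = 1) {
  n <- length(seq$frames)
  d <- seq_dim(seq)
  st <- init_bolus(seq$frames[[1]], box, cfg, derive_seed(seed, "idiff-1"))
  masks <- vector("list", n)
  boxes <- vector("list", n)
  cents <- matrix(NA_real_, n, 2)
  lost <- logical(n)
  masks[[1]] <- st$mask
  boxes[[1]] <- st$box
  cents[1, ] <- mask_centroid(st$mask)
  seg_p <- st$mask
  cur_box <- st$box
  vel <- c(0, 0)
  pts <- st$points
  prev_area <- sum(seg_p)
  for (t in 2:n) {
    pred <- bbox_clip(bbox(cur_box[[1]] + vel[1], cur_box[[2]] + vel[2],
                           cur_box[[3]], cur_box[[4]]), d)
    # dynamic tracking frame: if the mask collapses (violent motion carried
    # the target outside the search box) retry with a wider expansion
    fac <- cfg$expand_factor
    repeat {
      cfg_try <- cfg; cfg_try$expand_factor <- fac
      r <- improved_diff(seq$frames[[t - 1]], seq$frames[[t]], seg_p, pred,
                         cfg_try, points = pts)
      if (!r$lost && sum(r$seg_c) >= 0.4 * prev_area) break
      if (fac >= 4 * cfg$expand_factor) break
      fac <- fac * 2
    }
    if (r$lost) {
      lost[t] <- TRUE
      masks[[t]] <- matrix(FALSE, d[1], d[2])
      cur_box <- pred
      boxes[[t]] <- pred
      cents[t, ] <- bbox_center(pred)
      next
    }
    masks[[t]] <- r$seg_c
    new_ctr <- mask_centroid(r$seg_c)
    vel <- new_ctr - cents[t - 1, ]
    cents[t, ] <- new_ctr
    cur_box <- mask_bbox(r$seg_c)
    boxes[[t]] <- cur_box
    seg_p <- r$seg_c
    prev_area <- sum(seg_p)
    pts <- sample_points(r$seg_c, seq$frames[[t]], cfg$gamma_p,
                         derive_seed(seed, paste0("idiff-", t)))
  }
  list(masks = masks,
       trajectory = trajectory("improved_diff", seq_len(n), boxes, cents,
                               as.numeric(!lost)),
       lost = lost)
}
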