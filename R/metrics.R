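# Evaluation metrics: average pixel error (mean center distance), average
# overlap ratio (mean IoU), success rate at an IoU threshold, and the
# comparison harnesses for detectors and trackers.

match_frames <- function(pred, truth) {
  common <- intersect(pred$frames, truth$frames)
  if (length(common) == 0) stop("trajectories share no frames")
  list(p = match(common, pred$frames), t = match(common, truth$frames),
       frames = common)
}

#' Average pixel error between two trajectories
#'
#' Mean Euclidean distance between predicted and true centers over the
#' common frames; lower is better.
#'
#' @param pred,truth [trajectory()] objects.
#' @return APE in pixels.
#' @export
ape <- function(pred, truth) {
  m <- match_frames(pred, truth)
  d <- pred$centroids[m$p, , drop = FALSE] - truth$centroids[m$t, , drop = FALSE]
  mean(sqrt(rowSums(d^2)))
}

#' Average overlap ratio between two trajectories
#'
#' Mean intersection-over-union of predicted vs true boxes over common
#' frames. Frames with a degenerate truth box are skipped with a warning.
#'
#' @param pred,truth [trajectory()] objects.
#' @return AOR in `[0, 1]`.
#' @export
aor <- function(pred, truth) {
  m <- match_frames(pred, truth)
  vals <- vapply(seq_along(m$frames), function(i) {
    tb <- truth$boxes[[m$t[i]]]
    if (tb[[3]] <= 0 || tb[[4]] <= 0) return(NA_real_)
    bbox_iou(pred$boxes[[m$p[i]]], tb)
  }, numeric(1))
  if (anyNA(vals)) warning("skipped ", sum(is.na(vals)), " degenerate truth boxes")
  mean(vals, na.rm = TRUE)
}

#' Success rate (tracking accuracy) at an IoU threshold
#'
#' Fraction of common frames whose predicted/truth box overlap is at least
#' `threshold` (default 0.5, the standard benchmark operating point).
#'
#' @param pred,truth [trajectory()] objects.
#' @param threshold IoU success threshold.
#' @return Fraction in `[0, 1]`.
#' @export
success_rate <- function(pred, truth, threshold = 0.5) {
  m <- match_frames(pred, truth)
  vals <- vapply(seq_along(m$frames), function(i)
    bbox_iou(pred$boxes[[m$p[i]]], truth$boxes[[m$t[i]]]), numeric(1))
  mean(vals >= threshold)
}

truth_trajectory <- function(truth_target, id = "truth") {
  keep <- which(!vapply(truth_target$boxes, is.null, logical(1)))
  trajectory(id, keep, truth_target$boxes[keep],
             truth_target$centroids[keep, , drop = FALSE])
}

# mask-based APE/AOR used for the detector comparison; empty predictions
# carry the previous centroid and score 0 overlap
mask_metrics <- function(pred_masks, truth_masks, init_center) {
  n <- length(truth_masks)
  errs <- numeric(n); ious <- numeric(n)
  last <- init_center
  for (t in seq_len(n)) {
    tm <- truth_masks[[t]]
    pm <- pred_masks[[t]]
    ctr <- mask_centroid(pm)
    if (is.null(ctr)) ctr <- last
    last <- ctr
    tctr <- mask_centroid(tm)
    errs[t] <- sqrt(sum((ctr - tctr)^2))
    ious[t] <- mask_iou(pm, tm)
  }
  c(APE = mean(errs), AOR = mean(ious))
}

#' Compare moving-target detectors on a sequence with truth masks
#'
#' Runs the improved inter-frame difference detector, ViBe and EGMM on
#' identical input and scores each with mask-centroid APE and mask-IoU AOR
#' against the ground-truth masks.
#'
#' @param seq [video_sequence()].
#' @param truth_masks Per-frame logical truth masks of the moving target.
#' @param init_box First-frame [bbox()] handed to the improved detector.
#' @param methods Subset of `c("improved", "vibe", "egmm")`.
#' @param cfg [run_config()].
#' @param seed Integer seed.
#' @return data.frame with one row per method: `method`, `APE`, `AOR`.
#' @export
compare_detectors <- function(seq, truth_masks, init_box,
                              methods = c("improved", "vibe", "egmm"),
                              cfg = run_config(), seed = 1) {
  known <- c("improved", "vibe", "egmm")
  bad <- setdiff(methods, known)
  if (length(bad)) stop("unknown detector method(s): ", paste(bad, collapse = ", "))
  ctr0 <- bbox_center(init_box)
  rows <- lapply(methods, function(m) {
    masks <- switch(m,
      improved = track_improved_diff(seq, init_box, cfg, seed)$masks,
      vibe = track_vibe(seq, cfg, seed),
      egmm = track_egmm(seq, cfg))
    mm <- mask_metrics(masks, truth_masks, ctr0)
    data.frame(method = m, APE = mm[["APE"]], AOR = mm[["AOR"]])
  })
  do.call(rbind, rows)
}

#' Compare trackers on a sequence with a truth trajectory
#'
#' All methods start from the same initial box. `combined` is the
#' position+scale tracker with watershed correction; `kcf` disables the
#' scale filter and correction; `csk_like` additionally restricts features
#' to raw gray; `dsst_like` keeps the scale filter but gray-only features;
#' `mosse` is the single-channel baseline. Reported speed (frames/second)
#' is hardware-dependent and informational only.
#'
#' @param seq [video_sequence()].
#' @param truth A truth [trajectory()] (or truth target list from
#'   [render_scene()]).
#' @param init_box Shared initial [bbox()].
#' @param methods Subset of `c("mosse", "csk_like", "kcf", "dsst_like",
#'   "combined")`.
#' @param cfg Base [run_config()].
#' @param threshold IoU success threshold.
#' @return data.frame: `method`, `accuracy` (success rate), `APE`, `fps`.
#' @export
compare_trackers <- function(seq, truth, init_box,
                             methods = c("mosse", "csk_like", "kcf",
                                         "dsst_like", "combined"),
                             cfg = run_config(), threshold = 0.5) {
  if (!inherits(truth, "trajectory")) truth <- truth_trajectory(truth)
  # baselines are the plain published trackers: no watershed correction and
  # no occlusion handling, those belong to the combined method only
  variants <- list(
    mosse = cfg,
    csk_like = run_config(utils::modifyList(unclass(cfg),
      list(features = "gray", use_scale = FALSE, correction = FALSE,
           occl_handling = FALSE))),
    kcf = run_config(utils::modifyList(unclass(cfg),
      list(use_scale = FALSE, correction = FALSE, occl_handling = FALSE))),
    dsst_like = run_config(utils::modifyList(unclass(cfg),
      list(features = "gray", use_scale = TRUE, correction = FALSE,
           occl_handling = FALSE))),
    combined = cfg)
  bad <- setdiff(methods, names(variants))
  if (length(bad)) stop("unknown tracker method(s): ", paste(bad, collapse = ", "))
  rows <- lapply(methods, function(m) {
    t0 <- Sys.time()
    r <- if (m == "mosse") mosse_track(seq, init_box, variants[[m]])
         else track_organ(seq, init_box, variants[[m]])
    dt <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    data.frame(method = m,
               accuracy = success_rate(r$trajectory, truth, threshold),
               APE = ape(r$trajectory, truth),
               fps = length(seq$frames) / max(dt, 1e-9))
  })
  do.call(rbind, rows)
}
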