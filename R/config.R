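# All free parameters of the toolkit live in one flat list so that every
# pipeline can be driven from a key=value config file and the CLI.

#' Default run configuration
#'
#' Collects every tunable of the trackers, detectors and baselines with its
#' default. Values are documented where they are used; the important ones:
#'
#' * `gamma_p` (0.1): ratio of discrete points to bolus-area pixels.
#' * `c_init` (4), `c_min` (1): initial / minimum watershed segmentation
#'   level; the marker-suppression depth is `h_base * 2^(c-1)` intensity
#'   levels.
#' * `expand_factor` (1.2): search-box expansion between frames.
#' * `theta0..theta3`, `e0`, `e1`: region-evaluation weights and acceptance
#'   band for the discrete-point tracker.
#' * `t_diff` (15): inter-frame difference threshold; `t_p` (NA = Otsu of
#'   the box): background-projection threshold.
#' * ViBe: `vibe_n` (20), `vibe_r` (20), `vibe_nmin` (2), `vibe_phi` (16).
#' * EGMM: `egmm_buffer` (50), `egmm_k` (5), `egmm_density` (0.005).
#' * Correlation filters: `lambda` (1e-4), `sigma_k` (0.5), learning rate
#'   `theta` (0.02), `n_scales` (33), `scale_step` (1.02), `pca_dims` (32);
#'   occlusion gating on the normalized cross-correlation of the
#'   target-sized crop with the stored target appearance: below
#'   `occl_enter` (0.45) the frame is occluded, and a reappearance probe
#'   must reach `occl_exit` (0.55) to resume, with coasting damped by
#'   `coast_damp` (0.85) per occluded frame.
#'
#' @param ... Named overrides of any default.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    # discrete-point bolus tracker
    gamma_p      = 0.1,
    c_init       = 4,
    c_min        = 1,
    h_base       = 4,
    expand_factor = 1.2,
    theta0       = 0,
    theta1       = 0.5,
    theta2       = 0.3,
    theta3       = -0.01,
    e0           = 0.25,
    e1           = Inf,
    beta_img     = 0.5,
    g0           = 0,
    g1           = NA,       # NA: derived from g_avg + g1_offset (or Otsu at init)
    g1_offset    = 25,
    morph_size   = 3,
    # inter-frame difference
    t_diff       = 15,
    t_p          = NA,       # NA: Otsu threshold of the box region
    frame_gap    = 1,
    fuse_gray_tol = 20,
    bilateral_sigma_s = 2,
    bilateral_sigma_r = 25,
    # ViBe
    vibe_n       = 20,
    vibe_r       = 20,
    vibe_nmin    = 2,
    vibe_phi     = 16,
    # EGMM balloon estimator
    egmm_buffer  = 50,
    egmm_k       = 5,
    egmm_density = 0.005,
    # correlation filters
    lambda       = 1e-4,
    sigma_k      = 0.5,
    theta        = 0.02,
    target_sigma_div = 16,   # Gaussian regression target bandwidth = sqrt(wh)/this
    hog_cell     = 4,
    hog_bins     = 9,
    features     = "gray+hog",
    search_factor = 2.5,
    n_scales     = 33,
    scale_step   = 1.02,
    scale_sigma_div = 16,
    pca_dims     = 32,
    scale_model_max = 32,
    scale_lr     = 0.025,
    occl_enter   = 0.45,
    occl_exit    = 0.55,
    coast_damp   = 0.85,
    occl_handling = TRUE,
    window_type  = "hanning",
    use_scale    = TRUE,
    correction   = TRUE,
    correction_iou = 0.5,
    # multi-target
    lost_patience = 10,
    # local contrast stretch
    stretch_window = 31,
    # misc
    seed         = 1
  )
  over <- list(...)
  if (length(over) == 1 && is.list(over[[1]]) && is.null(names(over)))
    over <- over[[1]]
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  class(cfg) <- "run_config"
  cfg
}

#' Write a configuration as a flat key=value file
#'
#' @param cfg A [run_config()].
#' @param path Output file path.
#' @export
write_config <- function(cfg, path) {
  keys <- names(cfg)
  vals <- vapply(keys, function(k) {
    v <- cfg[[k]]
    if (is.character(v)) v else format(v, digits = 17)
  }, character(1))
  writeLines(paste0(keys, "=", vals), path)
  invisible(path)
}

#' Read a key=value configuration file
#'
#' Unknown keys are rejected; values are coerced back to the type of the
#' corresponding default.
#'
#' @param path File written by [write_config()] (or by hand).
#' @return A [run_config()].
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, function(p) paste(p[-1], collapse = "="), character(1))
  defaults <- run_config()
  over <- list()
  for (i in seq_along(keys)) {
    k <- trimws(keys[i]); v <- trimws(vals[i])
    if (!k %in% names(defaults)) stop("unknown config key: ", k)
    over[[k]] <- if (is.character(defaults[[k]])) v
      else if (v == "NA") NA
      else if (is.logical(defaults[[k]]) && !is.na(defaults[[k]])) as.logical(v)
      else as.numeric(v)
  }
  do.call(run_config, over)
}
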