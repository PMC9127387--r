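# Correlation-filter tracking for rigid tissue/organ targets: a kernelized
# position filter (ridge regression over all cyclic shifts with a Gaussian
# kernel, gray and/or HOG features), a discriminative scale-space filter
# (1-D correlation filter over a pyramid of scaled patches), an exponential
# template update, optional watershed edge correction, and a MOSSE baseline.
# All correlations are computed in the frequency domain.

fft2 <- function(m) stats::fft(m)
ifft2 <- function(m) stats::fft(m, inverse = TRUE) / length(m)

as_channels <- function(x) if (is.list(x)) x else list(x)

#' Circular cross-correlation via the frequency domain
#'
#' Computes `real(ifft(sum_c fft(x_c) * conj(fft(m_c))))`: the circular
#' cross-correlation of input and filter summed over channels. Entry
#' `[1, 1]` corresponds to zero shift.
#'
#' @param x Input: a matrix or list of same-shape matrices (channels).
#' @param m Filter of matching shape.
#' @return Real response matrix of the common spatial shape.
#' @export
correlate <- function(x, m) {
  xc <- as_channels(x); mc <- as_channels(m)
  if (length(xc) != length(mc)) stop("channel counts differ")
  acc <- NULL
  for (i in seq_along(xc)) {
    if (!identical(dim(xc[[i]]), dim(mc[[i]]))) stop("channel shapes differ")
    p <- fft2(xc[[i]]) * Conj(fft2(mc[[i]]))
    acc <- if (is.null(acc)) p else acc + p
  }
  Re(ifft2(acc))
}

#' Gaussian kernel correlation over all cyclic shifts
#'
#' `k(tau) = exp(-max(0, ||x||^2 + ||z||^2 - 2 * circcorr(x, z)(tau)) /
#' (sigma^2 * N))` with `N` the total number of feature values, evaluated
#' for every cyclic shift via the FFT.
#'
#' @param x,z Feature maps (matrix or channel list) of identical shape.
#' @param sigma Kernel bandwidth (> 0), on the normalized feature scale.
#' @return Real kernel response matrix.
#' @export
gaussian_kernel_correlation <- function(x, z, sigma = 0.5) {
  if (sigma <= 0) stop("sigma must be positive")
  xc <- as_channels(x); zc <- as_channels(z)
  cross <- correlate(xc, zc)
  xx <- sum(vapply(xc, function(c) sum(c^2), numeric(1)))
  zz <- sum(vapply(zc, function(c) sum(c^2), numeric(1)))
  n <- sum(vapply(xc, length, numeric(1)))
  dist2 <- xx + zz - 2 * cross      # keeps matrix shape (cross is a matrix)
  dist2[dist2 < 0] <- 0
  exp(-dist2 / (sigma^2 * n))
}

cosine_window <- function(n, type = "hanning") {
  if (n == 1) return(1)
  i <- seq_len(n) - 1
  switch(type,
         hanning = 0.5 - 0.5 * cos(2 * pi * i / (n - 1)),
         hamming = 0.54 - 0.46 * cos(2 * pi * i / (n - 1)),
         stop("unknown window type: ", type))
}

# replicate-padded subwindow of `size = c(h, w)` px sampled around float
# center (x, y) at scale `scale` (patch of size*scale px resized to size)
get_subwindow <- function(f, center, size, scale = 1) {
  d <- dim(f)
  sh <- max(4L, round(size[1] * scale))
  sw <- max(4L, round(size[2] * scale))
  ys <- round(center[2]) - floor(sh / 2) + seq_len(sh) - 1
  xs <- round(center[1]) - floor(sw / 2) + seq_len(sw) - 1
  ys <- pmin(pmax(ys, 0), d[1] - 1)
  xs <- pmin(pmax(xs, 0), d[2] - 1)
  patch <- f[ys + 1, xs + 1, drop = FALSE]
  if (sh != size[1] || sw != size[2]) {
    patch <- matrix(as.vector(EBImage::resize(patch, w = size[1], h = size[2])),
                    size[1], size[2])
  }
  patch
}

#' Histogram-of-oriented-gradients features
#'
#' Cell-based HOG: central-difference gradients, unsigned orientations
#' binned into `nbins` channels, magnitudes accumulated per `cell x cell`
#' block, each cell's bin vector L2-normalized. No block structure is used;
#' illumination robustness comes from the per-cell normalization.
#'
#' @param patch Grayscale matrix (any intensity scale).
#' @param cell Cell side in pixels.
#' @param nbins Number of orientation bins.
#' @return List of `nbins` matrices of cell-grid shape.
#' @export
hog_features <- function(patch, cell = 4, nbins = 9) {
  h <- nrow(patch); w <- ncol(patch)
  ny <- h %/% cell; nx <- w %/% cell
  if (ny < 1 || nx < 1) stop("patch smaller than one HOG cell")
  gx <- patch[, c(2:w, w)] - patch[, c(1, 1:(w - 1))]
  gy <- patch[c(2:h, h), ] - patch[c(1, 1:(h - 1)), ]
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx) %% pi
  bin <- pmin(floor(ang / pi * nbins), nbins - 1)
  mm <- mag[seq_len(ny * cell), seq_len(nx * cell), drop = FALSE]
  bb <- bin[seq_len(ny * cell), seq_len(nx * cell), drop = FALSE]
  rg <- rep(seq_len(ny), each = cell)
  cg <- rep(seq_len(nx), each = cell)
  ch <- vector("list", nbins)
  for (b in seq_len(nbins)) {
    mb <- mm * (bb == b - 1)
    r1 <- rowsum(mb, rg)
    ch[[b]] <- t(rowsum(t(r1), cg))
  }
  norm <- sqrt(Reduce(`+`, lapply(ch, function(c) c^2))) + 1e-6
  lapply(ch, function(c) c / norm)
}

# feature stack for the position filter: gray and/or HOG at cell resolution,
# cosine-windowed
extract_features <- function(patch, cfg) {
  use_hog <- grepl("hog", cfg$features)
  use_gray <- grepl("gray", cfg$features)
  cell <- if (use_hog) cfg$hog_cell else 1L
  ny <- nrow(patch) %/% cell; nx <- ncol(patch) %/% cell
  chans <- list()
  if (use_hog) chans <- hog_features(patch, cell, cfg$hog_bins)
  if (use_gray) {
    g <- if (cell == 1) patch else
      matrix(as.vector(EBImage::resize(patch, w = ny * 1, h = nx * 1)), ny, nx)
    g <- g / 255 - 0.5
    chans <- c(list(g), chans)
  }
  win <- outer(cosine_window(ny, cfg$window_type),
               cosine_window(nx, cfg$window_type))
  feats <- lapply(chans, function(c) c[seq_len(ny), seq_len(nx), drop = FALSE] * win)
  attr(feats, "cell") <- cell
  feats
}

gaussian_label <- function(ny, nx, sigma) {
  dy <- (seq_len(ny) - 1); dy <- pmin(dy, ny - dy)
  dx <- (seq_len(nx) - 1); dx <- pmin(dx, nx - dx)
  exp(-0.5 * outer(dy^2, dx^2, `+`) / sigma^2)
}

# peak location of a circular response -> signed shift in grid units, with
# one-cell parabolic interpolation around the peak for sub-grid accuracy
response_shift <- function(res) {
  idx <- which(res == max(res), arr.ind = TRUE)[1, ]
  ny <- nrow(res); nx <- ncol(res)
  para <- function(l, c, r) {
    den <- l - 2 * c + r
    if (den >= 0) 0 else max(-0.5, min(0.5, 0.5 * (l - r) / den))
  }
  sy <- if (ny >= 3) para(res[(idx[1] - 2) %% ny + 1, idx[2]],
                          res[idx[1], idx[2]],
                          res[idx[1] %% ny + 1, idx[2]]) else 0
  sx <- if (nx >= 3) para(res[idx[1], (idx[2] - 2) %% nx + 1],
                          res[idx[1], idx[2]],
                          res[idx[1], idx[2] %% nx + 1]) else 0
  dy <- idx[1] - 1 + sy; dx <- idx[2] - 1 + sx
  if (dy > ny / 2) dy <- dy - ny
  if (dx > nx / 2) dx <- dx - nx
  c(dx, dy)
}

#' Initialize the kernelized position filter
#'
#' Trains ridge-regression dual coefficients against a Gaussian regression
#' target over all cyclic shifts of the first-frame search window
#' (`search_factor` times the target box), using the Gaussian kernel.
#'
#' @param f First frame.
#' @param box Target [bbox()] (w, h >= 8 px).
#' @param cfg [run_config()].
#' @return A `position_filter` with `alphaf` (complex), template `z`,
#'   window/target geometry and parameters.
#' @export
pf_init <- function(f, box, cfg = run_config()) {
  d <- dim(f)
  if (!bbox_inside(box, d)) stop("box must lie inside the frame")
  if (box[[3]] < 8 || box[[4]] < 8) stop("target box must be at least 8x8 px")
  center <- bbox_center(box)
  win <- c(round(box[[4]] * cfg$search_factor),
           round(box[[3]] * cfg$search_factor))    # (h, w)
  patch <- get_subwindow(f, center, win)
  x <- extract_features(patch, cfg)
  cell <- attr(x, "cell")
  ny <- nrow(x[[1]]); nx <- ncol(x[[1]])
  sigma_y <- max(sqrt(box[[3]] * box[[4]]) / cfg$target_sigma_div / cell, 0.5)
  y <- gaussian_label(ny, nx, sigma_y)
  yf <- fft2(y)
  k <- gaussian_kernel_correlation(x, x, cfg$sigma_k)
  alphaf <- yf / (fft2(k) + cfg$lambda)
  structure(list(alphaf = alphaf, z = x, yf = yf, window = win, cell = cell,
                 sigma_k = cfg$sigma_k, lambda = cfg$lambda, cfg = cfg),
            class = "position_filter")
}

#' Detect the target with the position filter
#'
#' Samples the search window at `center` (and `scale` relative to the
#' initial window), correlates against the learned template through the
#' Gaussian kernel, and returns the sub-window displacement of the response
#' peak together with the peak value.
#'
#' @param pf A `position_filter`.
#' @param f Frame.
#' @param center Current target center `c(x, y)`.
#' @param scale Current scale relative to initialization.
#' @return List with `disp` (c(dx, dy) px) and `peak`.
#' @export
pf_detect <- function(pf, f, center, scale = 1) {
  patch <- get_subwindow(f, center, pf$window, scale)
  x <- extract_features(patch, pf$cfg)
  k <- gaussian_kernel_correlation(x, pf$z, pf$sigma_k)
  res <- Re(ifft2(pf$alphaf * fft2(k)))
  shift <- response_shift(res)
  # max(k) is the appearance similarity to the template at the best cyclic
  # shift; it is the occlusion signal (far steadier than the regression peak)
  list(disp = shift * pf$cell * scale, peak = max(res), sim = max(k))
}

#' Update the position filter template
#'
#' Retrains dual coefficients on the current window and blends them (and
#' the feature template) into the stored model:
#' `alpha_hat <- (1 - theta) * alpha_hat + theta * alpha`. `theta = 0`
#' leaves the filter untouched; `theta = 1` replaces it.
#'
#' @param pf A `position_filter`.
#' @param f Frame.
#' @param center Target center after detection.
#' @param scale Current scale.
#' @param theta Learning rate in `[0, 1]` (default from the stored config).
#' @return Updated `position_filter`.
#' @export
pf_update <- function(pf, f, center, scale = 1, theta = NULL) {
  if (is.null(theta)) theta <- pf$cfg$theta
  if (theta < 0 || theta > 1) stop("theta must lie in [0, 1]")
  if (theta == 0) return(pf)
  patch <- get_subwindow(f, center, pf$window, scale)
  x <- extract_features(patch, pf$cfg)
  k <- gaussian_kernel_correlation(x, x, pf$sigma_k)
  alphaf_new <- pf$yf / (fft2(k) + pf$lambda)
  pf$alphaf <- (1 - theta) * pf$alphaf + theta * alphaf_new
  pf$z <- mapply(function(old, new) (1 - theta) * old + theta * new,
                 pf$z, x, SIMPLIFY = FALSE)
  pf
}

# --- scale filter (discriminative scale space) ------------------------------

scale_factors <- function(n, step) step^(ceiling(n / 2) - seq_len(n))

scale_sample <- function(f, center, base_sz, current_scale, factors, model_sz,
                         cfg) {
  cols <- lapply(factors, function(a) {
    patch <- get_subwindow(f, center, model_sz, current_scale * a *
                             base_sz[1] / model_sz[1])
    feats <- hog_features(patch, cfg$hog_cell, cfg$hog_bins)
    v <- unlist(feats)
    v / max(sqrt(sum(v^2)), 1e-9)
  })
  do.call(cbind, cols)
}

#' Initialize the scale filter
#'
#' Builds a 1-D correlation filter over `n_scales` patches of sizes
#' `a^s * (M, N)` around the target center. Each patch is resized to a
#' fixed scale-model size, HOG-featurized, unit-normalized, projected onto
#' a PCA basis learned from the first frame, and Hanning-weighted across
#' scales.
#'
#' @param f Frame.
#' @param center Target center.
#' @param target_sz Target size `c(h, w)` px.
#' @param cfg [run_config()].
#' @return A `scale_filter`.
#' @export
sf_init <- function(f, center, target_sz, cfg = run_config()) {
  n <- cfg$n_scales
  factors <- scale_factors(n, cfg$scale_step)
  sc <- cfg$scale_model_max / max(target_sz)
  model_sz <- pmax(round(target_sz * min(sc, 1)), cfg$hog_cell * 2)
  S <- scale_sample(f, center, target_sz, 1, factors, model_sz, cfg)
  p <- min(cfg$pca_dims, nrow(S), ncol(S))
  basis <- svd(S, nu = p, nv = 0)$u                   # d x p, fixed
  hann_s <- cosine_window(n, "hanning")
  proj <- t(basis) %*% S
  Xs <- proj * rep(hann_s, each = nrow(proj))
  ss <- seq_len(n) - ceiling(n / 2)
  sigma_s <- max(n / cfg$scale_sigma_div, 0.6)
  ys <- exp(-0.5 * ss^2 / sigma_s^2)
  ysf <- stats::fft(ys)
  Xsf <- t(apply(Xs, 1, stats::fft))
  num <- Conj(Xsf) * rep(ysf, each = nrow(Xsf))
  den <- Re(colSums(Xsf * Conj(Xsf)))
  structure(list(num = num, den = den, basis = basis, model_sz = model_sz,
                 base_sz = target_sz, factors = factors, hann = hann_s,
                 ysf = ysf, lambda = cfg$lambda, lr = cfg$scale_lr, cfg = cfg),
            class = "scale_filter")
}

#' Estimate the target scale and update the scale filter
#'
#' Samples the scale pyramid at the (already position-updated) center,
#' correlates against the 1-D scale filter and returns the argmax scale
#' factor; the filter numerator/denominator are then blended with the new
#' sample at the scale learning rate (unless `update = FALSE`).
#'
#' @param sf A `scale_filter`.
#' @param f Frame.
#' @param center Target center.
#' @param current_scale Current scale multiplier.
#' @param update Whether to update the filter.
#' @return List with `factor` (best relative scale step), `sf` (updated
#'   filter).
#' @export
sf_estimate <- function(sf, f, center, current_scale = 1, update = TRUE) {
  n <- length(sf$factors)
  if (n == 1) return(list(factor = 1, sf = sf))
  S <- scale_sample(f, center, sf$base_sz, current_scale, sf$factors,
                    sf$model_sz, sf$cfg)
  Xs <- (t(sf$basis) %*% S) * rep(sf$hann, each = ncol(sf$basis))
  Xsf <- t(apply(Xs, 1, stats::fft))
  resp <- Re(stats::fft(colSums(sf$num * Xsf) / (sf$den + sf$lambda),
                        inverse = TRUE)) / n
  best <- which.max(resp)
  if (update) {
    num_new <- Conj(Xsf) * rep(sf$ysf, each = nrow(Xsf))
    den_new <- Re(colSums(Xsf * Conj(Xsf)))
    sf$num <- (1 - sf$lr) * sf$num + sf$lr * num_new
    sf$den <- (1 - sf$lr) * sf$den + sf$lr * den_new
  }
  list(factor = sf$factors[best], sf = sf)
}

# --- combined tracker -------------------------------------------------------

#' Initialize the combined position + scale tracker
#'
#' @param f First frame.
#' @param box Initial target [bbox()].
#' @param cfg [run_config()]; `use_scale` and `correction` toggle the scale
#'   filter and the watershed edge correction.
#' @return A `combined_tracker`.
#' @export
ct_init <- function(f, box, cfg = run_config()) {
  pf <- pf_init(f, box, cfg)
  center <- bbox_center(box)
  target_sz <- c(box[[4]], box[[3]])
  sf <- if (cfg$use_scale) sf_init(f, center, target_sz, cfg) else NULL
  ct <- structure(list(pf = pf, sf = sf, center = center,
                       target_sz = target_sz, init_sz = target_sz, scale = 1,
                       tpl = NULL, vel = c(0, 0), occluded = FALSE,
                       occl_run = 0L, anchor = center, entry_pos = center,
                       entry_vel = c(0, 0), cfg = cfg),
                  class = "combined_tracker")
  ct$tpl <- target_crop(ct, f, center)
  ct
}

# normalized target-sized gray crop: the appearance evidence that the target
# itself (not the search window, which is background-dominated) is at a
# given position; lightly smoothed so sub-pixel misregistration and scale
# resampling do not crater the correlation, then compared with the stored
# template by plain inner product (= normalized cross-correlation)
target_crop <- function(ct, f, center) {
  sz <- pmax(round(ct$init_sz), 4)
  patch <- get_subwindow(f, center, sz, ct$scale)
  patch <- EBImage::gblur(patch, sigma = 1)
  v <- as.vector(patch)
  v <- v - mean(v)
  v / max(sqrt(sum(v^2)), 1e-9)
}

# best match over a +/-4 px neighborhood ("is the target within a few px of
# here"): tolerant of the localization error left after an occlusion coast
target_ncc <- function(ct, f, center) {
  best <- -1
  for (dy in seq(-4, 4, by = 2)) {
    for (dx in seq(-4, 4, by = 2)) {
      v <- sum(target_crop(ct, f, center + c(dx, dy)) * ct$tpl)
      if (v > best) best <- v
    }
  }
  best
}

# coarse template-matching sweep over the search area, used to reacquire the
# target after an occlusion when the coasted position has fallen behind;
# returns the best-matching position and its (refined) correlation
target_search <- function(ct, f, center, radius, step = 3) {
  d <- dim(f)
  best <- -1; best_p <- center
  for (dy in seq(-radius, radius, by = step)) {
    for (dx in seq(-radius, radius, by = step)) {
      p <- pmin(pmax(center + c(dx, dy), c(0, 0)), c(d[2] - 1, d[1] - 1))
      v <- sum(target_crop(ct, f, p) * ct$tpl)
      if (v > best) { best <- v; best_p <- p }
    }
  }
  list(pos = best_p, ncc = target_ncc(ct, f, best_p))
}

# Edge correction: snap the tracked box to the bounding box of the dominant
# watershed region inside it, but only when that region plausibly IS the
# target: bbox IoU with the current box above the gate and comparable area.
watershed_correct <- function(f, box, cfg) {
  d <- dim(f)
  ebox <- expand_box(box, 1.4, d)
  if (ebox[[3]] < 8 || ebox[[4]] < 8) return(NULL)
  seg <- tryCatch(watershed_segment(f, ebox, c = 4, h_base = cfg$h_base),
                  error = function(e) NULL)
  if (is.null(seg) || nrow(seg$stats) == 0) return(NULL)
  best <- NULL; best_iou <- 0
  for (i in seq_len(nrow(seg$stats))) {
    rb <- bbox(seg$stats$x[i], seg$stats$y[i], seg$stats$w[i], seg$stats$h[i])
    iou <- bbox_iou(rb, box)
    if (iou > best_iou) { best_iou <- iou; best <- rb }
  }
  if (is.null(best) || best_iou < cfg$correction_iou) return(NULL)
  ratio <- (best[[3]] * best[[4]]) / (box[[3]] * box[[4]])
  if (ratio < 0.7 || ratio > 1.4) return(NULL)
  best
}

#' Advance the combined tracker one frame
#'
#' Runs the six-step loop: sample the search window (at the current scale),
#' extract gray+HOG features, correlate in the frequency domain, move to
#' the response peak, estimate scale with the scale filter, and update both
#' filters. When the response peak falls below `conf_floor` times its
#' running mean the frame is flagged occluded: templates are frozen and the
#' box coasts on the last reliable displacement. When correction is
#' enabled, the box snaps to the dominant watershed region's bounding box
#' if that region overlaps the box with IoU at least `correction_iou`.
#'
#' @param ct A `combined_tracker`.
#' @param f Next frame.
#' @return List with `box` ([bbox()]), `score` (response peak),
#'   `occluded`, and `ct` (updated tracker).
#' @export
ct_step <- function(ct, f) {
  cfg <- ct$cfg
  d <- dim(f)
  clamp <- function(p) pmin(pmax(p, c(0, 0)), c(d[2] - 1, d[1] - 1))
  det <- pf_detect(ct$pf, f, ct$center, ct$scale)
  cap <- c(ct$pf$window[2], ct$pf$window[1]) * ct$scale / 4
  cand <- clamp(ct$center + pmin(pmax(det$disp, -cap), cap))
  ncc <- target_ncc(ct, f, cand)
  coast_disp <- ct$vel * cfg$coast_damp^(ct$occl_run + 1L)
  jump_to <- NULL
  if (!isTRUE(cfg$occl_handling)) {
    # plain correlation-filter tracking (the MOSSE/CSK/KCF/DSST baselines):
    # no occlusion gate, no reacquisition, fixed learning rate
    occluded <- FALSE
  } else if (!ct$occluded) {
    # occlusion gate: the target-sized crop at the detected position must
    # still correlate with the stored target appearance
    occluded <- ncc < cfg$occl_enter
  } else {
    # probe reappearance hypotheses: the detector's candidate, the coasted
    # position, the anchor (last surely-seen position; right for a static
    # target) and the undamped velocity extrapolation from occlusion entry
    # (right for a target that kept moving behind the occluder); resume
    # needs stronger evidence (occl_exit > occl_enter) than staying
    coast_pos <- clamp(ct$center + coast_disp)
    extrap <- clamp(ct$entry_pos + ct$entry_vel * (ct$occl_run + 1))
    occluded <- TRUE
    for (probe in list(cand, coast_pos, ct$anchor, extrap)) {
      ncc_p <- target_ncc(ct, f, probe)
      if (ncc_p >= cfg$occl_exit) {
        occluded <- FALSE
        jump_to <- probe
        ncc <- ncc_p
        break
      }
    }
    if (occluded) {
      # none of the point hypotheses matched: sweep the search area around
      # the coasted position with the frozen target template
      sw <- target_search(ct, f, coast_pos,
                          radius = floor(max(ct$pf$window) * ct$scale / 2))
      # a long-range jump needs strong evidence: a clean reappearance
      # correlates far higher than a partial or distractor match
      if (sw$ncc >= 0.7) {
        occluded <- FALSE
        jump_to <- sw$pos
        ncc <- sw$ncc
      }
    }
    if (occluded && ct$occl_run >= 20L) {
      occluded <- FALSE      # hard cap: escape hatch for a false entry
      jump_to <- cand
    }
  }
  if (occluded) {
    # coast on the smoothed pre-occlusion velocity, damped so the center
    # cannot run away during a long occlusion
    if (ct$occl_run == 0L) {
      ct$entry_pos <- ct$center
      ct$entry_vel <- ct$vel
    }
    ct$occl_run <- ct$occl_run + 1L
    ct$center <- clamp(ct$center + coast_disp)
  } else {
    ct$occl_run <- 0L
    new_center <- if (is.null(jump_to)) cand else jump_to
    disp <- new_center - ct$center
    ct$center <- new_center
    # velocity and anchor are trusted state: refresh them only while the
    # appearance is solid, so a distractor dragging the box cannot corrupt
    # the coast direction or the reacquisition point
    if (ncc >= 0.7 && is.null(jump_to)) {
      ct$vel <- 0.7 * ct$vel + 0.3 * disp
      ct$anchor <- ct$center
    } else if (!is.null(jump_to)) {
      ct$vel <- ct$vel * 0.5      # velocity is stale after a jump
      if (ncc >= 0.7) ct$anchor <- ct$center
    }
  }
  if (!occluded && cfg$use_scale && !is.null(ct$sf)) {
    se <- sf_estimate(ct$sf, f, ct$center, ct$scale, update = TRUE)
    ct$sf <- se$sf
    new_scale <- ct$scale * se$factor
    sz <- ct$init_sz * new_scale
    if (all(sz >= 8) && all(sz <= d * 0.8)) {
      ct$scale <- new_scale
      ct$target_sz <- sz
    }
  }
  if (!occluded) {
    # learning scales with the appearance evidence, so an occlusion the
    # gate misses still pollutes the filter only marginally
    conf <- if (isTRUE(cfg$occl_handling)) {
      max(0, min(1, (ncc - cfg$occl_enter) / (0.8 - cfg$occl_enter)))
    } else 1
    ct$pf <- pf_update(ct$pf, f, ct$center, ct$scale, theta = cfg$theta * conf)
    if (ncc >= 0.7) {
      tpl_new <- target_crop(ct, f, ct$center)
      mixed <- 0.95 * ct$tpl + 0.05 * tpl_new
      ct$tpl <- mixed / max(sqrt(sum(mixed^2)), 1e-9)
    }
  }
  box <- bbox_clip(bbox(ct$center[1] - ct$target_sz[2] / 2,
                        ct$center[2] - ct$target_sz[1] / 2,
                        ct$target_sz[2], ct$target_sz[1]), d)
  # edge correction refines the box SIZE from the dominant watershed region;
  # position stays at the correlation peak, and only confident frames are
  # corrected so an occluder's edges are never learned into the scale
  high_conf <- !occluded && ncc >= 0.75
  if (high_conf && cfg$correction) {
    snapped <- watershed_correct(f, box, cfg)
    if (!is.null(snapped)) {
      new_sz <- 0.5 * ct$target_sz + 0.5 * c(snapped[[4]], snapped[[3]])
      ct$target_sz <- new_sz
      ct$scale <- sqrt(prod(new_sz) / prod(ct$init_sz))
      box <- bbox_clip(bbox(ct$center[1] - new_sz[2] / 2,
                            ct$center[2] - new_sz[1] / 2,
                            new_sz[2], new_sz[1]), d)
    }
  }
  ct$occluded <- occluded
  list(box = box, score = det$peak, occluded = occluded, ct = ct)
}

#' Track an organ target through a sequence with the combined tracker
#'
#' @param seq [video_sequence()].
#' @param box Initial [bbox()] on frame 1.
#' @param cfg [run_config()].
#' @return List with `trajectory` (scores are response peaks; NA on frame
#'   1) and `occluded` (logical per frame).
#' @export
track_organ <- function(seq, box, cfg = run_config()) {
  n <- length(seq$frames)
  ct <- ct_init(seq$frames[[1]], bbox_clip(box, seq_dim(seq)), cfg)
  boxes <- vector("list", n)
  cents <- matrix(NA_real_, n, 2)
  scores <- rep(NA_real_, n)
  occl <- logical(n)
  boxes[[1]] <- bbox_clip(box, seq_dim(seq))
  cents[1, ] <- bbox_center(boxes[[1]])
  for (t in 2:n) {
    st <- ct_step(ct, seq$frames[[t]])
    ct <- st$ct
    boxes[[t]] <- st$box
    cents[t, ] <- bbox_center(st$box)
    scores[t] <- st$score
    occl[t] <- st$occluded
  }
  list(trajectory = trajectory("organ", seq_len(n), boxes, cents, scores),
       occluded = occl)
}

# --- MOSSE baseline ---------------------------------------------------------

mosse_preprocess <- function(patch, win) {
  p <- log(patch + 1)
  p <- (p - mean(p)) / (stats::sd(p) + 1e-5)
  p * win
}

#' Track with the MOSSE filter (single-channel baseline)
#'
#' Classic minimum-output-sum-of-squared-error filter on log-normalized
#' gray patches with a Gaussian target, numerator/denominator running
#' averages at learning rate `theta`.
#'
#' @param seq [video_sequence()].
#' @param box Initial [bbox()].
#' @param cfg [run_config()].
#' @return List with `trajectory`.
#' @export
mosse_track <- function(seq, box, cfg = run_config()) {
  d <- seq_dim(seq)
  box <- bbox_clip(box, d)
  if (box[[3]] < 8 || box[[4]] < 8) stop("target box must be at least 8x8 px")
  n <- length(seq$frames)
  center <- bbox_center(box)
  win_sz <- c(round(box[[4]] * cfg$search_factor),
              round(box[[3]] * cfg$search_factor))
  win <- outer(cosine_window(win_sz[1], cfg$window_type),
               cosine_window(win_sz[2], cfg$window_type))
  sigma_y <- max(sqrt(box[[3]] * box[[4]]) / cfg$target_sigma_div, 1)
  G <- fft2(gaussian_label(win_sz[1], win_sz[2], sigma_y))
  p0 <- mosse_preprocess(get_subwindow(seq$frames[[1]], center, win_sz), win)
  F0 <- fft2(p0)
  A <- G * Conj(F0)
  B <- F0 * Conj(F0)
  boxes <- vector("list", n)
  cents <- matrix(NA_real_, n, 2)
  scores <- rep(NA_real_, n)
  boxes[[1]] <- box
  cents[1, ] <- center
  for (t in 2:n) {
    f <- seq$frames[[t]]
    p <- mosse_preprocess(get_subwindow(f, center, win_sz), win)
    Fp <- fft2(p)
    H <- A / (B + cfg$lambda)
    res <- Re(ifft2(H * Fp))
    shift <- response_shift(res)
    center <- pmin(pmax(center + shift, c(0, 0)), c(d[2] - 1, d[1] - 1))
    p2 <- mosse_preprocess(get_subwindow(f, center, win_sz), win)
    F2 <- fft2(p2)
    A <- (1 - cfg$theta) * A + cfg$theta * (G * Conj(F2))
    B <- (1 - cfg$theta) * B + cfg$theta * (F2 * Conj(F2))
    boxes[[t]] <- bbox_clip(bbox(center[1] - box[[3]] / 2,
                                 center[2] - box[[4]] / 2,
                                 box[[3]], box[[4]]), d)
    cents[t, ] <- bbox_center(boxes[[t]])
    scores[t] <- max(res)
  }
  list(trajectory = trajectory("mosse", seq_len(n), boxes, cents, scores))
}
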