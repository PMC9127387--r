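# Seeded generator of fluoroscopy-like grayscale sequences with exact ground
# truth. Scenes contain (a) a dark deformable bolus advecting along a smooth
# path with changing size/intensity, (b) rigid textured organ patches under
# translation and mild scale change, (c) transient occluder bars, and
# (d) additive Gaussian plus Poisson-like noise. Truth (masks, boxes,
# centroids, occlusion flags) is recorded before noise is applied.

#' Scene specification for the synthetic generator
#'
#' Usually built via [scene_preset()]; direct construction is for custom
#' scenes. Paths are per-frame center coordinates.
#'
#' @param preset Free-text scene name.
#' @param dim Frame dimensions `c(height, width)` in pixels.
#' @param n_frames Number of frames (>= 2).
#' @param bolus `NULL` or a list with `centers` (n x 2 matrix of (x, y)),
#'   `radius` (length-n vector, px), `intensity` (length-n, 0-255), and
#'   optional `deform` (logical: seeded eccentricity jitter).
#' @param organs List of organ patches, each a list with `id`, `size` (px),
#'   `centers` (n x 2), `scales` (length-n multipliers), `base_gray`.
#' @param occluders List of bars, each a list with `x` (length-n horizontal
#'   center path), `width`, `intensity`, `frames` (active frame indices).
#' @param noise List with `sigma` (Gaussian, intensity levels) and `poisson`
#'   (scale of the Poisson-like signal-dependent component; 0 disables).
#' @param seed Integer seed; together with the spec it fully determines the
#'   rendered sequence.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(preset, dim, n_frames, bolus = NULL, organs = list(),
                       occluders = list(), noise = list(sigma = 2, poisson = 0.2),
                       seed = 1) {
  spec <- structure(list(preset = preset, dim = dim, n_frames = n_frames,
                         bolus = bolus, organs = organs, occluders = occluders,
                         noise = noise, seed = as.integer(seed)),
                    class = "scene_spec")
  validate_scene(spec)
  spec
}

validate_scene <- function(spec) {
  h <- spec$dim[1]; w <- spec$dim[2]; n <- spec$n_frames
  if (n < 2) stop("scene must have at least 2 frames")
  inside <- function(cx, cy, rx, ry) {
    all(cx - rx >= 0) && all(cx + rx <= w - 1) &&
      all(cy - ry >= 0) && all(cy + ry <= h - 1)
  }
  if (!is.null(spec$bolus)) {
    b <- spec$bolus
    rmax <- b$radius * 1.35          # headroom for deformation jitter
    if (!inside(b$centers[, 1], b$centers[, 2], rmax, rmax))
      stop("bolus path exits the frame")
  }
  for (o in spec$organs) {
    half <- ceiling(o$size * o$scales / 2)
    if (!inside(o$centers[, 1], o$centers[, 2], half, half))
      stop(sprintf("organ '%s' path exits the frame", o$id))
  }
  invisible(spec)
}

# smooth seeded jitter in [-amp, amp]: moving-average of white noise
smooth_jitter <- function(n, amp, span = 5) {
  x <- stats::filter(rnorm(n + 2 * span), rep(1 / (2 * span + 1), 2 * span + 1),
                     sides = 2)
  x <- x[(span + 1):(span + n)]
  x[is.na(x)] <- 0
  s <- max(abs(x), 1e-9)
  amp * x / s
}

render_background <- function(dim) {
  h <- dim[1]; w <- dim[2]
  base <- matrix(150, h, w)
  # large-scale anatomy-like structure: blurred random field
  field <- matrix(rnorm(h * w), h, w)
  field <- EBImage::gblur(field, sigma = 8)
  field <- field / max(abs(field), 1e-9)
  base <- base + 25 * field
  # fixed dark vertical band standing in for the spine column
  xs <- col(base)
  spine_x <- round(w * 0.82)
  band <- exp(-((xs - spine_x)^2) / (2 * 6^2))
  base <- base - 45 * band
  pmin(pmax(base, 0), 255)
}

organ_texture <- function(size, base_gray) {
  t1 <- matrix(rnorm(size * size), size, size)
  t1 <- EBImage::gblur(t1, sigma = 1.5)
  t1 <- t1 / max(abs(t1), 1e-9)
  # add a couple of ridges so gradient features have structure
  yy <- row(t1); xx <- col(t1)
  ridges <- 18 * sin(2 * pi * xx / (size / 2.5)) * sin(2 * pi * yy / (size / 3))
  pmin(pmax(base_gray + 35 * t1 + ridges, 0), 255)
}

ellipse_mask <- function(dim, cx, cy, rx, ry) {
  yy <- matrix(0:(dim[1] - 1), dim[1], dim[2])
  xx <- matrix(0:(dim[2] - 1), dim[1], dim[2], byrow = TRUE)
  ((xx - cx) / rx)^2 + ((yy - cy) / ry)^2 <= 1
}

#' Render a synthetic fluoroscopy sequence with ground truth
#'
#' Deterministic given `(spec, spec$seed)`. Targets are composited in the
#' order background, organs, bolus, occluders; noise is added last and truth
#' is recorded pre-noise. A target is flagged occluded in a frame when an
#' occluder covers at least half of its mask.
#'
#' @param spec A [scene_spec()].
#' @return List with `seq` (a [video_sequence()]) and `truth`: per-target
#'   list with `kind`, and per-frame `boxes` (list of [bbox()]), `centroids`
#'   (n x 2), `masks` (list of logical matrices), `occluded` (logical n).
#' @export
render_scene <- function(spec) {
  withr::with_seed(derive_seed(spec$seed, paste0("render-", spec$preset)), {
    h <- spec$dim[1]; w <- spec$dim[2]; n <- spec$n_frames
    bg <- render_background(spec$dim)
    textures <- lapply(spec$organs, function(o) organ_texture(o$size, o$base_gray))
    if (!is.null(spec$bolus) && isTRUE(spec$bolus$deform)) {
      ecc <- smooth_jitter(n, 0.2)
      rjit <- 1 + smooth_jitter(n, 0.12)
      ijit <- smooth_jitter(n, 8)
    } else {
      ecc <- numeric(n); rjit <- rep(1, n); ijit <- numeric(n)
    }
    truth <- list()
    t_ids <- c(vapply(spec$organs, `[[`, character(1), "id"),
               if (!is.null(spec$bolus)) "bolus")
    for (id in t_ids)
      truth[[id]] <- list(kind = if (id == "bolus") "bolus" else "organ",
                          boxes = vector("list", n),
                          centroids = matrix(NA_real_, n, 2),
                          masks = vector("list", n),
                          occluded = logical(n))
    frames <- vector("list", n)
    for (t in seq_len(n)) {
      f <- bg
      occ_mask <- matrix(FALSE, h, w)
      for (j in seq_along(spec$organs)) {
        o <- spec$organs[[j]]
        s <- o$scales[t]
        tex <- textures[[j]]
        sz <- max(4L, round(o$size * s))
        if (sz != o$size)
          tex <- matrix(as.vector(EBImage::resize(tex, w = sz, h = sz)), sz, sz)
        x0 <- round(o$centers[t, 1] - sz / 2)
        y0 <- round(o$centers[t, 2] - sz / 2)
        f[(y0 + 1):(y0 + sz), (x0 + 1):(x0 + sz)] <- tex
        m <- matrix(FALSE, h, w)
        m[(y0 + 1):(y0 + sz), (x0 + 1):(x0 + sz)] <- TRUE
        truth[[o$id]]$masks[[t]] <- m
        truth[[o$id]]$boxes[[t]] <- bbox(x0, y0, sz, sz)
        truth[[o$id]]$centroids[t, ] <- c(x0 + sz / 2, y0 + sz / 2)
      }
      if (!is.null(spec$bolus)) {
        b <- spec$bolus
        r <- b$radius[t] * rjit[t]
        rx <- r * (1 + ecc[t]); ry <- r * (1 - ecc[t])
        m <- ellipse_mask(spec$dim, b$centers[t, 1], b$centers[t, 2], rx, ry)
        f[m] <- pmin(pmax(b$intensity[t] + ijit[t], 0), 255)
        truth$bolus$masks[[t]] <- m
        truth$bolus$boxes[[t]] <- mask_bbox(m)
        truth$bolus$centroids[t, ] <- mask_centroid(m)
      }
      for (oc in spec$occluders) {
        if (!t %in% oc$frames) next
        xc <- oc$x[t]
        x0 <- max(0, round(xc - oc$width / 2)); x1 <- min(w, round(xc + oc$width / 2))
        if (x1 <= x0) next
        f[, (x0 + 1):x1] <- oc$intensity
        occ_mask[, (x0 + 1):x1] <- TRUE
      }
      for (id in t_ids) {
        m <- truth[[id]]$masks[[t]]
        cov <- if (sum(m) > 0) sum(m & occ_mask) / sum(m) else 0
        truth[[id]]$occluded[t] <- cov >= 0.5
      }
      if (spec$noise$sigma > 0)
        f <- f + rnorm(h * w, sd = spec$noise$sigma)
      if (spec$noise$poisson > 0) {
        ps <- spec$noise$poisson
        lam <- pmax(f, 0) / max(ps, 1e-9)
        f <- rpois(h * w, lam) * ps
        f <- matrix(f, h, w)
      }
      frames[[t]] <- round(pmin(pmax(f, 0), 255))
    }
    list(seq = video_sequence(frames, source_id = spec$preset), truth = truth)
  })
}

# --- presets ----------------------------------------------------------------

lin_path <- function(n, from, to) {
  cbind(seq(from[1], to[1], length.out = n), seq(from[2], to[2], length.out = n))
}

#' Build a named synthetic scene preset
#'
#' Available presets:
#' * `side_view`: 50 frames, 120x160 px; deforming bolus advecting along a
#'   curved oropharyngeal-like path past two organ patches.
#' * `elevation_view` / `elevation_small_target`: 30 frames, 100x120 px;
#'   small bolus dwelling motionless for most of the sequence then moving
#'   abruptly (about 6 px/frame).
#' * `clean_translation`: deforming bolus translating at a constant
#'   3 px/frame, no occlusion — the discrete-point tracker benchmark.
#' * `occlusion_pass`: rigid organ patch crossed by an opaque bar that fully
#'   covers it for several frames.
#' * `forward_lean`: chin and spine-anchor patches translating along
#'   correlated "lean forward" paths.
#' * `bolus_interference`: organ patch with the bolus sweeping directly past
#'   and over it.
#' * `scale_change`: organ patch growing about 35% in linear size while
#'   drifting.
#'
#' @param name Preset name (see above).
#' @param seed Integer seed.
#' @return A [scene_spec()].
#' @export
scene_preset <- function(name, seed = 1) {
  switch(name,
    side_view = {
      n <- 50
      # curved path: two linear legs blended smoothly
      tt <- seq(0, 1, length.out = n)
      cx <- 30 + 90 * tt
      cy <- 30 + 55 * tt^1.6
      scene_spec("side_view", c(120, 160), n,
        bolus = list(centers = cbind(cx, cy),
                     radius = rep(9, n), intensity = rep(48, n), deform = TRUE),
        organs = list(
          list(id = "chin", size = 22,
               centers = cbind(45 + 1.5 * sin(tt * 2 * pi), 88 + cos(tt * 2 * pi)),
               scales = rep(1, n), base_gray = 150),
          list(id = "spine_anchor", size = 20,
               centers = cbind(rep(131, n), rep(58, n)),
               scales = rep(1, n), base_gray = 135)),
        seed = seed)
    },
    elevation_view = ,
    elevation_small_target = {
      n <- 30
      dwell <- 18
      cx <- c(rep(40, dwell), 40 + 6 * seq_len(n - dwell))
      cy <- c(rep(50, dwell), 50 + 2.5 * seq_len(n - dwell))
      scene_spec(name, c(100, 120), n,
        bolus = list(centers = cbind(cx, cy),
                     radius = rep(5, n), intensity = rep(52, n), deform = TRUE),
        seed = seed)
    },
    clean_translation = {
      n <- 40
      scene_spec("clean_translation", c(120, 160), n,
        bolus = list(centers = lin_path(n, c(20, 55), c(20 + 3 * (n - 1), 55 + 0.5 * (n - 1))),
                     radius = rep(10, n), intensity = rep(50, n), deform = TRUE),
        noise = list(sigma = 1.5, poisson = 0.15),
        seed = seed)
    },
    occlusion_pass = {
      n <- 40
      centers <- lin_path(n, c(40, 58), c(40 + 1.5 * (n - 1), 58 + 0.3 * (n - 1)))
      scene_spec("occlusion_pass", c(120, 160), n,
        organs = list(list(id = "organ", size = 26, centers = centers,
                           scales = rep(1, n), base_gray = 150)),
        occluders = list(list(
          # bar sweeps right at 4 px/frame, overtaking the target mid-sequence
          # (full coverage around frames 17-21)
          x = -5 + 4 * (seq_len(n) - 1), width = 30, intensity = 35,
          frames = 14:24)),
        seed = seed)
    },
    forward_lean = {
      n <- 40
      tt <- seq(0, 1, length.out = n)
      scene_spec("forward_lean", c(120, 160), n,
        organs = list(
          list(id = "chin", size = 22,
               centers = cbind(55 + 38 * tt - 8 * tt^2, 42 + 26 * tt),
               scales = rep(1, n), base_gray = 150),
          list(id = "spine_anchor", size = 20,
               centers = cbind(118 + 6 * tt, 66 + 3 * tt),
               scales = rep(1, n), base_gray = 135)),
        seed = seed)
    },
    bolus_interference = {
      n <- 40
      organ_c <- cbind(rep(80, n), rep(60, n))
      scene_spec("bolus_interference", c(120, 160), n,
        organs = list(list(id = "organ", size = 24, centers = organ_c,
                           scales = rep(1, n), base_gray = 150)),
        bolus = list(centers = lin_path(n, c(20, 58), c(140, 64)),
                     radius = rep(8, n), intensity = rep(48, n), deform = TRUE),
        seed = seed)
    },
    scale_change = {
      n <- 30
      scene_spec("scale_change", c(120, 160), n,
        organs = list(list(id = "organ", size = 24,
                           centers = lin_path(n, c(50, 55), c(50 + (n - 1), 55 + 0.5 * (n - 1))),
                           scales = seq(1, 1.35, length.out = n),
                           base_gray = 150)),
        seed = seed)
    },
    stop("unknown preset: ", name)
  )
}

#' Render the fixed benchmark suite
#'
#' Six scenes exercising the failure modes the trackers are designed for:
#' clean translation, occlusion, forward lean, bolus interference, scale
#' change, and a small target with long dwell then abrupt motion.
#'
#' @param seed Integer seed applied to every scene.
#' @return Named list; each element has `name`, `seq`, `truth`.
#' @export
preset_suite <- function(seed = 1) {
  names <- c("clean_translation", "occlusion_pass", "forward_lean",
             "bolus_interference", "scale_change", "elevation_small_target")
  out <- lapply(names, function(nm) {
    r <- render_scene(scene_preset(nm, seed))
    list(name = nm, seq = r$seq, truth = r$truth)
  })
  stats::setNames(out, names)
}
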