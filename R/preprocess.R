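# Preprocessing: rotation into a spine-anchored coordinate frame, global and
# local contrast stretching, ROI-restricted bilateral denoising, and
# level-controlled watershed segmentation. Every tracker in the package sits
# on top of these.

#' Rotation specification
#'
#' @param center Rotation anchor `c(xc, yc)` in 0-based pixels (typically a
#'   point on the spine).
#' @param angle Rotation angle in degrees, clockwise positive, in
#'   `(-180, 180]`.
#' @return A `rotation_spec` list.
#' @export
rotation_spec <- function(center, angle) {
  if (length(center) != 2) stop("center must be c(xc, yc)")
  if (angle <= -180 || angle > 180) stop("angle must lie in (-180, 180]")
  structure(list(center = as.numeric(center), angle = as.numeric(angle)),
            class = "rotation_spec")
}

# 3x3 homogeneous transform for a clockwise rotation about (a, b):
# translate by -O, rotate, translate back (C %*% B %*% A).
rotation_matrix <- function(center, angle) {
  a <- center[1]; b <- center[2]
  th <- angle * pi / 180
  A <- matrix(c(1, 0, -a, 0, 1, -b, 0, 0, 1), 3, 3, byrow = TRUE)
  B <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1),
              3, 3, byrow = TRUE)
  C <- matrix(c(1, 0, a, 0, 1, b, 0, 0, 1), 3, 3, byrow = TRUE)
  C %*% B %*% A
}

# apply a 3x3 homogeneous transform to n points given as an n x 2 matrix
transform_points <- function(M, pts) {
  p <- cbind(pts, 1) %*% t(M)
  p[, 1:2, drop = FALSE]
}

#' Rotate a frame about an anchor point
#'
#' Rotates the image clockwise by `spec$angle` degrees about `spec$center`
#' using the translate / rotate / translate-back composition, sampling the
#' source with bilinear interpolation. Pixels whose source falls outside the
#' frame are set to 0. Output has the same dimensions as the input.
#'
#' @param f Frame (numeric matrix, 0-255).
#' @param spec A [rotation_spec()]; the center must lie inside the frame.
#' @return Rotated frame.
#' @export
rotate_about <- function(f, spec) {
  d <- dim(f)
  ctr <- spec$center
  if (ctr[1] < 0 || ctr[1] > d[2] - 1 || ctr[2] < 0 || ctr[2] > d[1] - 1)
    stop("rotation center lies outside the frame")
  if (spec$angle == 0) return(f)
  # inverse mapping: destination pixel <- source at rotation by -angle
  Minv <- rotation_matrix(ctr, -spec$angle)
  xs <- rep(0:(d[2] - 1), each = d[1])
  ys <- rep(0:(d[1] - 1), times = d[2])
  src <- transform_points(Minv, cbind(xs, ys))
  sx <- src[, 1]; sy <- src[, 2]
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  # gather with zero fill outside
  pick <- function(xx, yy) {
    ok <- xx >= 0 & xx <= d[2] - 1 & yy >= 0 & yy <= d[1] - 1
    v <- numeric(length(xx))
    v[ok] <- f[cbind(yy[ok] + 1, xx[ok] + 1)]
    v
  }
  v <- (1 - fx) * (1 - fy) * pick(x0, y0) +
       fx * (1 - fy) * pick(x0 + 1, y0) +
       (1 - fx) * fy * pick(x0, y0 + 1) +
       fx * fy * pick(x0 + 1, y0 + 1)
  matrix(v, d[1], d[2])
}

#' Contrast stretch specification
#'
#' @param o_min,o_max Output intensity limits, `0 <= o_min < o_max <= 255`.
#' @param scope `"global"` or `"local"`; local stretching computes the input
#'   range in a sliding window centered at each pixel.
#' @param window Odd window side in pixels for `scope = "local"`.
#' @return A `stretch_spec` list.
#' @export
stretch_spec <- function(o_min = 0, o_max = 255, scope = c("global", "local"),
                         window = 31) {
  scope <- match.arg(scope)
  if (o_min >= o_max) stop("o_min must be < o_max")
  if (o_min < 0 || o_max > 255) stop("output limits must lie in [0, 255]")
  if (scope == "local" && (window < 3 || window %% 2 == 0))
    stop("local window must be odd and >= 3")
  structure(list(o_min = o_min, o_max = o_max, scope = scope, window = window),
            class = "stretch_spec")
}

#' Linear contrast stretching
#'
#' Maps input intensities so the observed range `[N_min, N_max]` lands on
#' `[o_min, o_max]`:
#' `P_out = (P_in - N_min) * (o_max - o_min) / (N_max - N_min) + o_min`,
#' with the result clipped to `[0, 255]`. For local scope, `N_min` and
#' `N_max` are the sliding-window minimum and maximum around each pixel
#' (computed by grayscale erosion / dilation).
#'
#' @param f Frame.
#' @param spec A [stretch_spec()].
#' @return Stretched frame (double precision; not truncated to integers).
#' @export
contrast_stretch <- function(f, spec = stretch_spec()) {
  if (spec$scope == "global") {
    n_min <- min(f); n_max <- max(f)
    if (n_min == n_max) {
      warning("constant frame: contrast stretch undefined, returning input")
      return(f)
    }
    out <- (f - n_min) * (spec$o_max - spec$o_min) / (n_max - n_min) + spec$o_min
  } else {
    brush <- EBImage::makeBrush(spec$window, shape = "box")
    n_min <- EBImage::erode(f / 255, brush) * 255
    n_max <- EBImage::dilate(f / 255, brush) * 255
    rng <- pmax(n_max - n_min, 1e-8)
    out <- (f - n_min) * (spec$o_max - spec$o_min) / rng + spec$o_min
  }
  pmin(pmax(out, 0), 255)
}

#' Bilateral denoising restricted to a region of interest
#'
#' Applies an edge-preserving bilateral filter inside `roi`; pixels outside
#' the box are returned untouched. The filter is evaluated over a window of
#' radius `2 * sigma_s` with Gaussian spatial weights (scale `sigma_s`, in
#' pixels) and Gaussian range weights (scale `sigma_r`, in intensity
#' levels). Neighborhoods are clamped at the frame border.
#'
#' @param f Frame.
#' @param roi [bbox()] inside the frame.
#' @param sigma_s Spatial standard deviation (px).
#' @param sigma_r Range standard deviation (intensity levels).
#' @return Frame with the ROI denoised.
#' @export
bilateral_denoise <- function(f, roi, sigma_s = 2, sigma_r = 25) {
  d <- dim(f)
  if (!bbox_inside(roi, d)) stop("roi must lie inside the frame")
  if (roi[[3]] < 1 || roi[[4]] < 1) stop("empty roi")
  r <- max(1L, ceiling(2 * sigma_s))
  # pad the crop with replicated context so the ROI border is filtered with
  # true neighbors where available
  x0 <- max(0, roi[[1]] - r); y0 <- max(0, roi[[2]] - r)
  x1 <- min(d[2], roi[[1]] + roi[[3]] + r); y1 <- min(d[1], roi[[2]] + roi[[4]] + r)
  sub <- f[(y0 + 1):y1, (x0 + 1):x1, drop = FALSE]
  sd1 <- dim(sub)
  num <- matrix(0, sd1[1], sd1[2])
  den <- matrix(0, sd1[1], sd1[2])
  for (dy in -r:r) {
    for (dx in -r:r) {
      w_s <- exp(-(dx * dx + dy * dy) / (2 * sigma_s^2))
      # shifted copy with clamped (replicated) borders
      ri <- pmin(pmax(seq_len(sd1[1]) + dy, 1), sd1[1])
      ci <- pmin(pmax(seq_len(sd1[2]) + dx, 1), sd1[2])
      sh <- sub[ri, ci, drop = FALSE]
      w <- w_s * exp(-(sh - sub)^2 / (2 * sigma_r^2))
      num <- num + w * sh
      den <- den + w
    }
  }
  filt <- num / den
  out <- f
  ry <- (roi[[2]] + 1):(roi[[2]] + roi[[4]])
  rx <- (roi[[1]] + 1):(roi[[1]] + roi[[3]])
  out[ry, rx] <- filt[ry - y0, rx - x0, drop = FALSE]
  out
}

sobel_gradient <- function(f) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)
  gx <- EBImage::filter2(f, kx)
  gy <- EBImage::filter2(f, t(kx))
  sqrt(gx^2 + gy^2)
}

#' Level-controlled watershed segmentation
#'
#' Computes the Sobel gradient magnitude of the frame restricted to `roi`
#' and applies a watershed transform whose markers are the regional minima
#' that survive an h-minima suppression of depth `h = h_base * 2^(c - 1)`.
#' The segmentation level `c` therefore controls coarseness: larger `c`
#' suppresses more shallow basins and yields fewer, larger regions;
#' lowering `c` never decreases the region count.
#'
#' @param f Frame.
#' @param roi [bbox()] of at least 3x3 px inside the frame.
#' @param c Segmentation level, integer >= 1.
#' @param h_base Base suppression depth in intensity levels (default 4).
#' @return A `segmentation_map`: list with `labels` (integer matrix of ROI
#'   shape, regions 1..n), `roi`, `level`, and `stats` (data.frame with
#'   `label`, `area`, `mean_gray`, and box coordinates in frame coordinates).
#' @export
watershed_segment <- function(f, roi, c = 4, h_base = 4) {
  d <- dim(f)
  if (c < 1) stop("segmentation level c must be >= 1")
  roi <- bbox_clip(roi, d)
  if (roi[[3]] < 3 || roi[[4]] < 3) stop("roi must be at least 3x3 px")
  sub <- bbox_crop(f, roi)
  grad <- sobel_gradient(sub)
  h <- h_base * 2^(c - 1)
  # flood from gradient minima: invert so basins become peaks, merge basins
  # shallower than h (h-minima suppression)
  inv <- max(grad) + 1 - grad
  labels <- EBImage::watershed(inv, tolerance = h, ext = 1)
  labels <- matrix(as.integer(round(as.vector(labels))), nrow(sub), ncol(sub))
  segmentation_map(labels, roi, c, sub)
}

segmentation_map <- function(labels, roi, level, sub) {
  labs <- sort(unique(as.vector(labels)))
  labs <- labs[labs > 0]
  stats <- do.call(rbind, lapply(labs, function(l) {
    m <- labels == l
    idx <- which(m, arr.ind = TRUE)
    data.frame(label = l, area = nrow(idx),
               mean_gray = mean(sub[m]),
               x = roi[[1]] + min(idx[, 2]) - 1,
               y = roi[[2]] + min(idx[, 1]) - 1,
               w = max(idx[, 2]) - min(idx[, 2]) + 1,
               h = max(idx[, 1]) - min(idx[, 1]) + 1)
  }))
  if (is.null(stats))
    stats <- data.frame(label = integer(), area = integer(),
                        mean_gray = numeric(), x = numeric(), y = numeric(),
                        w = numeric(), h = numeric())
  structure(list(labels = labels, roi = roi, level = level, stats = stats),
            class = "segmentation_map")
}

#' @export
print.segmentation_map <- function(x, ...) {
  cat(sprintf("<segmentation_map: %d regions at level %d in [%g,%g,%g,%g]>\n",
              nrow(x$stats), x$level, x$roi[[1]], x$roi[[2]], x$roi[[3]],
              x$roi[[4]]))
  invisible(x)
}

# full-frame logical mask of one watershed region
segmap_region_mask <- function(seg, label, dim) {
  m <- matrix(FALSE, dim[1], dim[2])
  sub <- seg$labels == label
  m[(seg$roi[[2]] + 1):(seg$roi[[2]] + seg$roi[[4]]),
    (seg$roi[[1]] + 1):(seg$roi[[1]] + seg$roi[[3]])] <- sub
  m
}
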