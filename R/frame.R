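#' @importFrom stats fft rnorm runif rpois setNames
#' @importFrom utils read.csv
NULL

# Frames are plain numeric matrices: rows index y (down), columns index x
# (right), intensities on the 0-255 scale. Pixel (x, y) in 0-based image
# coordinates is f[y + 1, x + 1].

#' Construct an axis-aligned bounding box
#'
#' Boxes use the half-open integer convention `[x, x + w) x [y, y + h)` in
#' 0-based image coordinates (x right, y down). They are the unit of all
#' tracker input and output.
#'
#' @param x,y Top-left corner (0-based pixels).
#' @param w,h Width and height in pixels (must be positive).
#' @return A named numeric vector of class `bbox`.
#' @export
bbox <- function(x, y, w, h) {
  if (w <= 0 || h <= 0) stop("bbox width and height must be positive")
  structure(c(x = x, y = y, w = w, h = h), class = "bbox")
}

#' @export
print.bbox <- function(x, ...) {
  cat(sprintf("<bbox x=%g y=%g w=%g h=%g>\n", x[1], x[2], x[3], x[4]))
  invisible(x)
}

bbox_center <- function(b) c(b[[1]] + b[[3]] / 2, b[[2]] + b[[4]] / 2)

#' Clip a box to frame bounds
#'
#' @param b A [bbox()].
#' @param dim Frame dimensions `c(nrow, ncol)` i.e. `c(height, width)`.
#' @return Clipped `bbox`; degenerate results collapse to a 1x1 box at the
#'   nearest valid corner.
#' @export
bbox_clip <- function(b, dim) {
  h <- dim[1]; w <- dim[2]
  x0 <- max(0, min(round(b[[1]]), w - 1))
  y0 <- max(0, min(round(b[[2]]), h - 1))
  x1 <- max(x0 + 1, min(round(b[[1]] + b[[3]]), w))
  y1 <- max(y0 + 1, min(round(b[[2]] + b[[4]]), h))
  bbox(x0, y0, x1 - x0, y1 - y0)
}

bbox_inside <- function(b, dim) {
  b[[1]] >= 0 && b[[2]] >= 0 &&
    b[[1]] + b[[3]] <= dim[2] && b[[2]] + b[[4]] <= dim[1]
}

# submatrix of f covered by integer box b (assumed clipped)
bbox_crop <- function(f, b) {
  f[(b[[2]] + 1):(b[[2]] + b[[4]]), (b[[1]] + 1):(b[[1]] + b[[3]]), drop = FALSE]
}

# logical matrix of frame shape with TRUE inside b
bbox_mask <- function(b, dim) {
  m <- matrix(FALSE, dim[1], dim[2])
  bc <- bbox_clip(b, dim)
  m[(bc[[2]] + 1):(bc[[2]] + bc[[4]]), (bc[[1]] + 1):(bc[[1]] + bc[[3]])] <- TRUE
  m
}

#' Intersection-over-union of two boxes
#'
#' @param a,b [bbox()] vectors.
#' @return IoU in \[0, 1\]; 0 for disjoint boxes.
#' @export
bbox_iou <- function(a, b) {
  ix <- max(0, min(a[[1]] + a[[3]], b[[1]] + b[[3]]) - max(a[[1]], b[[1]]))
  iy <- max(0, min(a[[2]] + a[[4]], b[[2]] + b[[4]]) - max(a[[2]], b[[2]]))
  inter <- ix * iy
  union <- a[[3]] * a[[4]] + b[[3]] * b[[4]] - inter
  if (union <= 0) return(0)
  inter / union
}

# bounding box of TRUE pixels in a logical matrix; NULL if empty
mask_bbox <- function(m) {
  idx <- which(m, arr.ind = TRUE)
  if (nrow(idx) == 0) return(NULL)
  y0 <- min(idx[, 1]) - 1; y1 <- max(idx[, 1])
  x0 <- min(idx[, 2]) - 1; x1 <- max(idx[, 2])
  bbox(x0, y0, x1 - x0, y1 - y0)
}

# centroid (x, y) of TRUE pixels, 0-based pixel centers
mask_centroid <- function(m) {
  idx <- which(m, arr.ind = TRUE)
  if (nrow(idx) == 0) return(NULL)
  c(mean(idx[, 2]) - 1, mean(idx[, 1]) - 1)
}

mask_iou <- function(a, b) {
  inter <- sum(a & b)
  union <- sum(a | b)
  if (union == 0) return(0)
  inter / union
}

#' Assemble a video sequence container
#'
#' @param frames List of frames (numeric matrices sharing one shape).
#' @param frame_rate Frames per second, metadata only.
#' @param source_id Free-text provenance label.
#' @return A `video_sequence` object (list with `frames`, `frame_rate`,
#'   `source_id`).
#' @export
video_sequence <- function(frames, frame_rate = 25, source_id = "") {
  stopifnot(is.list(frames), length(frames) >= 1)
  d <- dim(frames[[1]])
  for (i in seq_along(frames)) {
    if (!identical(dim(frames[[i]]), d))
      stop(sprintf("frame %d has dimensions %s, expected %s", i,
                   paste(dim(frames[[i]]), collapse = "x"),
                   paste(d, collapse = "x")))
  }
  structure(list(frames = frames, frame_rate = frame_rate,
                 source_id = source_id),
            class = "video_sequence")
}

#' @export
print.video_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<video_sequence: %d frames, %dx%d px, %g fps, '%s'>\n",
              length(x$frames), d[2], d[1], x$frame_rate, x$source_id))
  invisible(x)
}

#' @export
length.video_sequence <- function(x) length(x$frames)

seq_dim <- function(seq) dim(seq$frames[[1]])

# mix a base seed with a small stream label, staying inside 32-bit range
derive_seed <- function(seed, stream) {
  s <- sum(utf8ToInt(as.character(stream)) * (seq_along(utf8ToInt(as.character(stream))) %% 7 + 1))
  as.integer((as.numeric(seed) * 7919 + s * 131) %% 2147483647L)
}
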