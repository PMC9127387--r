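# Sequence and trajectory I/O. Frames travel as PNG/TIFF stacks ordered by
# natural (numeric-aware) filename sort; trajectories as plain CSV.

natural_order <- function(x) {
  # numeric-aware sort: split into digit / non-digit runs and pad numbers
  key <- vapply(x, function(s) {
    parts <- regmatches(s, gregexpr("[0-9]+|[^0-9]+", s))[[1]]
    parts <- vapply(parts, function(p) {
      if (grepl("^[0-9]+$", p)) sprintf("%020d", as.numeric(p)) else p
    }, character(1))
    paste(parts, collapse = "")
  }, character(1))
  order(key)
}

read_one_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", path))
  # readPNG/readTIFF return [0,1] doubles, possibly with channels
  if (length(dim(img)) == 3) {
    # luminance conversion for color inputs
    nc <- dim(img)[3]
    img <- if (nc >= 3)
      0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    else img[, , 1]
  }
  # linear rescale to 0-255 regardless of source bit depth
  img * 255
}

#' Read an image stack as a video sequence
#'
#' Frames are ordered by natural sort of filename, converted to luminance if
#' colored, and linearly rescaled to the 0-255 range.
#'
#' @param path Directory containing the frames.
#' @param pattern Glob pattern for frame files (default all PNG/TIFF).
#' @param frame_rate Metadata frames/second.
#' @return A [video_sequence()].
#' @export
read_sequence <- function(path, pattern = "*.png", frame_rate = 25) {
  if (!dir.exists(path)) {
    if (grepl("\\.avi$", path, ignore.case = TRUE))
      stop("AVI input is not supported; export the video as a PNG/TIFF stack")
    stop("no such directory: ", path)
  }
  files <- Sys.glob(file.path(path, pattern))
  if (length(files) < 2)
    stop(sprintf("fewer than 2 frames match '%s' in %s", pattern, path))
  files <- files[natural_order(basename(files))]
  frames <- lapply(files, read_one_image)
  d <- dim(frames[[1]])
  for (i in seq_along(frames))
    if (!identical(dim(frames[[i]]), d))
      stop(sprintf("frame '%s' has dimensions %s, expected %s",
                   basename(files[i]), paste(dim(frames[[i]]), collapse = "x"),
                   paste(d, collapse = "x")))
  video_sequence(frames, frame_rate = frame_rate, source_id = path)
}

#' Write a video sequence as a PNG stack
#'
#' @param seq A [video_sequence()].
#' @param path Output directory (created if needed).
#' @param prefix Filename prefix; frames become `prefix0000.png`, ...
#' @return The directory path, invisibly.
#' @export
write_sequence <- function(seq, path, prefix = "f") {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(seq$frames)) {
    f <- pmin(pmax(round(seq$frames[[i]]), 0), 255) / 255
    png::writePNG(f, file.path(path, sprintf("%s%04d.png", prefix, i - 1)))
  }
  invisible(path)
}

#' Write a binary mask stack as PNGs (0 background / 255 foreground)
#'
#' @param masks List of logical matrices.
#' @param path Output directory.
#' @param prefix Filename prefix.
#' @export
write_masks <- function(masks, path, prefix = "m") {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(masks)) {
    png::writePNG(masks[[i]] * 1,
                  file.path(path, sprintf("%s%04d.png", prefix, i - 1)))
  }
  invisible(path)
}

#' Construct a trajectory record
#'
#' @param target_id Target label.
#' @param frames Integer frame indices (strictly increasing, 1-based).
#' @param boxes List of [bbox()] per frame.
#' @param centroids n x 2 matrix of (x, y) centers.
#' @param scores Per-frame confidence (unitless); NA allowed.
#' @return A `trajectory` object.
#' @export
trajectory <- function(target_id, frames, boxes, centroids, scores = NULL) {
  n <- length(frames)
  if (n == 0) stop("trajectory must contain at least one record")
  if (any(diff(frames) <= 0)) stop("frame indices must be strictly increasing")
  if (is.null(scores)) scores <- rep(NA_real_, n)
  stopifnot(length(boxes) == n, nrow(centroids) == n, length(scores) == n)
  structure(list(target_id = target_id, frames = as.integer(frames),
                 boxes = boxes, centroids = centroids,
                 scores = as.numeric(scores)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory '%s': %d records, frames %d..%d>\n", x$target_id,
              length(x$frames), min(x$frames), max(x$frames)))
  invisible(x)
}

#' Write a trajectory as CSV
#'
#' Columns: `frame,x,y,w,h,cx,cy,score`. Numeric values are written with
#' full precision so [read_trajectory()] round-trips exactly.
#'
#' @param t A [trajectory()].
#' @param path Output CSV path.
#' @export
write_trajectory <- function(t, path) {
  if (length(t$frames) == 0) stop("empty trajectory")
  num <- function(v) ifelse(is.na(v), "NA", sprintf("%.17g", v))
  lines <- c("frame,x,y,w,h,cx,cy,score",
             vapply(seq_along(t$frames), function(i) {
               b <- t$boxes[[i]]
               paste(c(t$frames[i], num(b[[1]]), num(b[[2]]), num(b[[3]]),
                       num(b[[4]]), num(t$centroids[i, 1]),
                       num(t$centroids[i, 2]), num(t$scores[i])),
                     collapse = ",")
             }, character(1)))
  con <- file(path, "wb")     # binary mode: byte-identical across platforms
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read a trajectory CSV written by [write_trajectory()]
#'
#' @param path CSV path.
#' @param target_id Label to attach (default: file stem).
#' @return A [trajectory()].
#' @export
read_trajectory <- function(path, target_id = NULL) {
  df <- utils::read.csv(path)
  need <- c("frame", "x", "y", "w", "h", "cx", "cy", "score")
  if (!all(need %in% names(df)))
    stop("trajectory CSV must have columns ", paste(need, collapse = ","))
  if (is.null(target_id))
    target_id <- tools::file_path_sans_ext(basename(path))
  trajectory(target_id, df$frame,
             lapply(seq_len(nrow(df)), function(i)
               bbox(df$x[i], df$y[i], df$w[i], df$h[i])),
             cbind(df$cx, df$cy), df$score)
}
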