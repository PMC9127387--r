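# Background-subtraction baselines used in the detector comparison: ViBe
# (per-pixel sample sets initialized from one frame, stochastic
# temporal/spatial update) and a non-parametric EGMM variant built on the
# balloon density estimator (kernel width expands at each pixel until k
# history samples are covered).

#' Initialize a ViBe background model from a single frame
#'
#' Each pixel's `n` samples are drawn uniformly at random, with replacement,
#' from its 8-neighborhood (clamped at borders) in the first frame.
#'
#' @param f Frame.
#' @param n Samples per pixel (default 20).
#' @param r Match radius in intensity levels (default 20).
#' @param n_min Minimum match count for background (default 2).
#' @param phi Subsampling factor: 1-in-phi update probability (default 16).
#' @param seed Integer seed.
#' @return A `vibe_model`: `samples` (h x w x n array), parameters, `dim`.
#' @export
vibe_init <- function(f, n = 20, r = 20, n_min = 2, phi = 16, seed = 1) {
  d <- dim(f)
  h <- d[1]; w <- d[2]
  samples <- withr::with_seed(derive_seed(seed, "vibe-init"), {
    arr <- array(0, c(h, w, n))
    ys <- matrix(rep(seq_len(h), w), h, w)
    xs <- matrix(rep(seq_len(w), each = h), h, w)
    for (i in seq_len(n)) {
      dy <- matrix(sample(-1:1, h * w, replace = TRUE), h, w)
      dx <- matrix(sample(-1:1, h * w, replace = TRUE), h, w)
      ny <- pmin(pmax(ys + dy, 1), h)
      nx <- pmin(pmax(xs + dx, 1), w)
      arr[, , i] <- f[cbind(as.vector(ny), as.vector(nx))]
    }
    arr
  })
  structure(list(samples = samples, n = n, r = r, n_min = n_min, phi = phi,
                 dim = d),
            class = "vibe_model")
}

#' Classify a frame against a ViBe model
#'
#' A pixel is background (`FALSE`) iff at least `n_min` of its stored
#' samples lie within radius `r` of its current value; otherwise foreground
#' (`TRUE`).
#'
#' @param model A `vibe_model`.
#' @param f Frame of matching shape.
#' @return Logical foreground mask.
#' @export
vibe_classify <- function(model, f) {
  if (!identical(dim(f), model$dim)) stop("frame shape does not match model")
  count <- matrix(0L, model$dim[1], model$dim[2])
  for (i in seq_len(model$n))
    count <- count + (abs(f - model$samples[, , i]) < model$r)
  count < model$n_min
}

#' Stochastic ViBe model update
#'
#' For each background pixel: with probability `1/phi` one of its own
#' samples (chosen at random) is replaced by its current value, and,
#' independently with probability `1/phi`, a random sample of a random
#' 8-neighbor is refreshed with that neighbor's current value (the spatial
#' "random protection" update, which lets a suddenly stopped object be
#' integrated into the background from its border inward). Foreground
#' pixels perform no update of their own.
#'
#' @param model A `vibe_model`.
#' @param f Current frame.
#' @param mask Foreground mask from [vibe_classify()].
#' @param seed Integer seed.
#' @return Updated `vibe_model`.
#' @export
vibe_update <- function(model, f, mask, seed = 1) {
  d <- model$dim
  bg <- which(!mask)
  if (length(bg) == 0) return(model)
  withr::with_seed(derive_seed(seed, "vibe-upd"), {
    # temporal update
    sel <- bg[runif(length(bg)) < 1 / model$phi]
    if (length(sel) > 0) {
      slot <- sample.int(model$n, length(sel), replace = TRUE)
      idx <- arrayInd(sel, d)
      model$samples[cbind(idx[, 1], idx[, 2], slot)] <- f[sel]
    }
    # spatial "protection" update: a background pixel refreshes a random
    # sample of a random 8-neighbor with that neighbor's current value, so
    # a stationary foreground object is absorbed from its border inward
    sel2 <- bg[runif(length(bg)) < 1 / model$phi]
    if (length(sel2) > 0) {
      idx <- arrayInd(sel2, d)
      dy <- sample(-1:1, length(sel2), replace = TRUE)
      dx <- sample(-1:1, length(sel2), replace = TRUE)
      ny <- pmin(pmax(idx[, 1] + dy, 1), d[1])
      nx <- pmin(pmax(idx[, 2] + dx, 1), d[2])
      slot <- sample.int(model$n, length(sel2), replace = TRUE)
      model$samples[cbind(ny, nx, slot)] <- f[cbind(ny, nx)]
    }
  })
  model
}

#' Run ViBe over a sequence
#'
#' Initializes on frame 1 and classifies/updates each subsequent frame.
#'
#' @param seq [video_sequence()].
#' @param cfg [run_config()] supplying `vibe_n`, `vibe_r`, `vibe_nmin`,
#'   `vibe_phi`.
#' @param seed Integer seed.
#' @return List of per-frame logical foreground masks (frame 1 all
#'   background by construction).
#' @export
track_vibe <- function(seq, cfg = run_config(), seed = 1) {
  model <- vibe_init(seq$frames[[1]], cfg$vibe_n, cfg$vibe_r, cfg$vibe_nmin,
                     cfg$vibe_phi, seed)
  n <- length(seq$frames)
  masks <- vector("list", n)
  masks[[1]] <- vibe_classify(model, seq$frames[[1]])
  for (t in 2:n) {
    m <- vibe_classify(model, seq$frames[[t]])
    model <- vibe_update(model, seq$frames[[t]], m,
                         derive_seed(seed, paste0("vibe-", t)))
    masks[[t]] <- m
  }
  masks
}

#' Initialize an EGMM (balloon-estimator) background model
#'
#' @param f First frame.
#' @param buffer History buffer length in frames.
#' @param k Neighbor count covered by the expanding kernel.
#' @param density Density threshold: background iff the balloon-estimated
#'   density at the pixel's current value exceeds it.
#' @return An `egmm_model` with a FIFO history initialized to the first
#'   frame.
#' @export
egmm_init <- function(f, buffer = 50, k = 5, density = 0.005) {
  d <- dim(f)
  hist <- array(f, c(d[1], d[2], 1))
  structure(list(history = hist, buffer = buffer, k = k, density = density,
                 dim = d),
            class = "egmm_model")
}

# Smallest integer radius D such that at least k history samples lie within
# D of each pixel's current value, vectorized over pixels by binary search
# on the 0-255 intensity grid. This is the k-th nearest-neighbor distance
# rounded up to the grid, which is the resolution the 8-bit data carries.
kth_nearest_dist <- function(vals, hist_mat, k) {
  L <- ncol(hist_mat)
  k <- min(k, L)
  d <- abs(hist_mat - vals)         # npix x L
  lo <- rep(0L, length(vals)); hi <- rep(256L, length(vals))
  while (any(lo < hi)) {
    mid <- (lo + hi) %/% 2L
    cnt <- rowSums(d <= mid)
    ok <- cnt >= k
    hi[ok] <- pmin(hi[ok], mid[ok])
    lo[!ok] <- mid[!ok] + 1L
  }
  lo
}

#' EGMM classify-and-update step
#'
#' The balloon estimator expands a uniform kernel at each pixel until it
#' covers the `k` nearest history samples; the density estimate is
#' `k / (2 * L * D_k)` with `L` the history length and `D_k` the covering
#' half-width. The pixel is background iff the density exceeds the model
#' threshold. The history buffer is then updated FIFO with the current
#' frame.
#'
#' @param model An `egmm_model`.
#' @param f Frame.
#' @return List with `mask` (logical foreground) and `model` (updated).
#' @export
egmm_classify_update <- function(model, f) {
  if (!identical(dim(f), model$dim)) stop("frame shape does not match model")
  L <- dim(model$history)[3]
  npix <- prod(model$dim)
  hist_mat <- matrix(model$history, npix, L)
  dk <- kth_nearest_dist(as.vector(f), hist_mat, model$k)
  dens <- min(model$k, L) / (2 * L * pmax(dk, 0.5))
  mask <- matrix(dens < model$density, model$dim[1], model$dim[2])
  if (L < model$buffer) {
    model$history <- array(c(model$history, f), c(model$dim, L + 1))
  } else {
    model$history <- array(c(model$history[, , -1], f), c(model$dim, L))
  }
  list(mask = mask, model = model)
}

#' Run the EGMM detector over a sequence
#'
#' @param seq [video_sequence()].
#' @param cfg [run_config()] supplying `egmm_buffer`, `egmm_k`,
#'   `egmm_density`.
#' @return List of per-frame logical foreground masks.
#' @export
track_egmm <- function(seq, cfg = run_config()) {
  model <- egmm_init(seq$frames[[1]], cfg$egmm_buffer, cfg$egmm_k,
                     cfg$egmm_density)
  n <- length(seq$frames)
  masks <- vector("list", n)
  masks[[1]] <- matrix(FALSE, seq_dim(seq)[1], seq_dim(seq)[2])
  for (t in 2:n) {
    r <- egmm_classify_update(model, seq$frames[[t]])
    masks[[t]] <- r$mask
    model <- r$model
  }
  masks
}
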