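# Independent brute-force oracles and tiny fixtures shared by the tests.
# These deliberately avoid the package's FFT / vectorized code paths.

# circular cross-correlation by direct double loop over shifts
brute_circcorr <- function(x, m) {
  h <- nrow(x); w <- ncol(x)
  out <- matrix(0, h, w)
  for (dy in 0:(h - 1)) {
    for (dx in 0:(w - 1)) {
      xs <- x[(seq_len(h) - 1 + dy) %% h + 1, (seq_len(w) - 1 + dx) %% w + 1]
      out[dy + 1, dx + 1] <- sum(xs * m)
    }
  }
  out
}

# Gaussian kernel correlation by direct evaluation over every cyclic shift
brute_kernel_corr <- function(x, z, sigma) {
  h <- nrow(x); w <- ncol(x)
  out <- matrix(0, h, w)
  n <- h * w
  for (dy in 0:(h - 1)) {
    for (dx in 0:(w - 1)) {
      xs <- x[(seq_len(h) - 1 + dy) %% h + 1, (seq_len(w) - 1 + dx) %% w + 1]
      out[dy + 1, dx + 1] <- exp(-max(0, sum((xs - z)^2)) / (sigma^2 * n))
    }
  }
  out
}

# ViBe foreground decision by per-pixel counting loops
brute_vibe_classify <- function(model, f) {
  d <- dim(f)
  out <- matrix(FALSE, d[1], d[2])
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      cnt <- sum(abs(f[i, j] - model$samples[i, j, ]) < model$r)
      out[i, j] <- cnt < model$n_min
    }
  }
  out
}

# bilateral filter by direct double loop (clamped borders)
brute_bilateral <- function(f, sigma_s, sigma_r) {
  d <- dim(f); r <- max(1L, ceiling(2 * sigma_s))
  out <- f
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      num <- 0; den <- 0
      for (dy in -r:r) {
        for (dx in -r:r) {
          ii <- min(max(i + dy, 1), d[1])
          jj <- min(max(j + dx, 1), d[2])
          w <- exp(-(dx^2 + dy^2) / (2 * sigma_s^2)) *
            exp(-(f[ii, jj] - f[i, j])^2 / (2 * sigma_r^2))
          num <- num + w * f[ii, jj]
          den <- den + w
        }
      }
      out[i, j] <- num / den
    }
  }
  out
}

# flat frame with a filled dark disc
disc_frame <- function(h, w, cx, cy, r, fg = 40, bg = 200) {
  f <- matrix(bg, h, w)
  f[(col(f) - 1 - cx)^2 + (row(f) - 1 - cy)^2 <= r^2] <- fg
  f
}

disc_mask <- function(h, w, cx, cy, r) {
  m <- matrix(FALSE, h, w)
  m[(col(m) - 1 - cx)^2 + (row(m) - 1 - cy)^2 <= r^2] <- TRUE
  m
}

# textured frame pair with a rigid square target translated by (dx, dy)
shifted_pair <- function(h = 60, w = 80, dx = 4, dy = 1, seed = 1) {
  set.seed(seed)
  tex <- matrix(runif(16 * 16) * 100 + 60, 16, 16)
  f1 <- matrix(100, h, w); f1[20:35, 30:45] <- tex
  f2 <- matrix(100, h, w); f2[(20:35) + dy, (30:45) + dx] <- tex
  list(f1 = f1, f2 = f2, box = bbox(29, 19, 17, 17))
}
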