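# Independent brute-force oracles used to check the implementation.
# These deliberately avoid the package's own code paths.

# sort-based median (no stats::median)
brute_median <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

brute_mad <- function(x) brute_median(abs(x - brute_median(x)))

brute_ssmd <- function(pos, neg) {
  (brute_median(pos) - brute_median(neg)) /
    (1.4826 * sqrt(brute_mad(pos)^2 + brute_mad(neg)^2))
}

# explicit grayscale erosion / dilation / opening / top-hat by a disc of
# radius r (pixels outside the image are ignored)
brute_erode <- function(img, r) {
  out <- img
  for (i in seq_len(nrow(img))) for (j in seq_len(ncol(img))) {
    v <- Inf
    for (di in -r:r) for (dj in -r:r) {
      if (di * di + dj * dj > r * r) next
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= nrow(img) && jj >= 1 && jj <= ncol(img))
        v <- min(v, img[ii, jj])
    }
    out[i, j] <- v
  }
  out
}

brute_dilate <- function(img, r) -brute_erode(-img, r)

brute_tophat <- function(img, r) img - brute_dilate(brute_erode(img, r), r)

# flood-fill connected-component labeling
brute_label <- function(mask, connectivity = 8) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  offs <- if (connectivity == 8)
    rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
          c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  else rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  nxt <- 0L
  for (j in seq_len(ncol(mask))) for (i in seq_len(nrow(mask))) {
    if (!mask[i, j] || lab[i, j] != 0) next
    nxt <- nxt + 1L
    queue <- list(c(i, j)); lab[i, j] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(offs))) {
        q <- p + offs[k, ]
        if (q[1] < 1 || q[1] > nrow(mask) || q[2] < 1 || q[2] > ncol(mask))
          next
        if (mask[q[1], q[2]] && lab[q[1], q[2]] == 0) {
          lab[q[1], q[2]] <- nxt
          queue[[length(queue) + 1]] <- q
        }
      }
    }
  }
  lab
}

# a small flat-background image with one centered capsule
capsule_image <- function(shape = c(128, 128), width = 20, length = 60,
                          intensity = 1000, background = 800,
                          theta = 0) {
  cfg <- image_sim_config(shape = shape, n_objects = 0, noise_sd = 0,
                          background_level = background)
  sw <- simulate_well_image(cfg, seed = 1)
  img <- sw$image
  r <- width / 2
  cx <- shape[1] / 2; cy <- shape[2] / 2
  hx <- cos(theta) * (length / 2 - r); hy <- sin(theta) * (length / 2 - r)
  seg_d <- function(px, py) {
    x0 <- cx - hx; y0 <- cy - hy; x1 <- cx + hx; y1 <- cy + hy
    vx <- x1 - x0; vy <- y1 - y0; vv <- vx^2 + vy^2
    t <- if (vv > 0) pmin(pmax(((px - x0) * vx + (py - y0) * vy) / vv, 0), 1)
         else 0
    sqrt((px - (x0 + t * vx))^2 + (py - (y0 + t * vy))^2)
  }
  px <- matrix(seq_len(shape[1]), shape[1], shape[2])
  py <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  mask <- seg_d(px, py) <= r
  img[mask] <- img[mask] + intensity
  list(image = img, mask = mask)
}
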