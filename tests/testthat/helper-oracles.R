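# Independent brute-force oracles used to check the package's fast paths.

# Queue-based flood fill connected-component labeling.
flood_fill_label <- function(mask, connectivity = 8) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nb <- if (connectivity == 8) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  cur <- 0L
  for (j in seq_len(w)) for (i in seq_len(h)) {
    if (!mask[i, j] || lab[i, j] > 0L) next
    cur <- cur + 1L
    queue <- list(c(i, j)); lab[i, j] <- cur
    while (length(queue)) {
      p <- queue[[length(queue)]]; queue[[length(queue)]] <- NULL
      for (k in seq_len(nrow(nb))) {
        r <- p[1] + nb[k, 1]; c <- p[2] + nb[k, 2]
        if (r >= 1 && r <= h && c >= 1 && c <= w &&
            mask[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- cur
          queue[[length(queue) + 1L]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# Canonical renumbering by first occurrence (column-major) so two labelings
# can be compared as partitions.
canonical_labels <- function(lab) {
  ids <- unique(lab[lab > 0L])
  out <- lab
  out[lab > 0L] <- match(lab[lab > 0L], ids)
  out
}

# Direct (double-loop) patch features: clipped windows at scales 1, 2, 4,
# population sd, channels r/g/b plus |dx|+|dy| luminance gradient with
# zeroed trailing edges. Mirrors the documented feature definition without
# using integral images.
naive_patch_features <- function(pixels, centers, patch_px) {
  h <- dim(pixels)[1]; w <- dim(pixels)[2]
  lum <- (pixels[, , 1] + pixels[, , 2] + pixels[, , 3]) / 3
  dx <- matrix(0, h, w); dy <- matrix(0, h, w)
  if (w > 1) dx[, -w] <- abs(lum[, -1] - lum[, -w])
  if (h > 1) dy[-h, ] <- abs(lum[-1, ] - lum[-h, ])
  gm <- dx + dy
  chans <- list(pixels[, , 1], pixels[, , 2], pixels[, , 3], gm)
  pop_sd <- function(v) sqrt(mean(v^2) - mean(v)^2)
  out <- matrix(0, nrow(centers), 24)
  for (i in seq_len(nrow(centers))) {
    col <- 0L
    for (s in c(1L, 2L, 4L)) {
      win <- max(1L, patch_px %/% s)
      p2 <- floor(win / 2)
      r1 <- max(1L, centers[i, 1] + 1L - p2)
      r2 <- min(h, centers[i, 1] + 1L - p2 + win - 1L)
      c1 <- max(1L, centers[i, 2] + 1L - p2)
      c2 <- min(w, centers[i, 2] + 1L - p2 + win - 1L)
      for (ch in chans) {
        v <- ch[r1:r2, c1:c2]
        out[i, col + 1L] <- mean(v)
        out[i, col + 2L] <- max(0, pop_sd(v))
        col <- col + 2L
      }
    }
  }
  out
}

# Direct confusion-matrix recount.
naive_confusion <- function(pred, truth) {
  c(tp = sum(pred == "PFI_S" & truth == "PFI_S"),
    fp = sum(pred == "PFI_S" & truth == "PFI_L"),
    tn = sum(pred == "PFI_L" & truth == "PFI_L"),
    fn = sum(pred == "PFI_L" & truth == "PFI_S"))
}

# Disc mask of given pixel radius centered in an h x w frame.
centered_disc <- function(h, w, r, cy = h / 2, cx = w / 2) {
  outer((seq_len(h) - cy)^2, (seq_len(w) - cx)^2, "+") <= r^2
}
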