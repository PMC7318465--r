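# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: labeling by queue-based flood fill, thresholds by
# direct formula evaluation, p values by explicit enumeration.

# flood-fill connected-component labeling (BFS over an explicit queue)
flood_fill_label <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  k <- 0L
  nb <- if (connectivity == 8)
    rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
          c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  else rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (mask[i, j] && lab[i, j] == 0L) {
      k <- k + 1L
      queue <- list(c(i, j))
      lab[i, j] <- k
      while (length(queue)) {
        cur <- queue[[1]]; queue <- queue[-1]
        for (d in seq_len(nrow(nb))) {
          r <- cur[1] + nb[d, 1]; c2 <- cur[2] + nb[d, 2]
          if (r >= 1 && r <= nr && c2 >= 1 && c2 <= nc &&
              mask[r, c2] && lab[r, c2] == 0L) {
            lab[r, c2] <- k
            queue[[length(queue) + 1L]] <- c(r, c2)
          }
        }
      }
    }
  }
  lab
}

# direct evaluation of the gradient-weighted threshold formula over the whole
# image (the single-leaf RATS threshold), central differences with
# replicated edges
rats_single_leaf_oracle <- function(image, p = 2, noise_sigma = 0, lambda = 3) {
  nr <- nrow(image); nc <- ncol(image)
  g <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    gi <- (image[min(i + 1, nr), j] - image[max(i - 1, 1), j]) / 2
    gj <- (image[i, min(j + 1, nc)] - image[i, max(j - 1, 1)]) / 2
    g[i, j] <- sqrt(gi^2 + gj^2)
  }
  w <- g^p
  w[g <= lambda * noise_sigma] <- 0
  sum(w * image) / sum(w)
}

# exact two-sided Mann-Whitney p by enumeration of every group assignment
mwu_enumeration_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  U_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  lo <- min(U_obs, n1 * n2 - U_obs); hi <- max(U_obs, n1 * n2 - U_obs)
  combs <- utils::combn(N, n1)
  Us <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  min(1, mean(Us <= lo + 1e-9) + mean(Us >= hi - 1e-9))
}

# grey-level erosion/dilation (opening) by direct neighborhood min/max scan
opening_oracle <- function(image, offsets) {
  nr <- nrow(image); nc <- ncol(image)
  scan <- function(img, f, pad) {
    out <- matrix(pad, nr, nc)
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      vals <- c()
      for (d in seq_len(nrow(offsets))) {
        r <- i + offsets[d, 1]; c2 <- j + offsets[d, 2]
        if (r >= 1 && r <= nr && c2 >= 1 && c2 <= nc)
          vals <- c(vals, img[r, c2])
      }
      out[i, j] <- f(vals)
    }
    out
  }
  scan(scan(image, min, Inf), max, -Inf)
}

disc_offsets <- function(radius) {
  o <- expand.grid(r = -radius:radius, c = -radius:radius)
  as.matrix(o[o$r^2 + o$c^2 <= radius^2, ])
}

# a fast small-field spec shared by recovery tests
small_spec <- function(...) {
  args <- utils::modifyList(
    list(image_size_px = 384, n_nuclei = 5, n_nuclei_cv = 0), list(...))
  do.call(synthetic_spec, args)
}
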