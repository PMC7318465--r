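#' Robust Automatic Threshold Selection (RATS)
#'
#' Local thresholding for fluorescence images that weights each pixel's
#' intensity by a power of its gradient magnitude, so the threshold settles
#' at the mid-level of the strongest local edges. The image is decomposed
#' recursively into quadrants (a uniform quadtree, realized per axis as
#' `2^depth` regions with `depth = ceiling(log2(extent / min_leaf_px))`). In
#' each leaf the threshold is
#'
#'   `T = sum(g^p * I) / sum(g^p)`
#'
#' with gradient magnitude `g` from central differences; weights are zeroed
#' where `g <= lambda * noise_sigma` so noise-only gradients do not vote.
#' Leaves whose total weight does not exceed the noise floor
#' `(lambda * noise_sigma)^p` contain no usable edge and inherit the nearest
#' valid ancestor's threshold. Leaf thresholds are then interpolated
#' bilinearly between leaf centers to give a smooth threshold surface, and
#' the mask is `I > T`.
#'
#' @param image numeric 2-D matrix.
#' @param p gradient exponent (> 0); 2 gives squared-gradient weights.
#' @param noise_sigma expected standard deviation of the gradient noise, on
#'   the image's intensity scale.
#' @param lambda noise multiplier for the gradient cutoff.
#' @param min_leaf_px stop subdividing when a region edge is at most this
#'   (>= 2). A value >= the image extent gives a single global threshold.
#' @param max_depth optional cap on the subdivision depth.
#' @param support optional logical matrix: only pixels inside the support
#'   contribute gradient weights (all pixels are still thresholded). Used to
#'   exclude artificial gradients, e.g. at the border of a pre-applied mask.
#' @param min_support a leaf is only considered valid when its total weight
#'   exceeds `min_support * (lambda * noise_sigma)^p`, i.e. it must hold
#'   more edge evidence than a few isolated noise-level gradients.
#' @return logical mask with the interpolated threshold surface attached as
#'   attribute `"threshold"`. A constant image (no gradient support) yields
#'   an empty mask with a warning.
#' @export
rats_threshold <- function(image, p = 2, noise_sigma = 0.02, lambda = 3,
                           min_leaf_px = 16, max_depth = NULL,
                           support = NULL, min_support = 8) {
  if (!is_matrix2d(image)) stop_input("image must be a numeric matrix")
  check_finite_image(image)
  stopifnot(p > 0, noise_sigma >= 0, lambda >= 0)
  if (min_leaf_px < 2) stop_input("min_leaf_px must be >= 2")
  nr <- nrow(image); nc <- ncol(image)

  # gradient magnitude, central differences with replicated edges
  gr <- (image[c(2:nr, nr), , drop = FALSE] -
           image[c(1, 1:(nr - 1)), , drop = FALSE]) / 2
  gc <- (image[, c(2:nc, nc), drop = FALSE] -
           image[, c(1, 1:(nc - 1)), drop = FALSE]) / 2
  g <- sqrt(gr^2 + gc^2)
  w <- g^p
  w[g <= lambda * noise_sigma] <- 0
  if (!is.null(support)) {
    if (!all(dim(support) == dim(image)))
      stop_input("support and image dimensions differ")
    w[!support] <- 0
  }
  floor_w <- min_support * (lambda * noise_sigma)^p

  depth_axis <- function(n) max(0L, as.integer(ceiling(log2(n / min_leaf_px))))
  dr <- depth_axis(nr); dc <- depth_axis(nc)
  if (!is.null(max_depth)) {
    dr <- min(dr, as.integer(max_depth)); dc <- min(dc, as.integer(max_depth))
  }
  ntr <- 2L^dr; ntc <- 2L^dc
  idx_r <- ceiling(seq_len(nr) * ntr / nr)
  idx_c <- ceiling(seq_len(nc) * ntc / nc)

  agg <- function(m, ir, ic) t(rowsum(t(rowsum(m, ir)), ic))
  sw <- agg(w, idx_r, idx_c)
  swi <- agg(w * image, idx_r, idx_c)

  # climb to the nearest valid ancestor where a leaf lacks edge support
  Tleaf <- matrix(NA_real_, ntr, ntc)
  lev_sw <- sw; lev_swi <- swi
  pr <- seq_len(ntr); pc <- seq_len(ntc) # ancestor tile index of each leaf
  repeat {
    vals <- lev_swi / lev_sw
    valid <- lev_sw > floor_w
    fill <- is.na(Tleaf) & valid[cbind(pr[row(Tleaf)], pc[col(Tleaf)])]
    Tleaf[fill] <- vals[cbind(pr[row(Tleaf)], pc[col(Tleaf)])][fill]
    if (!anyNA(Tleaf) || (nrow(lev_sw) == 1L && ncol(lev_sw) == 1L)) break
    cr <- ceiling(seq_len(nrow(lev_sw)) / 2)
    cc2 <- ceiling(seq_len(ncol(lev_sw)) / 2)
    lev_sw <- agg(lev_sw, cr, cc2)
    lev_swi <- agg(lev_swi, cr, cc2)
    pr <- ceiling(pr / 2); pc <- ceiling(pc / 2)
  }
  if (anyNA(Tleaf)) {
    warning("rats_threshold: no gradient support above the noise floor; ",
            "returning empty mask")
    out <- matrix(FALSE, nr, nc)
    attr(out, "threshold") <- matrix(Inf, nr, nc)
    return(out)
  }

  cen_r <- as.numeric(tapply(seq_len(nr), idx_r, mean))
  cen_c <- as.numeric(tapply(seq_len(nc), idx_c, mean))
  lerp <- function(centers, xout) {
    k <- length(centers)
    if (k == 1L) return(list(i = rep(1L, length(xout)), f = rep(0, length(xout))))
    j <- pmin(pmax(findInterval(xout, centers), 1L), k - 1L)
    f <- (xout - centers[j]) / (centers[j + 1L] - centers[j])
    list(i = j, f = pmin(pmax(f, 0), 1)) # clamp = constant extrapolation
  }
  lc <- lerp(cen_c, seq_len(nc))
  m1 <- Tleaf[, lc$i, drop = FALSE] * rep(1 - lc$f, each = ntr) +
    Tleaf[, pmin(lc$i + 1L, ntc), drop = FALSE] * rep(lc$f, each = ntr)
  lr <- lerp(cen_r, seq_len(nr))
  Tfull <- m1[lr$i, , drop = FALSE] * (1 - lr$f) +
    m1[pmin(lr$i + 1L, ntr), , drop = FALSE] * lr$f

  out <- image > Tfull
  attr(out, "threshold") <- Tfull
  out
}
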