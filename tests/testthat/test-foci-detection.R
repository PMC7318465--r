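options(nsbquant.verbose = FALSE)

test_that("RATS on a constant image warns and returns an empty mask", {
  expect_warning(m <- rats_threshold(matrix(4, 20, 20)), "no gradient support")
  expect_false(any(m))
})

test_that("RATS threshold of a half-plane step is the mid level", {
  img <- cbind(matrix(0, 32, 16), matrix(100, 32, 16))
  m <- rats_threshold(img, p = 2, noise_sigma = 0, min_leaf_px = 64)
  # symmetric gradient weights about the edge put the threshold at 50
  expect_equal(unique(as.vector(attr(m, "threshold"))), 50)
  expect_equal(m, img > 50, ignore_attr = TRUE)
})

test_that("single-leaf RATS equals the direct weighted-mean formula", {
  set.seed(53)
  for (i in 1:6) {
    img <- matrix(runif(24 * 24), 24, 24)
    sig <- sample(c(0, 0.05), 1)
    m <- rats_threshold(img, p = 2, noise_sigma = sig, lambda = 3,
                        min_leaf_px = 32)
    oracle <- rats_single_leaf_oracle(img, p = 2, noise_sigma = sig, lambda = 3)
    got <- unique(as.vector(attr(m, "threshold")))
    expect_equal(length(got), 1L)
    expect_lt(abs(got - oracle) / oracle, 1e-9)
    expect_equal(m, matrix(img > oracle, 24, 24), ignore_attr = TRUE)
  }
  # other gradient exponents
  img <- matrix(runif(400, 0, 2), 20, 20)
  for (p in c(1, 3)) {
    m <- rats_threshold(img, p = p, noise_sigma = 0, min_leaf_px = 32)
    oracle <- rats_single_leaf_oracle(img, p = p, noise_sigma = 0)
    expect_lt(abs(unique(as.vector(attr(m, "threshold"))) - oracle) / oracle,
              1e-9)
  }
})

test_that("multi-leaf RATS adapts the threshold between image halves", {
  # left half: levels 0/40; right half: levels 50/100 -- a global threshold
  # cannot separate both, a local one can
  set.seed(3)
  left <- matrix(0, 64, 32); left[20:30, 10:20] <- 40
  right <- matrix(50, 64, 32); right[35:45, 10:20] <- 100
  img <- cbind(left, right)
  m <- rats_threshold(img, p = 2, noise_sigma = 0, min_leaf_px = 16)
  expect_true(all(m[20:30, 10:20]))      # left blob above local threshold
  expect_true(all(m[35:45, 42:52]))      # right blob above local threshold
  expect_false(any(m[1:10, 1:30]))       # left background below
  # background adjacent to the right blob sits below its local threshold
  # (far-field regions inherit ancestor thresholds and are not asserted)
  expect_false(any(m[33:47, 54:58]))
})

make_nucleus_scene <- function() {
  # three disc nuclei; labels follow column-major first occurrence
  m <- matrix(FALSE, 150, 150)
  centers <- list(c(30, 30), c(30, 110), c(110, 75))
  for (cen in centers)
    m[outer(seq_len(150), seq_len(150), function(i, j)
      (i - cen[1])^2 + (j - cen[2])^2 <= 20^2)] <- TRUE
  label_components(m, field_id = "scene")
}

test_that("foci are detected inside the right nucleus and size-gated", {
  nuclei <- make_nucleus_scene()
  cfg <- pipeline_config(focus_area_range_um2 = c(0.2, 3.0))
  blank <- matrix(0, 150, 150)
  expect_equal(nrow(detect_foci(blank, nuclei, cfg)), 0)
  # one Gaussian spot inside the nucleus at (110, 75)
  spot <- blank + 0.05 * (nuclei$labels > 0)
  d2 <- outer((seq_len(150) - 110)^2, (seq_len(150) - 75)^2, `+`)
  spot <- spot + 0.6 * exp(-d2 / (2 * 3^2))
  foci <- detect_foci(spot, nuclei, cfg, pixel_size_um = 0.102)
  expect_equal(nrow(foci), 1)
  expect_equal(foci$nucleus_id, nuclei$labels[110, 75])
  expect_equal(foci$centroid_row, 110, tolerance = 1)
  expect_equal(foci$centroid_col, 75, tolerance = 1)
  expect_true(in_interval <- foci$area_um2 >= 0.2 && foci$area_um2 <= 3)
  # a blob far larger than the upper gate is discarded (area known: the
  # bright plateau radius 15 px -> ~7.4 um^2 > 3 um^2)
  big <- blank
  big[outer((seq_len(150) - 30)^2, (seq_len(150) - 30)^2, `+`) <= 15^2] <- 0.8
  expect_equal(nrow(detect_foci(big, nuclei, cfg, 0.102)), 0)
})

test_that("focus records never leave their nucleus and counts are conserved", {
  set.seed(61)
  for (i in 1:6) {
    gen <- generate_field(small_spec(), seed = NULL)
    res <- quantify_field(gen$field)
    # conservation: per-nucleus tallies sum to the number of focus records
    expect_equal(sum(res$nuclei$focus_count), nrow(res$foci))
    # mask restriction: every focus centroid lies on its nucleus' pixels
    L <- res$label_map$labels
    if (nrow(res$foci)) {
      at <- L[cbind(round(res$foci$centroid_row), round(res$foci$centroid_col))]
      expect_equal(at, res$foci$nucleus_id)
    }
  }
})

test_that("foci_per_nucleus tallies counts and flags dangling ids", {
  nuclei <- data.frame(field_id = "f", nucleus_id = 1:3,
                       focus_count = c(9L, 9L, 9L))
  foci0 <- data.frame(nucleus_id = integer(0))
  expect_equal(foci_per_nucleus(foci0, nuclei)$focus_count, c(0, 0, 0))
  foci <- data.frame(nucleus_id = c(1, 1, 1, 2))
  expect_equal(foci_per_nucleus(foci, nuclei)$focus_count, c(3, 1, 0))
  bad <- data.frame(nucleus_id = 7)
  expect_error(foci_per_nucleus(bad, nuclei), "internal error")
})

test_that("per-nucleus focus counts are recovered exactly at high SNR", {
  # 40 small fields x 5 nuclei = 200 nuclei with known counts; amplitude to
  # noise ratio >> 5 at spec defaults
  set.seed(71)
  match_n <- 0L; total_n <- 0L
  for (i in 1:40) {
    gen <- generate_field(small_spec(), seed = NULL)
    res <- quantify_field(gen$field)
    tn <- gen$truth$nuclei
    an <- res$nuclei
    for (j in seq_len(nrow(tn))) {
      d <- sqrt((an$centroid_row - tn$center_row[j])^2 +
                  (an$centroid_col - tn$center_col[j])^2)
      k <- which.min(d)
      total_n <- total_n + 1L
      if (d[k] < 10 && an$focus_count[k] == tn$focus_count[j])
        match_n <- match_n + 1L
    }
  }
  expect_gte(total_n, 190L)
  expect_gte(match_n / total_n, 0.95)
})
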