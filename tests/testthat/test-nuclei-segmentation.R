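options(nsbquant.verbose = FALSE)

test_that("fixed-fraction thresholding matches its definition", {
  # two-level image at fraction 0.5 selects exactly the high level
  img <- matrix(c(0, 100, 100, 0, 0, 100), 2, 3)
  expect_equal(threshold_fixed(img, 0.5), img == 100)
  # everything below the cutoff: empty mask
  low <- matrix(c(0, 1, 2, 3), 2, 2)
  expect_equal(threshold_fixed(low, 0.9), matrix(c(F, F, F, T), 2, 2))
  # random image equals brute-force per-pixel comparison
  set.seed(31)
  r <- matrix(runif(400, 10, 50), 20, 20)
  fr <- 0.37
  cut <- min(r) + fr * (max(r) - min(r))
  oracle <- matrix(vapply(seq_along(r), function(i) r[i] >= cut, logical(1)),
                   20, 20)
  expect_equal(threshold_fixed(r, fr), oracle)
  # constant image: warning and empty mask
  expect_warning(m <- threshold_fixed(matrix(5, 3, 3), 0.5), "constant")
  expect_false(any(m))
})

test_that("component labeling respects connectivity and matches flood fill", {
  # empty mask
  expect_equal(max(label_components(matrix(FALSE, 4, 4))$labels), 0)
  # two diagonally touching pixels
  diag2 <- matrix(FALSE, 4, 4); diag2[1, 1] <- diag2[2, 2] <- TRUE
  expect_equal(max(label_components(diag2, 8)$labels), 1)
  expect_equal(max(label_components(diag2, 4)$labels), 2)
  # random blob images against the flood-fill oracle, both connectivities
  set.seed(17)
  for (i in 1:8) {
    m <- matrix(runif(30 * 30) < 0.4, 30, 30)
    for (conn in c(4, 8)) {
      lab <- label_components(m, conn)$labels
      oracle <- flood_fill_label(m, conn)
      expect_equal(max(lab), max(oracle))
      # identical partitions, not just counts
      expect_equal(lab[lab > 0] + 0, oracle[oracle > 0] + 0)
      # labels consecutive 1..K and all foreground labeled
      expect_setequal(unique(lab[lab > 0]), seq_len(max(lab)))
      expect_equal(lab > 0, m)
    }
  }
})

disc_mask <- function(n, r, cx = n / 2, cy = n / 2) {
  outer(seq_len(n), seq_len(n),
        function(i, j) (i - cx)^2 + (j - cy)^2 <= r^2)
}

test_that("shape features: Crofton perimeter is accurate for discs, harsh on lines", {
  m <- disc_mask(101, 30)
  lm <- label_components(m)
  f <- shape_features(lm, pixel_size_um = 1)
  expect_equal(f$area_px, sum(m))
  expect_equal(f$perimeter_px, 2 * pi * 30, tolerance = 0.02)
  expect_gt(f$circularity, 0.97)
  expect_lte(f$circularity, 1)
  # 1-px line: circularity far below any disc-like gate
  line <- matrix(FALSE, 40, 40); line[20, 5:35] <- TRUE
  fl <- shape_features(label_components(line), 1)
  expect_lt(fl$circularity, 0.3)
  # centroid of a centered disc
  expect_equal(f$centroid_row, 101 / 2, tolerance = 0.6)
})

test_that("filter_nuclei gates by size, shape and border and relabels 1..K", {
  # two discs, one below the area gate (areas known analytically)
  m <- matrix(FALSE, 120, 120)
  m[disc_mask(120, 20, 40, 40)] <- TRUE     # area ~1257 px
  m[disc_mask(120, 5, 90, 90)] <- TRUE      # area ~79 px
  cfg <- pipeline_config(nucleus_area_range_um2 = c(500, 2000),
                         nucleus_circularity_range = c(0.3, 1))
  res <- filter_nuclei(label_components(m), m + 0, cfg, pixel_size_um = 1)
  expect_equal(nrow(res$records), 1)
  expect_equal(res$records$area_um2, sum(disc_mask(120, 20, 40, 40)),
               tolerance = 1e-12)
  expect_equal(sort(unique(res$label_map$labels[res$label_map$labels > 0])), 1L)
  # a thin line is removed by the circularity gate even when its area passes
  line <- matrix(FALSE, 120, 120); line[75, 10:110] <- TRUE
  m2 <- m | line
  cfg2 <- pipeline_config(nucleus_area_range_um2 = c(50, 2000),
                          nucleus_circularity_range = c(0.3, 1))
  res2 <- filter_nuclei(label_components(m2), m2 + 0, cfg2, pixel_size_um = 1)
  expect_equal(nrow(res2$records), 2) # both discs, no line
  # border-touching component removed
  mb <- m; mb[disc_mask(120, 10, 3, 60)] <- TRUE
  res3 <- filter_nuclei(label_components(mb), mb + 0, cfg2, pixel_size_um = 1)
  expect_true(all(!res3$records$touches_border))
  # empty label map: empty record list
  res0 <- filter_nuclei(label_components(matrix(FALSE, 10, 10)),
                        matrix(0, 10, 10), cfg)
  expect_equal(nrow(res0$records), 0)
  expect_equal(count_cells(res0$records), 0)
})

test_that("area filtering is monotone: shrinking the interval never adds survivors", {
  set.seed(41)
  m <- matrix(FALSE, 150, 150)
  for (i in 1:6)
    m[disc_mask(150, runif(1, 4, 18), runif(1, 30, 120), runif(1, 30, 120))] <- TRUE
  lm <- label_components(m)
  wide <- c(10, 1500)
  prev <- Inf
  for (shrink in c(0, 100, 400, 700)) {
    rng <- c(wide[1] + shrink / 4, wide[2] - shrink)
    cfg <- pipeline_config(nucleus_area_range_um2 = rng,
                           nucleus_circularity_range = c(0, 1),
                           exclude_border_nuclei = FALSE)
    n <- nrow(filter_nuclei(lm, m + 0, cfg, pixel_size_um = 1)$records)
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("every foreground pixel of a filtered map belongs to exactly one nucleus", {
  gen <- generate_field(small_spec(), seed = 9)
  cfg <- pipeline_config()
  mask <- threshold_fixed(gen$field$channels$dapi, cfg$dapi_threshold)
  seg <- filter_nuclei(label_components(mask), gen$field$channels$dapi, cfg,
                       0.102)
  L <- seg$label_map$labels
  K <- max(L)
  expect_setequal(unique(L[L > 0]), seq_len(K))
  expect_equal(nrow(seg$records), K)
})

test_that("cell counts on noise-free synthetic fields equal ground truth", {
  # noise-free, blur-free renders must count exactly; many random layouts
  spec <- small_spec(read_noise_sd = 0, blur_sd_px = 0, dapi_sd = 0)
  set.seed(77)
  for (i in 1:100) {
    n <- sample(0:7, 1)
    sp <- small_spec(read_noise_sd = 0, blur_sd_px = 0, dapi_sd = 0,
                     n_nuclei = n)
    gen <- generate_field(sp, seed = NULL)
    if (gen$truth$cell_count == 0) {
      expect_warning(res <- quantify_field(gen$field), "constant")
    } else {
      res <- quantify_field(gen$field)
    }
    expect_equal(res$cell_count, gen$truth$cell_count)
  }
})

test_that("default-noise synthetic fields still count exactly", {
  set.seed(99)
  for (i in 1:10) {
    gen <- generate_field(small_spec(), seed = NULL)
    res <- quantify_field(gen$field)
    expect_equal(res$cell_count, gen$truth$cell_count)
  }
})
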