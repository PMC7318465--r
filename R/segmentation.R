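#' Fixed-fraction intensity threshold
#'
#' Binarizes an image at a fixed fraction of its own dynamic range: a pixel
#' is foreground iff `I >= min + fraction * (max - min)`. Expressing the
#' cutoff relative to the per-image range makes uint8, uint16 and float
#' inputs behave identically.
#'
#' @param image numeric 2-D matrix.
#' @param threshold_fraction fraction of the dynamic range in `(0, 1)`.
#' @return logical matrix of the same size. A constant image yields an empty
#'   mask with a warning (its dynamic range is zero).
#' @export
threshold_fixed <- function(image, threshold_fraction = 0.25) {
  if (!is_matrix2d(image)) stop_input("image must be a numeric matrix")
  check_finite_image(image)
  if (!(threshold_fraction > 0 && threshold_fraction < 1))
    stop_input("threshold_fraction must be in (0, 1)")
  rng <- range(image)
  if (rng[1] == rng[2]) {
    warning("threshold_fixed: constant image, returning empty mask")
    return(matrix(FALSE, nrow(image), ncol(image)))
  }
  image >= rng[1] + threshold_fraction * (rng[2] - rng[1])
}

#' Label connected foreground components
#'
#' Finds maximal 4- or 8-connected components of a binary mask and labels
#' them 1..K in order of first appearance (column-major scan). Built on an
#' igraph pixel-adjacency graph so both connectivities are exact.
#'
#' @param mask logical (or 0/1 numeric) matrix.
#' @param connectivity 4 (edge neighbors) or 8 (edge + diagonal neighbors).
#' @param field_id carried into the result for bookkeeping.
#' @return a `NucleusLabelMap`: list with integer matrix `labels`
#'   (0 = background), `field_id`, and `connectivity`.
#' @export
label_components <- function(mask, connectivity = 8, field_id = "field") {
  if (is.numeric(mask)) mask <- mask != 0
  if (!is.matrix(mask) || !is.logical(mask))
    stop_input("mask must be a logical matrix")
  if (!connectivity %in% c(4, 8)) stop_input("connectivity must be 4 or 8")
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  fg <- which(mask)
  if (length(fg)) {
    pos <- integer(nr * nc)
    pos[fg] <- seq_along(fg)
    rr <- ((fg - 1L) %% nr) + 1L
    cc <- ((fg - 1L) %/% nr) + 1L
    shift_edges <- function(dr, dc) {
      ok <- rr + dr >= 1L & rr + dr <= nr & cc + dc <= nc
      from <- fg[ok]
      to <- from + dr + dc * nr
      keep <- mask[to]
      cbind(pos[from[keep]], pos[to[keep]])
    }
    shifts <- list(c(0L, 1L), c(1L, 0L))
    if (connectivity == 8) shifts <- c(shifts, list(c(1L, 1L), c(-1L, 1L)))
    edges <- do.call(rbind, lapply(shifts, function(s) shift_edges(s[1], s[2])))
    g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
    if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
    memb <- igraph::components(g)$membership
    labels[fg] <- match(memb, unique(memb))
  }
  structure(list(labels = labels, field_id = field_id,
                 connectivity = as.integer(connectivity)),
            class = "NucleusLabelMap")
}

#' @export
print.NucleusLabelMap <- function(x, ...) {
  cat(sprintf("NucleusLabelMap '%s': %d objects, %d x %d px, %d-connected\n",
              x$field_id, max(x$labels), nrow(x$labels), ncol(x$labels),
              x$connectivity))
  invisible(x)
}

# Per-label boundary crossing counts along one direction, attributed to the
# nonzero label(s) on either side of the crossing. The matrix is zero-padded
# so image-border boundaries count.
crossings_dir <- function(labels, K, dr, dc) {
  nr <- nrow(labels); nc <- ncol(labels)
  pad <- matrix(0L, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- labels
  ar <- 1:(nrow(pad) - abs(dr)); ac <- 1:(ncol(pad) - abs(dc))
  br <- ar + abs(dr); bc <- ac + abs(dc)
  if (dr * dc < 0) { # anti-diagonal: shift rows down, cols up
    a <- pad[br, ac, drop = FALSE]
    b <- pad[ar, bc, drop = FALSE]
  } else {
    a <- pad[ar, ac, drop = FALSE]
    b <- pad[br, bc, drop = FALSE]
  }
  diffm <- a != b
  av <- a[diffm]; bv <- b[diffm]
  tabulate(av[av > 0L], K) + tabulate(bv[bv > 0L], K)
}

#' Geometric features of labeled objects
#'
#' Computes per-label pixel area, centroid, border contact, and a perimeter
#' estimate by the 4-direction Cauchy-Crofton formula (counting boundary
#' crossings along rows, columns and both diagonals). The Crofton estimator
#' is unbiased for discs, so `circularity = 4*pi*A/P^2` is ~1 for a disc and
#' stays within `[0, 1]` up to discretization error.
#'
#' @param label_map a `NucleusLabelMap`.
#' @param pixel_size_um pixel calibration used for `area_um2`.
#' @return data frame with one row per label: `nucleus_id`, `area_px`,
#'   `area_um2`, `centroid_row`, `centroid_col`, `perimeter_px`,
#'   `circularity`, `touches_border`.
#' @export
shape_features <- function(label_map, pixel_size_um = 0.102) {
  stopifnot(inherits(label_map, "NucleusLabelMap"))
  L <- label_map$labels
  K <- max(L)
  if (K == 0L)
    return(data.frame(nucleus_id = integer(0), area_px = integer(0),
                      area_um2 = numeric(0), centroid_row = numeric(0),
                      centroid_col = numeric(0), perimeter_px = numeric(0),
                      circularity = numeric(0), touches_border = logical(0)))
  nr <- nrow(L); nc <- ncol(L)
  fg <- which(L > 0L)
  lab <- L[fg]
  rr <- ((fg - 1L) %% nr) + 1L
  cc <- ((fg - 1L) %/% nr) + 1L
  area <- tabulate(lab, K)
  cen_r <- rowsum(as.numeric(rr), lab)[, 1] / area
  cen_c <- rowsum(as.numeric(cc), lab)[, 1] / area
  ch <- crossings_dir(L, K, 0L, 1L)
  cv <- crossings_dir(L, K, 1L, 0L)
  cd1 <- crossings_dir(L, K, 1L, 1L)
  cd2 <- crossings_dir(L, K, 1L, -1L)
  perim <- pi / 8 * (ch + cv + (cd1 + cd2) / sqrt(2))
  border <- unique(c(L[1, ], L[nr, ], L[, 1], L[, nc]))
  data.frame(
    nucleus_id = seq_len(K),
    area_px = area,
    area_um2 = area * pixel_size_um^2,
    centroid_row = cen_r,
    centroid_col = cen_c,
    perimeter_px = perim,
    # discretization can push the estimate past the theoretical maximum of a
    # disc; cap at 1 so the [0, 1] gate semantics hold
    circularity = pmin(4 * pi * area / perim^2, 1),
    touches_border = seq_len(K) %in% border)
}

#' Gate segmented nuclei by size, shape and border contact
#'
#' Removes labeled components whose area falls outside
#' `nucleus_area_range_um2`, whose circularity falls outside
#' `nucleus_circularity_range`, or which touch the field border (when
#' `exclude_border_nuclei`), then relabels the survivors 1..K'. This is the
#' false-positive filter applied after DAPI thresholding.
#'
#' @param label_map a `NucleusLabelMap` from [label_components()].
#' @param dapi the nuclear-channel image the map was derived from (used for
#'   per-nucleus DAPI intensity in the records).
#' @param cfg a [pipeline_config()].
#' @param pixel_size_um pixel calibration.
#' @return list with the relabeled `label_map` and `records`, a data frame of
#'   nucleus records (`focus_count` initialized to 0).
#' @export
filter_nuclei <- function(label_map, dapi, cfg = pipeline_config(),
                          pixel_size_um = 0.102) {
  stopifnot(inherits(label_map, "NucleusLabelMap"))
  if (!all(dim(dapi) == dim(label_map$labels)))
    stop_input("dapi and label map dimensions differ")
  feats <- shape_features(label_map, pixel_size_um)
  keep <- in_interval(feats$area_um2, cfg$nucleus_area_range_um2) &
    in_interval(feats$circularity, cfg$nucleus_circularity_range)
  if (cfg$exclude_border_nuclei) keep <- keep & !feats$touches_border
  old_ids <- feats$nucleus_id[keep]
  lookup <- integer(max(label_map$labels, 1L))
  lookup[old_ids] <- seq_along(old_ids)
  L <- label_map$labels
  pos <- L > 0L
  L[pos] <- lookup[L[pos]]
  new_map <- structure(list(labels = L, field_id = label_map$field_id,
                            connectivity = label_map$connectivity),
                       class = "NucleusLabelMap")
  kept <- feats[keep, , drop = FALSE]
  records <- data.frame(
    field_id = rep(label_map$field_id, nrow(kept)),
    nucleus_id = seq_len(nrow(kept)),
    centroid_row = kept$centroid_row,
    centroid_col = kept$centroid_col,
    area_um2 = kept$area_um2,
    circularity = kept$circularity,
    touches_border = kept$touches_border,
    focus_count = integer(nrow(kept)))
  if (nrow(kept)) {
    fg <- which(L > 0L)
    lab <- L[fg]
    npx <- tabulate(lab, nrow(kept))
    sums <- rowsum(as.numeric(dapi[fg]), lab)[, 1]
    records$dapi_mean_intensity <- sums / npx
    records$dapi_integrated_intensity <- sums
  } else {
    records$dapi_mean_intensity <- numeric(0)
    records$dapi_integrated_intensity <- numeric(0)
  }
  list(label_map = new_map, records = records)
}

#' Count cells in a field
#'
#' The cell count of a field is the number of nucleus records that survived
#' filtering.
#'
#' @param records nucleus record data frame from [filter_nuclei()].
#' @return non-negative integer.
#' @export
count_cells <- function(records) {
  stopifnot(is.data.frame(records))
  nrow(records)
}
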