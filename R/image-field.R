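#' Construct a calibrated multi-channel image field
#'
#' An `ImageField` bundles the channels of one microscope field (2-D matrices,
#' or 3-D arrays `(row, col, slice)` for Z-stacks) with its pixel calibration
#' and subject/group metadata. Intensities are kept on their native scale —
#' for TIFF-backed fields this is the `[0, 1]` scale used by the `tiff`
#' package — and are never rescaled before Z-scoring.
#'
#' @param channels named list of numeric 2-D matrices or 3-D arrays, all with
#'   identical dimensions; values must be finite and non-negative.
#' @param pixel_size_um edge length of one pixel in micrometers. The default
#'   0.102 is a typical confocal X/Y sampling interval at high NA.
#' @param field_id,subject_id,group_label character metadata carried through
#'   to all result tables.
#' @return an object of class `ImageField`.
#' @export
image_field <- function(channels, pixel_size_um = 0.102,
                        field_id = "field", subject_id = "subject",
                        group_label = "group") {
  if (!is.list(channels) || length(channels) == 0L || is.null(names(channels)) ||
      any(!nzchar(names(channels))))
    stop_input("channels must be a non-empty named list")
  dims <- lapply(channels, dim)
  if (any(vapply(dims, is.null, logical(1))))
    stop_input("each channel must be a matrix or array")
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L)
    stop_input("all channels must share identical dimensions")
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (!is.numeric(ch)) stop_input("channel '", nm, "' is not numeric")
    if (!all(is.finite(ch))) stop_input("channel '", nm, "' has non-finite pixels")
    if (any(ch < 0)) stop_input("channel '", nm, "' has negative intensities")
  }
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop_input("pixel_size_um must be a single positive number")
  structure(
    list(field_id = as.character(field_id),
         subject_id = as.character(subject_id),
         group_label = as.character(group_label),
         channels = channels,
         pixel_size_um = pixel_size_um),
    class = "ImageField")
}

#' @export
print.ImageField <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("ImageField '%s' (subject %s, group %s)\n",
              x$field_id, x$subject_id, x$group_label))
  cat(sprintf("  channels: %s\n", paste(names(x$channels), collapse = ", ")))
  cat(sprintf("  size: %s px, %.4g um/px%s\n",
              paste(d[1:2], collapse = " x "), x$pixel_size_um,
              if (length(d) == 3L) sprintf(", %d slices", d[3]) else ""))
  invisible(x)
}

is_stack <- function(field) length(dim(field$channels[[1]])) == 3L

#' Read a multi-channel TIFF into an ImageField
#'
#' Pages are assumed channel-interleaved (channel fastest): with C channels,
#' page `c + C*(z-1)` is slice `z` of channel `c`. A page count equal to the
#' channel count yields 2-D channels; larger multiples yield Z-stacks that
#' keep their slice axis until [project_stack()].
#'
#' @param path a single- or multi-page TIFF file.
#' @param channel_names channel names, in page order.
#' @param pixel_size_um pixel calibration (micrometers per pixel edge).
#' @param field_id,subject_id,group_label metadata; `field_id` defaults to the
#'   file name without extension.
#' @return an [image_field()].
#' @export
read_field <- function(path, channel_names, pixel_size_um = 0.102,
                       field_id = NULL, subject_id = "subject",
                       group_label = "group") {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop_input("cannot read TIFF file: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) stop_input("unreadable TIFF '", path, "': ",
                                                   conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  nc <- length(channel_names)
  if (nc < 1L) stop_input("channel_names must be non-empty")
  if (length(pages) %% nc != 0L)
    stop_input("page count (", length(pages), ") of '", path,
               "' is not divisible by channel count (", nc, ")")
  nz <- length(pages) %/% nc
  channels <- lapply(seq_len(nc), function(ci) {
    slices <- pages[seq(ci, by = nc, length.out = nz)]
    if (nz == 1L) slices[[1]]
    else array(unlist(slices, use.names = FALSE),
               dim = c(dim(slices[[1]]), nz))
  })
  names(channels) <- channel_names
  if (is.null(field_id))
    field_id <- tools::file_path_sans_ext(basename(path))
  image_field(channels, pixel_size_um = pixel_size_um, field_id = field_id,
              subject_id = subject_id, group_label = group_label)
}

#' Write an ImageField as a multi-page 16-bit TIFF
#'
#' Pages are written channel-interleaved, matching [read_field()]. Values are
#' stored as 16-bit samples on the `[0, 1]` scale; intensities already on the
#' 16-bit grid (multiples of 1/65535, as produced by the synthetic generator)
#' round-trip pixel-exactly.
#'
#' @param field an [image_field()] with intensities in `[0, 1]`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "ImageField"))
  if (max(vapply(field$channels, max, numeric(1))) > 1)
    stop_input("write_field expects intensities in [0, 1]")
  d <- dim(field$channels[[1]])
  nz <- if (length(d) == 3L) d[3] else 1L
  pages <- vector("list", length(field$channels) * nz)
  k <- 1L
  for (z in seq_len(nz)) {
    for (ch in field$channels) {
      pages[[k]] <- if (nz == 1L) ch else ch[, , z]
      k <- k + 1L
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Collapse a Z-stack field to a single analysis plane
#'
#' Confocal fields are acquired as Z-stacks but the nuclear masks used
#' downstream are planar, so each channel is collapsed along the slice axis by
#' per-pixel maximum (default; preserves puncta) or mean. Metadata and
#' calibration are preserved. An already-planar field is returned unchanged
#' with a notice.
#'
#' @param field an [image_field()].
#' @param method `"max"` or `"mean"`.
#' @return a 2-D [image_field()].
#' @export
project_stack <- function(field, method = c("max", "mean")) {
  stopifnot(inherits(field, "ImageField"))
  method <- match.arg(method)
  if (!is_stack(field)) {
    msg("project_stack: field '", field$field_id, "' is already 2-D; unchanged")
    return(field)
  }
  field$channels <- lapply(field$channels, function(ch) {
    nz <- dim(ch)[3]
    slices <- lapply(seq_len(nz), function(z) ch[, , z])
    if (method == "max") Reduce(pmax, slices)
    else Reduce(`+`, slices) / nz
  })
  field
}

#' Rolling-ball style background subtraction
#'
#' Estimates the smooth background of a single channel by grayscale
#' morphological opening with a disc structuring element of the given radius
#' and subtracts it, clipping at zero. The disc radius should exceed the
#' radius of the structures to preserve (foci, nuclei).
#'
#' @param image numeric 2-D matrix with finite pixels.
#' @param radius_px structuring-element radius in pixels (>= 1).
#' @return matrix of the same size, `0 <= result <= image` pixelwise.
#' @export
subtract_background <- function(image, radius_px = 50) {
  if (!is_matrix2d(image)) stop_input("image must be a numeric matrix")
  check_finite_image(image)
  if (any(image < 0)) stop_input("image must be non-negative")
  stopifnot(radius_px >= 1)
  side <- 2L * as.integer(radius_px) + 1L
  # EBImage morphology clips to [0, 1]; work on a rescaled copy
  sc <- max(image, 1)
  bg <- EBImage::opening(image / sc, EBImage::makeBrush(side, shape = "disc"))
  out <- pmax(image - as.matrix(bg) * sc, 0)
  dim(out) <- dim(image)
  out
}
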