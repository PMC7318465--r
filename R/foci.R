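#' Detect size-gated intranuclear foci
#'
#' Restricts the inclusion channel to the segmented nuclear mask, thresholds
#' it with [rats_threshold()], labels the resulting particles, and keeps
#' those whose area lies inside `focus_area_range_um2` — the published size
#' range of nuclear stress bodies. Each surviving particle is assigned to the
#' nucleus owning the majority of its pixels (ties break to the lower
#' nucleus id; particles never extend beyond the nuclear mask, so every
#' pixel belongs to some nucleus).
#'
#' A diffuse-only nucleus typically thresholds as one nucleus-sized blob,
#' which the upper area gate removes — such nuclei correctly report zero
#' foci.
#'
#' @param inclusion_image numeric 2-D matrix (the inclusion-protein channel).
#' @param nuclei a filtered `NucleusLabelMap` from [filter_nuclei()].
#' @param cfg a [pipeline_config()] supplying the RATS parameters and size
#'   gate.
#' @param pixel_size_um pixel calibration.
#' @return data frame of focus records: `field_id`, `focus_id`,
#'   `nucleus_id`, `centroid_row`, `centroid_col`, `area_um2`,
#'   `mean_intensity`.
#' @export
detect_foci <- function(inclusion_image, nuclei, cfg = pipeline_config(),
                        pixel_size_um = 0.102) {
  stopifnot(inherits(nuclei, "NucleusLabelMap"))
  if (!is_matrix2d(inclusion_image)) stop_input("inclusion_image must be a numeric matrix")
  if (!all(dim(inclusion_image) == dim(nuclei$labels)))
    stop_input("inclusion image and label map dimensions differ")
  empty <- data.frame(field_id = character(0), focus_id = integer(0),
                      nucleus_id = integer(0), centroid_row = numeric(0),
                      centroid_col = numeric(0), area_um2 = numeric(0),
                      mean_intensity = numeric(0))
  nuc_mask <- nuclei$labels > 0L
  if (!any(nuc_mask)) return(empty)
  masked <- inclusion_image * nuc_mask
  if (diff(range(masked)) == 0) return(empty) # blank channel: nothing to threshold
  # gradients within 2 px of the mask border are artifacts of masking, not
  # image structure: restrict the gradient support to the eroded mask
  interior <- as.matrix(EBImage::erode(nuc_mask + 0,
                                       EBImage::makeBrush(5, "disc"))) > 0.5
  fmask <- withCallingHandlers(
    rats_threshold(masked, p = cfg$rats_p,
                   noise_sigma = cfg$rats_noise_sigma,
                   lambda = cfg$rats_lambda,
                   min_leaf_px = cfg$rats_min_leaf_px,
                   support = interior),
    warning = function(w) {
      # no gradient support above noise: a structureless channel has no foci
      if (grepl("no gradient support", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  fmask <- fmask & nuc_mask
  if (!any(fmask)) return(empty)
  particles <- label_components(fmask, connectivity = cfg$connectivity,
                                field_id = nuclei$field_id)
  P <- particles$labels
  K <- max(P)
  fg <- which(P > 0L)
  pl <- P[fg]
  area_px <- tabulate(pl, K)
  area_um2 <- area_px * pixel_size_um^2
  keep <- in_interval(area_um2, cfg$focus_area_range_um2)
  if (!any(keep)) return(empty)
  nr <- nrow(P)
  rr <- ((fg - 1L) %% nr) + 1L
  cc <- ((fg - 1L) %/% nr) + 1L
  nl <- nuclei$labels[fg]
  owner <- as.integer(tapply(nl, pl, function(v) {
    t <- tabulate(v)
    which.max(t) # first maximum = lowest nucleus id on ties
  }))
  cen_r <- rowsum(as.numeric(rr), pl)[, 1] / area_px
  cen_c <- rowsum(as.numeric(cc), pl)[, 1] / area_px
  mi <- rowsum(as.numeric(inclusion_image[fg]), pl)[, 1] / area_px
  ids <- which(keep)
  data.frame(field_id = rep(nuclei$field_id, length(ids)),
             focus_id = seq_along(ids),
             nucleus_id = owner[ids],
             centroid_row = cen_r[ids],
             centroid_col = cen_c[ids],
             area_um2 = area_um2[ids],
             mean_intensity = mi[ids])
}

#' Tally foci into their nuclei
#'
#' Sets each nucleus record's `focus_count` to the number of focus records
#' assigned to it; nuclei without foci get 0.
#'
#' @param foci focus record data frame from [detect_foci()].
#' @param nuclei nucleus record data frame from [filter_nuclei()].
#' @return `nuclei` with `focus_count` updated.
#' @export
foci_per_nucleus <- function(foci, nuclei) {
  stopifnot(is.data.frame(foci), is.data.frame(nuclei))
  if (nrow(foci) && !all(foci$nucleus_id %in% nuclei$nucleus_id))
    stop("internal error: focus records reference unknown nucleus ids")
  counts <- tabulate(match(foci$nucleus_id, nuclei$nucleus_id),
                     nbins = nrow(nuclei))
  nuclei$focus_count <- counts
  nuclei
}
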