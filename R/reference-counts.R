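#' Published tissue immunohistochemistry summary counts
#'
#' The per-group summary table from the human post-mortem tissue study of
#' nuclear RBM45 inclusion pathology that this package's synthetic presets
#' are calibrated against: subject counts, total cells counted over 8 fields
#' per subject, mean/SEM cells per field, and mean/SEM nuclear and
#' cytoplasmic inclusions per cell, for hippocampal dentate gyrus granule
#' cells, spinal cord glial cells, and spinal cord motor neurons.
#'
#' Two internal inconsistencies of the published table are preserved as
#' printed rather than corrected: the FTLD-TDP dentate and ALS glial
#' `mean_cells_per_field` entries do not exactly equal
#' `total_cells / (n_subjects * 8)` (consistent with a small number of
#' excluded fields); the control, AD, and ALS dentate rows are exactly
#' consistent.
#'
#' @return data frame with columns `region`, `group_label`, `n_subjects`,
#'   `total_cells`, `mean_cells_per_field`, `sem_cells_per_field`,
#'   `mean_nuclear_inclusions_per_cell`, `sem_nuclear_inclusions_per_cell`,
#'   `mean_cytoplasmic_inclusions_per_cell`,
#'   `sem_cytoplasmic_inclusions_per_cell`, `fields_per_subject`.
#' @export
tissue_reference_counts <- function() {
  df <- rbind(
    data.frame(region = "dentate_gyrus_granule_cells",
               group_label = c("Control", "AD", "ALS", "FTLD-TDP"),
               n_subjects = c(10L, 5L, 8L, 6L),
               total_cells = c(4145L, 1590L, 2943L, 1962L),
               mean_cells_per_field = c(51.81, 39.75, 45.98, 40.92),
               sem_cells_per_field = c(4.92, 8.32, 5.98, 5.81),
               mean_nuclear_inclusions_per_cell = c(0.44, 0.98, 1.49, 2.38),
               sem_nuclear_inclusions_per_cell = c(0.09, 0.34, 0.27, 0.23),
               mean_cytoplasmic_inclusions_per_cell = c(0, 0.044, 0.048, 0.109),
               sem_cytoplasmic_inclusions_per_cell = c(0, 0.051, 0.055, 0.072)),
    data.frame(region = "spinal_cord_glial_cells",
               group_label = c("Control", "ALS"),
               n_subjects = c(9L, 15L),
               total_cells = c(693L, 2689L),
               mean_cells_per_field = c(9.62, 22.35),
               sem_cells_per_field = c(1.18, 1.74),
               mean_nuclear_inclusions_per_cell = c(0.23, 1.04),
               sem_nuclear_inclusions_per_cell = c(0.06, 0.18),
               mean_cytoplasmic_inclusions_per_cell = c(0, 0.11),
               sem_cytoplasmic_inclusions_per_cell = c(0, 0.47)),
    data.frame(region = "spinal_cord_motor_neurons",
               group_label = c("Control", "ALS"),
               n_subjects = c(9L, 15L),
               total_cells = c(308L, 351L),
               mean_cells_per_field = c(4.29, 2.91),
               sem_cells_per_field = c(0.53, 0.42),
               mean_nuclear_inclusions_per_cell = c(0, 0),
               sem_nuclear_inclusions_per_cell = c(0, 0),
               mean_cytoplasmic_inclusions_per_cell = c(0, 0.15),
               sem_cytoplasmic_inclusions_per_cell = c(0, 0.14)))
  df$fields_per_subject <- 8L
  df
}
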