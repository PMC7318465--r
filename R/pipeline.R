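#' Quantify one field: segment, count foci, measure intensities
#'
#' Runs the per-field stages in order: Z-projection (if the field is a
#' stack), optional background subtraction, fixed-fraction DAPI
#' thresholding, component labeling, size/shape/border gating, RATS foci
#' detection inside the nuclear mask, per-nucleus focus tallies, and
#' per-nucleus channel intensities.
#'
#' @param field an [image_field()].
#' @param cfg a [pipeline_config()].
#' @param nuclear_channel,inclusion_channel,reference_channel channel names;
#'   defaults match the synthetic generator (`dapi`, `inclusion`, `safb`).
#'   The reference channel is optional and only needs to exist for the
#'   intensity-versus-count regression downstream.
#' @return a `FieldResult`: list with `field_id`, `subject_id`,
#'   `group_label`, `cell_count`, `nuclei`, `foci`, `intensity`,
#'   `label_map`.
#' @export
quantify_field <- function(field, cfg = pipeline_config(),
                           nuclear_channel = "dapi",
                           inclusion_channel = "inclusion",
                           reference_channel = "safb") {
  stopifnot(inherits(field, "ImageField"), inherits(cfg, "PipelineConfig"))
  for (ch in c(nuclear_channel, inclusion_channel))
    if (!ch %in% names(field$channels))
      stop_input("field '", field$field_id, "' lacks channel '", ch, "'")
  if (is_stack(field)) field <- project_stack(field, cfg$projection_method)
  if (!is.null(cfg$background_radius_px))
    field$channels <- lapply(field$channels, subtract_background,
                             radius_px = cfg$background_radius_px)
  dapi <- field$channels[[nuclear_channel]]
  mask <- threshold_fixed(dapi, cfg$dapi_threshold)
  lm0 <- label_components(mask, cfg$connectivity, field_id = field$field_id)
  seg <- filter_nuclei(lm0, dapi, cfg, pixel_size_um = field$pixel_size_um)
  foci <- detect_foci(field$channels[[inclusion_channel]], seg$label_map,
                      cfg, pixel_size_um = field$pixel_size_um)
  nuclei <- foci_per_nucleus(foci, seg$records)
  nuclei$subject_id <- rep(field$subject_id, nrow(nuclei))
  nuclei$group_label <- rep(field$group_label, nrow(nuclei))
  intensity <- nuclear_intensity(field, seg$label_map)
  intensity$subject_id <- rep(field$subject_id, nrow(intensity))
  intensity$group_label <- rep(field$group_label, nrow(intensity))
  structure(list(field_id = field$field_id, subject_id = field$subject_id,
                 group_label = field$group_label,
                 cell_count = count_cells(nuclei),
                 nuclei = nuclei, foci = foci, intensity = intensity,
                 label_map = seg$label_map),
            class = "FieldResult")
}

combine_field_results <- function(results) {
  field_table <- do.call(rbind, lapply(results, function(r)
    data.frame(field_id = r$field_id, subject_id = r$subject_id,
               group_label = r$group_label, cell_count = r$cell_count,
               total_foci = nrow(r$foci))))
  rownames(field_table) <- NULL
  bind <- function(part) {
    out <- do.call(rbind, lapply(results, `[[`, part))
    rownames(out) <- NULL
    out
  }
  list(field_table = field_table, nuclei = bind("nuclei"),
       foci = bind("foci"), intensity = bind("intensity"))
}

#' Statistical battery over combined per-nucleus results
#'
#' All pairwise Mann-Whitney U comparisons of per-cell inclusion counts
#' between groups with Bonferroni correction over the family of pairs
#' actually run, plus (when a reference channel was measured) the linear
#' regression of per-nucleus reference-channel Z-score on inclusion count.
#'
#' @param nuclei combined nucleus table (needs `group_label`,
#'   `focus_count`).
#' @param intensity combined intensity table, or `NULL` to skip the
#'   regression.
#' @param reference_channel channel regressed on inclusion count.
#' @param cfg a [pipeline_config()] (supplies `zscore_ddof`).
#' @return list with `pairwise` (a `StatsResult` data frame) and
#'   `regression` (one-row data frame or `NULL`).
#' @export
study_stats <- function(nuclei, intensity = NULL,
                        reference_channel = "safb",
                        cfg = pipeline_config()) {
  groups <- sort(unique(nuclei$group_label))
  pairwise <- NULL
  if (length(groups) >= 2L) {
    pairs <- utils::combn(groups, 2, simplify = FALSE)
    rows <- lapply(pairs, function(pr) {
      mann_whitney(nuclei$focus_count[nuclei$group_label == pr[1]],
                   nuclei$focus_count[nuclei$group_label == pr[2]],
                   comparison = paste(pr, collapse = " vs "))
    })
    pairwise <- do.call(rbind, rows)
    pairwise$p_adjusted <- bonferroni_adjust(pairwise$p_raw)
    pairwise$adjustment_method <- "bonferroni"
  }
  regression <- NULL
  if (!is.null(intensity) && reference_channel %in% intensity$channel) {
    ref <- intensity[intensity$channel == reference_channel, , drop = FALSE]
    if (nrow(ref) >= 3L && stats::sd(nuclei$focus_count) > 0) {
      z <- zscore_table(ref, value = "integrated", ddof = cfg$zscore_ddof)
      key <- paste(z$field_id, z$nucleus_id)
      counts <- nuclei$focus_count[match(key, paste(nuclei$field_id,
                                                    nuclei$nucleus_id))]
      regression <- linear_regression(counts, z$z)
    }
  }
  list(pairwise = pairwise, regression = regression)
}

#' Run the full pipeline over a study directory
#'
#' Reads a study bundle written by [generate_study()] (TIFF per field plus
#' `manifest.json`), quantifies every field, aggregates per-group summaries
#' and runs the statistical battery. Per-field failures are logged to stderr
#' and skipped; their ids are reported in the returned `failed` element.
#'
#' @param config a [pipeline_config()].
#' @param input_dir study directory containing `manifest.json`.
#' @return list with `field_results`, `field_table`, `nuclei`, `foci`,
#'   `intensity`, `group_summaries`, `stats`, `failed`.
#' @export
run_pipeline <- function(config = pipeline_config(), input_dir) {
  manifest_path <- file.path(input_dir, "manifest.json")
  if (!dir.exists(input_dir) || !file.exists(manifest_path))
    stop_input("input_dir must contain a manifest.json study bundle: ",
               input_dir)
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  entries <- manifest$fields
  if (!length(entries)) stop_input("empty study: manifest lists no fields")
  results <- list()
  failed <- character(0)
  for (e in entries) {
    res <- tryCatch({
      field <- read_field(file.path(input_dir, e$file),
                          channel_names = unlist(e$channel_names),
                          pixel_size_um = e$pixel_size_um,
                          field_id = e$field_id, subject_id = e$subject_id,
                          group_label = e$group_label)
      quantify_field(field, config)
    }, error = function(err) {
      message("run_pipeline: field '", e$field_id, "' failed: ",
              conditionMessage(err))
      NULL
    })
    if (is.null(res)) failed <- c(failed, e$field_id)
    else {
      results[[e$field_id]] <- res
      msg(sprintf("run_pipeline: %s: %d cells, %d foci", e$field_id,
                  res$cell_count, nrow(res$foci)))
    }
  }
  if (!length(results)) stop_input("all fields failed to process")
  comb <- combine_field_results(results)
  groups <- unique(comb$field_table$group_label)
  group_summaries <- do.call(rbind, lapply(groups, function(g) {
    ft <- comb$field_table[comb$field_table$group_label == g, , drop = FALSE]
    nt <- comb$nuclei[comb$nuclei$group_label == g, , drop = FALSE]
    summarize_group(ft, nt, group_label = g)
  }))
  stats <- study_stats(comb$nuclei, comb$intensity, cfg = config)
  c(list(field_results = results), comb,
    list(group_summaries = group_summaries, stats = stats, failed = failed))
}

signif_cols <- function(df, digits = 6) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], signif, digits = digits)
  df
}

#' Write pipeline results as CSV/JSON
#'
#' Emits `field_table.csv`, `nuclei.csv`, `foci.csv`, `intensity.csv`,
#' `group_summary.csv` and `stats.json`. Row order is fixed (group, subject,
#' field, nucleus) and doubles are rounded to 6 significant digits so that
#' re-running an identical configuration yields byte-identical files.
#'
#' @param results list from [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_results <- function(results, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ord <- function(df) {
    keys <- intersect(c("group_label", "subject_id", "field_id", "nucleus_id",
                        "focus_id", "channel"), names(df))
    df[do.call(order, df[keys]), , drop = FALSE]
  }
  emit <- function(df, name)
    utils::write.csv(signif_cols(ord(df)), file.path(out_dir, name),
                     row.names = FALSE)
  emit(results$field_table, "field_table.csv")
  emit(results$nuclei, "nuclei.csv")
  emit(results$foci, "foci.csv")
  emit(results$intensity, "intensity.csv")
  utils::write.csv(signif_cols(results$group_summaries),
                   file.path(out_dir, "group_summary.csv"), row.names = FALSE)
  stats <- results$stats
  jsonlite::write_json(
    list(pairwise = if (!is.null(stats$pairwise)) signif_cols(stats$pairwise),
         regression = if (!is.null(stats$regression))
           signif_cols(stats$regression)),
    file.path(out_dir, "stats.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA, null = "null")
  invisible(out_dir)
}

#' Validate the pipeline against synthetic ground truth
#'
#' Generates at least 10 synthetic fields from `spec`, quantifies them with
#' `cfg`, and reports the [agreement()] fraction between automated and true
#' counts together with pass/fail against the 95% criterion used when the
#' original pipeline was validated against manual counts.
#'
#' @param spec a [synthetic_spec()].
#' @param cfg a [pipeline_config()].
#' @param n_fields number of validation fields (>= 10).
#' @param seed RNG seed.
#' @param threshold pass threshold on the agreement fraction.
#' @return list with `agreement`, `pass`, `n_fields`, `per_field` (automated
#'   vs true counts per field).
#' @export
validate_run <- function(spec = synthetic_spec(), cfg = pipeline_config(),
                         n_fields = 20L, seed = 1L, threshold = 0.95) {
  if (n_fields < 10L) stop_input("validation needs at least 10 fields")
  with_seed(seed, {
    auto <- truth <- vector("list", n_fields)
    for (i in seq_len(n_fields)) {
      fid <- sprintf("val_f%03d", i)
      gen <- generate_field(spec, seed = NULL, field_id = fid)
      res <- quantify_field(gen$field, cfg)
      auto[[i]] <- data.frame(field_id = fid, cell_count = res$cell_count,
                              total_foci = nrow(res$foci))
      truth[[i]] <- data.frame(field_id = fid,
                               cell_count = gen$truth$cell_count,
                               total_foci = sum(gen$truth$nuclei$focus_count))
      msg(sprintf("validate_run: %s auto %d/%d true %d/%d", fid,
                  auto[[i]]$cell_count, auto[[i]]$total_foci,
                  truth[[i]]$cell_count, truth[[i]]$total_foci))
    }
    auto <- do.call(rbind, auto)
    truth <- do.call(rbind, truth)
    frac <- agreement(auto, truth)
    list(agreement = frac, pass = frac >= threshold, n_fields = n_fields,
         per_field = data.frame(
           field_id = auto$field_id, cell_count = auto$cell_count,
           total_foci = auto$total_foci, true_cell_count = truth$cell_count,
           true_total_foci = truth$total_foci))
  })
}
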