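#' Specification for synthetic fluorescence fields
#'
#' Describes one condition's image model: field geometry, nucleus placement,
#' the DAPI channel, the inclusion channel (diffuse nucleoplasmic signal plus
#' bright intranuclear foci with a zero-inflated Poisson count distribution
#' capped at 17 — the observed per-cell range in tissue), a reference
#' ("SAFB-like") channel whose nuclear level decreases linearly with the
#' focus count, and the optical/noise model. All defaults are chosen to
#' emulate dense granule-cell fields: ~104 x 104 um at 0.102 um/px, ~40-52
#' nuclei per field, and focus burdens matching published per-cell means.
#'
#' @param image_size_px field edge length in pixels (square field).
#' @param pixel_size_um pixel calibration.
#' @param n_nuclei target nucleus count per field.
#' @param n_nuclei_cv field-to-field coefficient of variation of the count.
#' @param nucleus_radius_um range of equivalent-disc nuclear radii; the
#'   default 3.8-5.2 um keeps nuclear areas inside the 40-300 um^2 gate.
#' @param nucleus_axis_ratio_max nuclei are ellipses with axis ratio drawn
#'   in `[1, this]` (area preserved).
#' @param min_separation_um minimum edge-to-edge distance between nuclei.
#' @param dapi_background,dapi_mean,dapi_sd nuclear-channel levels (native
#'   `[0, 1]` scale): background, per-nucleus mean, between-nucleus sd.
#' @param inclusion_background,inclusion_diffuse background and diffuse
#'   nucleoplasmic level of the inclusion channel.
#' @param focus_pi0 extra zero mass of the zero-inflated Poisson focus-count
#'   distribution.
#' @param focus_lambda Poisson mean of the non-zero-inflated component.
#' @param focus_cap hard upper support of the count distribution (17).
#' @param focus_diameter_um range of focus diameters (FWHM of the rendered
#'   Gaussian spot); the default 0.6-1.2 um sits inside the published
#'   nuclear-stress-body size range.
#' @param focus_amplitude peak spot intensity above the diffuse level.
#' @param safb_background,safb_b0,safb_beta,safb_sd reference channel:
#'   background, baseline nuclear level `b0`, per-focus decrement `beta`
#'   (nuclear level `= max(0, b0 - beta * k)`), and between-nucleus noise sd.
#' @param read_noise_sd Gaussian read noise sd added to every pixel.
#' @param shot_noise apply Poisson shot noise (at `shot_photons` photons per
#'   unit intensity) before read noise.
#' @param shot_photons photon scale for shot noise.
#' @param blur_sd_px Gaussian optical blur sd in pixels.
#' @param seed default seed used when the generating functions are called
#'   without one.
#' @return an object of class `SyntheticSpec`.
#' @export
synthetic_spec <- function(image_size_px = 1024,
                           pixel_size_um = 0.102,
                           n_nuclei = 46,
                           n_nuclei_cv = 0.05,
                           nucleus_radius_um = c(3.8, 5.2),
                           nucleus_axis_ratio_max = 1.15,
                           min_separation_um = 1.0,
                           dapi_background = 0.03,
                           dapi_mean = 0.6,
                           dapi_sd = 0.05,
                           inclusion_background = 0.02,
                           inclusion_diffuse = 0.08,
                           focus_pi0 = 0.4,
                           focus_lambda = 5 / 3,
                           focus_cap = 17,
                           focus_diameter_um = c(0.6, 1.2),
                           focus_amplitude = 0.55,
                           safb_background = 0.03,
                           safb_b0 = 0.55,
                           safb_beta = 0.04,
                           safb_sd = 0.04,
                           read_noise_sd = 0.02,
                           shot_noise = FALSE,
                           shot_photons = 500,
                           blur_sd_px = 1.0,
                           seed = 1L) {
  check_interval(nucleus_radius_um, "nucleus_radius_um")
  check_interval(focus_diameter_um, "focus_diameter_um")
  if (focus_diameter_um[2] >= 2 * nucleus_radius_um[1])
    stop_input("focus diameters must fit inside the smallest nucleus")
  stopifnot(image_size_px >= 32, pixel_size_um > 0, n_nuclei >= 0,
            n_nuclei_cv >= 0, nucleus_axis_ratio_max >= 1,
            min_separation_um >= 0, focus_pi0 >= 0, focus_pi0 <= 1,
            focus_lambda >= 0, focus_cap == 17, focus_amplitude >= 0,
            safb_beta >= 0, safb_sd >= 0, read_noise_sd >= 0,
            blur_sd_px >= 0, dapi_sd >= 0)
  spec <- as.list(environment())
  structure(spec, class = "SyntheticSpec")
}

#' Group presets emulating published tissue burdens
#'
#' Returns a [synthetic_spec()] whose focus-count distribution and nucleus
#' density emulate one dentate-gyrus group of [tissue_reference_counts()]:
#' zero-inflated Poisson parameters giving per-cell means of 0.44
#' (control-like), 0.98 (AD-like), 1.49 (ALS-like) and 2.38 (FTLD-like), and
#' per-field nucleus targets near the published mean cells/field.
#'
#' @param group one of `"control"`, `"AD"`, `"ALS"`, `"FTLD"`.
#' @param ... overrides passed on to [synthetic_spec()].
#' @return a `SyntheticSpec`.
#' @export
group_preset <- function(group = c("control", "AD", "ALS", "FTLD"), ...) {
  group <- match.arg(group)
  par <- switch(group,
    control = list(n_nuclei = 51.81, focus_pi0 = 0.60, focus_lambda = 1.100),
    AD      = list(n_nuclei = 39.75, focus_pi0 = 0.44, focus_lambda = 1.750),
    ALS     = list(n_nuclei = 45.98, focus_pi0 = 0.35, focus_lambda = 2.292),
    FTLD    = list(n_nuclei = 40.92, focus_pi0 = 0.20, focus_lambda = 2.975))
  do.call(synthetic_spec, utils::modifyList(par, list(...)))
}

#' Draw zero-inflated Poisson focus counts
#'
#' With probability `pi0` the count is 0; otherwise Poisson(`lambda`). The
#' support is capped at `cap` (counts above the published maximum of 17 are
#' truncated; at the preset rates this affects a negligible fraction of
#' draws). Mean = `(1 - pi0) * lambda` up to truncation.
#'
#' @param n number of draws.
#' @param pi0 extra zero mass in `[0, 1]`.
#' @param lambda Poisson mean.
#' @param cap upper support bound.
#' @return integer vector.
#' @export
rzip <- function(n, pi0, lambda, cap = 17) {
  stopifnot(n >= 0, pi0 >= 0, pi0 <= 1, lambda >= 0, cap >= 0)
  k <- stats::rpois(n, lambda)
  k[stats::runif(n) < pi0] <- 0L
  pmin(k, as.integer(cap))
}

# add a Gaussian spot in place within its 4-sigma bounding box
add_spot <- function(img, row, col, sigma_px, amplitude) {
  n <- nrow(img)
  h <- ceiling(4 * sigma_px)
  rs <- max(1, round(row) - h):min(n, round(row) + h)
  cs <- max(1, round(col) - h):min(ncol(img), round(col) + h)
  d2 <- outer((rs - row)^2, (cs - col)^2, `+`)
  img[rs, cs] <- img[rs, cs] + amplitude * exp(-d2 / (2 * sigma_px^2))
  img
}

# pixel set of an ellipse (area-preserving parameterization)
ellipse_pixels <- function(nr, nc, row, col, r_px, axis_ratio, theta) {
  a <- r_px * sqrt(axis_ratio); b <- r_px / sqrt(axis_ratio)
  h <- ceiling(a) + 1L
  rs <- max(1, floor(row - h)):min(nr, ceiling(row + h))
  cs <- max(1, floor(col - h)):min(nc, ceiling(col + h))
  dr <- rep(rs - row, times = length(cs))
  dc <- rep(cs - col, each = length(rs))
  u <- (dr * cos(theta) + dc * sin(theta)) / a
  v <- (-dr * sin(theta) + dc * cos(theta)) / b
  inside <- u^2 + v^2 <= 1
  cbind(rep(rs, times = length(cs))[inside],
        rep(cs, each = length(rs))[inside])
}

#' Generate one synthetic multi-channel field with ground truth
#'
#' Places non-overlapping elliptical nuclei by rejection sampling, renders
#' the DAPI, inclusion and reference channels, applies Gaussian blur and
#' noise, quantizes intensities to the 16-bit grid (so TIFF round-trips are
#' pixel-exact), and records the per-nucleus ground truth. Focus counts are
#' drawn from `spec`'s zero-inflated Poisson; each focus is placed inside
#' its nucleus with enough separation from its siblings to remain resolvable,
#' and the truth records the counts actually rendered.
#'
#' @param spec a [synthetic_spec()].
#' @param seed RNG seed (`NULL`: continue the current stream; the default
#'   uses `spec$seed`).
#' @param field_id,subject_id,group_label metadata for the field.
#' @return list with `field` (an [image_field()] with channels `dapi`,
#'   `inclusion`, `safb`) and `truth` (a `GroundTruth`: `field_id`,
#'   `cell_count`, per-nucleus data frame `nuclei` with `focus_count` and
#'   `safb_level`).
#' @export
generate_field <- function(spec, seed = spec$seed, field_id = "field",
                           subject_id = "subject", group_label = "group") {
  stopifnot(inherits(spec, "SyntheticSpec"))
  with_seed(seed, generate_field_impl(spec, field_id, subject_id, group_label))
}

generate_field_impl <- function(spec, field_id, subject_id, group_label) {
  n_px <- as.integer(spec$image_size_px)
  ps <- spec$pixel_size_um
  n <- if (spec$n_nuclei == 0) 0L else
    max(0L, as.integer(round(stats::rnorm(1, spec$n_nuclei,
                                          spec$n_nuclei_cv * spec$n_nuclei))))
  r_um <- stats::runif(n, spec$nucleus_radius_um[1], spec$nucleus_radius_um[2])
  r_um <- sort(r_um, decreasing = TRUE) # placing large nuclei first packs better
  r_px <- r_um / ps
  sep_px <- spec$min_separation_um / ps
  # bound the semi-major axes so min separation holds for any orientation
  ax <- sqrt(spec$nucleus_axis_ratio_max)

  cen <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    placed <- FALSE
    margin <- r_px[i] * ax + 4 # keep each nucleus clear of the field border
    for (try in seq_len(4000L)) {
      cand <- stats::runif(2, 1 + margin, n_px - margin)
      if (i == 1L ||
          all(sqrt(rowSums(sweep(cen[seq_len(i - 1L), , drop = FALSE], 2,
                                 cand)^2)) >=
              (r_px[i] + r_px[seq_len(i - 1L)]) * ax + sep_px)) {
        cen[i, ] <- cand; placed <- TRUE; break
      }
    }
    if (!placed)
      stop_input("generate_field: field too crowded to place ", n,
                 " nuclei without overlap")
  }

  dapi <- matrix(spec$dapi_background, n_px, n_px)
  incl <- matrix(spec$inclusion_background, n_px, n_px)
  safb <- matrix(spec$safb_background, n_px, n_px)
  axis_ratio <- stats::runif(n, 1, spec$nucleus_axis_ratio_max)
  theta <- stats::runif(n, 0, pi)
  dapi_level <- pmin(pmax(stats::rnorm(n, spec$dapi_mean, spec$dapi_sd),
                          0.2), 0.95)
  k_drawn <- rzip(n, spec$focus_pi0, spec$focus_lambda, spec$focus_cap)
  k_placed <- integer(n)
  safb_level <- numeric(n)

  for (i in seq_len(n)) {
    px <- ellipse_pixels(n_px, n_px, cen[i, 1], cen[i, 2], r_px[i],
                         axis_ratio[i], theta[i])
    dapi[px] <- dapi_level[i]
    incl[px] <- spec$inclusion_diffuse
    # place k resolvable foci; drop those that cannot fit
    b_px <- r_px[i] / sqrt(axis_ratio[i]) # minor semi-axis
    fr <- fc <- fs <- numeric(0)
    for (j in seq_len(k_drawn[i])) {
      d_um <- stats::runif(1, spec$focus_diameter_um[1],
                           spec$focus_diameter_um[2])
      sigma <- (d_um / ps) / 2.355 # FWHM -> sd
      rmax <- b_px - 2 * sigma - 2
      if (rmax <= 0) next
      for (try in seq_len(60L)) {
        ang <- stats::runif(1, 0, 2 * pi)
        rad <- sqrt(stats::runif(1)) * rmax
        pr <- cen[i, 1] + rad * cos(ang)
        pc <- cen[i, 2] + rad * sin(ang)
        if (!length(fr) ||
            all(sqrt((fr - pr)^2 + (fc - pc)^2) >= 2.2 * (fs + sigma) + 2)) {
          fr <- c(fr, pr); fc <- c(fc, pc); fs <- c(fs, sigma)
          break
        }
      }
    }
    k_placed[i] <- length(fr)
    for (j in seq_along(fr)) {
      amp <- spec$focus_amplitude * stats::runif(1, 0.9, 1.1)
      incl <- add_spot(incl, fr[j], fc[j], fs[j], amp)
    }
    safb_level[i] <- max(0, spec$safb_b0 - spec$safb_beta * k_placed[i] +
                           stats::rnorm(1, 0, spec$safb_sd))
    safb[px] <- safb_level[i]
  }

  finish <- function(img) {
    if (spec$blur_sd_px > 0)
      img <- as.matrix(EBImage::gblur(img, sigma = spec$blur_sd_px))
    if (isTRUE(spec$shot_noise))
      img <- stats::rpois(length(img), pmax(img, 0) * spec$shot_photons) /
        spec$shot_photons
    if (spec$read_noise_sd > 0)
      img <- img + stats::rnorm(length(img), 0, spec$read_noise_sd)
    img <- pmin(pmax(img, 0), 1)
    m <- round(img * 65535) / 65535 # 16-bit grid: exact TIFF round-trips
    matrix(m, n_px, n_px)
  }

  field <- image_field(
    channels = list(dapi = finish(dapi), inclusion = finish(incl),
                    safb = finish(safb)),
    pixel_size_um = ps, field_id = field_id, subject_id = subject_id,
    group_label = group_label)
  truth <- structure(
    list(field_id = field_id, subject_id = subject_id,
         group_label = group_label, cell_count = n,
         nuclei = data.frame(
           field_id = rep(field_id, n), nucleus_id = seq_len(n),
           center_row = cen[, 1], center_col = cen[, 2],
           radius_um = r_um, axis_ratio = axis_ratio,
           focus_count = k_placed, safb_level = safb_level,
           dapi_level = dapi_level)),
    class = "GroundTruth")
  list(field = field, truth = truth)
}

#' Generate a whole synthetic study
#'
#' For each group, generates `n_subjects[[group]]` subjects with
#' `fields_per_subject` fields each (8 by default, matching the tissue
#' protocol). Subject-level heterogeneity is emulated by jittering each
#' subject's nucleus target and focus rate by independent lognormal factors
#' (10% sd by default). Optionally writes the study to disk as one TIFF per
#' field plus truth CSVs and a JSON manifest sufficient for exact
#' regeneration and for [run_pipeline()].
#'
#' @param specs named list of [synthetic_spec()] objects, one per group.
#' @param n_subjects named integer vector/list of subjects per group.
#' @param seed study seed (all randomness flows from it).
#' @param fields_per_subject fields per subject.
#' @param subject_sdlog lognormal sdlog of the subject jitter
#'   (`log(1.1)` ~ 10%).
#' @param out_dir optional directory to write the study bundle to.
#' @return invisibly, a study bundle: list with `fields` (list of
#'   `generate_field()` results), `truth_fields` / `truth_nuclei` data
#'   frames, and `manifest`.
#' @export
generate_study <- function(specs, n_subjects, seed = 1L,
                           fields_per_subject = 8L,
                           subject_sdlog = log(1.1), out_dir = NULL) {
  stopifnot(is.list(specs), length(specs) >= 1L, !is.null(names(specs)))
  if (!all(names(specs) %in% names(n_subjects)))
    stop_input("n_subjects must name every group in specs")
  with_seed(seed, {
    fields <- list()
    manifest_fields <- list()
    for (grp in names(specs)) {
      spec <- specs[[grp]]
      for (s in seq_len(n_subjects[[grp]])) {
        subject_id <- sprintf("%s_s%02d", grp, s)
        jit_n <- stats::rlnorm(1, 0, subject_sdlog)
        jit_l <- stats::rlnorm(1, 0, subject_sdlog)
        sspec <- spec
        sspec$n_nuclei <- spec$n_nuclei * jit_n
        sspec$focus_lambda <- spec$focus_lambda * jit_l
        for (f in seq_len(fields_per_subject)) {
          field_id <- sprintf("%s_f%02d", subject_id, f)
          res <- generate_field(sspec, seed = NULL, field_id = field_id,
                                subject_id = subject_id, group_label = grp)
          fields[[field_id]] <- res
          manifest_fields[[field_id]] <- list(
            field_id = field_id, subject_id = subject_id, group_label = grp,
            file = paste0(field_id, ".tif"),
            channel_names = names(res$field$channels),
            pixel_size_um = res$field$pixel_size_um)
        }
      }
    }
    truth_fields <- do.call(rbind, lapply(fields, function(x)
      data.frame(field_id = x$truth$field_id, subject_id = x$truth$subject_id,
                 group_label = x$truth$group_label,
                 cell_count = x$truth$cell_count,
                 total_foci = sum(x$truth$nuclei$focus_count))))
    rownames(truth_fields) <- NULL
    truth_nuclei <- do.call(rbind, lapply(fields, function(x) x$truth$nuclei))
    rownames(truth_nuclei) <- NULL
    manifest <- list(seed = seed, fields_per_subject = fields_per_subject,
                     subject_sdlog = subject_sdlog,
                     groups = names(specs), fields = unname(manifest_fields))
    bundle <- list(fields = fields, truth_fields = truth_fields,
                   truth_nuclei = truth_nuclei, manifest = manifest)
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      for (x in fields)
        write_field(x$field, file.path(out_dir, paste0(x$field$field_id, ".tif")))
      utils::write.csv(truth_fields, file.path(out_dir, "truth_fields.csv"),
                       row.names = FALSE)
      utils::write.csv(truth_nuclei, file.path(out_dir, "truth_nuclei.csv"),
                       row.names = FALSE)
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
    }
    invisible(bundle)
  })
}

#' Automated-versus-truth agreement fraction
#'
#' Fraction of fields on which the automated cell count and the automated
#' total focus count both exactly match the generator's ground truth — the
#' quantity the tissue protocol required to reach at least 95% against
#' manual counts.
#'
#' @param results data frame with `field_id`, `cell_count`, `total_foci`
#'   (automated values, e.g. from [run_pipeline()]'s field results).
#' @param truth data frame with the same columns holding ground truth (e.g.
#'   `truth_fields` of [generate_study()]).
#' @return fraction in `[0, 1]`.
#' @export
agreement <- function(results, truth) {
  stopifnot(is.data.frame(results), is.data.frame(truth))
  need <- c("field_id", "cell_count", "total_foci")
  if (!all(need %in% names(results)) || !all(need %in% names(truth)))
    stop_input("results and truth need columns: ", paste(need, collapse = ", "))
  if (!setequal(results$field_id, truth$field_id) ||
      nrow(results) != nrow(truth))
    stop_input("results and truth field ids do not match")
  m <- match(results$field_id, truth$field_id)
  mean(results$cell_count == truth$cell_count[m] &
         results$total_foci == truth$total_foci[m])
}
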