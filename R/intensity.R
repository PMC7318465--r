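#' Per-nucleus channel intensities through the nuclear mask
#'
#' Measures every channel of a field inside each segmented nucleus, using the
#' nuclear label map as an overlay mask: background pixels are excluded, and
#' for each (nucleus, channel) pair the mean and integrated (summed)
#' intensity over the nucleus pixel set are reported.
#'
#' @param field a 2-D [image_field()].
#' @param nuclei a filtered `NucleusLabelMap`.
#' @return data frame keyed by (`field_id`, `nucleus_id`, `channel`) with
#'   `mean_intensity`, `integrated_intensity`, `area_um2`. The identity
#'   `integrated = mean * pixel count` holds exactly.
#' @export
nuclear_intensity <- function(field, nuclei) {
  stopifnot(inherits(field, "ImageField"), inherits(nuclei, "NucleusLabelMap"))
  if (is_stack(field))
    stop_input("field has a slice axis; project_stack() it first")
  if (!all(dim(field$channels[[1]]) == dim(nuclei$labels)))
    stop_input("field and label map dimensions differ")
  K <- max(nuclei$labels)
  chn <- names(field$channels)
  if (K == 0L)
    return(data.frame(field_id = character(0), nucleus_id = integer(0),
                      channel = character(0), mean_intensity = numeric(0),
                      integrated_intensity = numeric(0), area_um2 = numeric(0)))
  fg <- which(nuclei$labels > 0L)
  lab <- nuclei$labels[fg]
  npx <- tabulate(lab, K)
  if (any(npx == 0L))
    stop("internal error: empty nucleus label in filtered map")
  res <- lapply(chn, function(nm) {
    s <- rowsum(as.numeric(field$channels[[nm]][fg]), lab)[, 1]
    data.frame(field_id = field$field_id, nucleus_id = seq_len(K),
               channel = nm, mean_intensity = s / npx,
               integrated_intensity = s,
               area_um2 = npx * field$pixel_size_um^2)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Standardize a numeric vector to Z-scores
#'
#' `z_i = (x_i - mean(x)) / sd(x)` with the standard deviation computed with
#' `n - ddof` in the denominator (`ddof = 1`: sample sd, the default;
#' `ddof = 0`: population sd).
#'
#' @param values numeric vector, length >= 2.
#' @param ddof degrees-of-freedom correction.
#' @return numeric vector with mean 0 and (ddof-consistent) sd 1.
#' @export
zscore <- function(values, ddof = 1) {
  if (!is.numeric(values) || length(values) < 2L)
    stop_input("values must be numeric with length >= 2")
  if (!all(is.finite(values))) stop_input("values must be finite")
  stopifnot(ddof >= 0, ddof < length(values))
  m <- mean(values)
  s <- sqrt(sum((values - m)^2) / (length(values) - ddof))
  if (s == 0) stop_input("degenerate input: constant values have no Z-scores")
  (values - m) / s
}

#' Z-score an intensity table per channel
#'
#' Standardizes per-nucleus intensities within each (channel, scope) pool so
#' that conditions measured on different raw scales become comparable. By
#' default the pool is all nuclei of all fields sharing a channel — the
#' common scale needed to compare treated against untreated cells.
#'
#' @param intensity data frame from [nuclear_intensity()] (rows from several
#'   fields may be concatenated), optionally carrying extra grouping columns.
#' @param value which intensity to standardize: `"integrated"` (total
#'   nuclear signal, the default) or `"mean"`.
#' @param scope_by optional character vector of additional column names
#'   defining separate standardization pools (e.g. an experiment id).
#' @param ddof degrees-of-freedom correction, as in [zscore()].
#' @return the input with columns `z` and `grouping_scope` appended.
#' @export
zscore_table <- function(intensity, value = c("integrated", "mean"),
                         scope_by = NULL, ddof = 1) {
  value <- match.arg(value)
  col <- paste0(value, "_intensity")
  stopifnot(is.data.frame(intensity), col %in% names(intensity))
  if (!is.null(scope_by) && !all(scope_by %in% names(intensity)))
    stop_input("scope_by columns missing from intensity table")
  keys <- c("channel", scope_by)
  pool <- interaction(intensity[keys], drop = TRUE, sep = "/")
  z <- rep(NA_real_, nrow(intensity))
  for (lev in levels(pool)) {
    sel <- pool == lev
    z[sel] <- zscore(intensity[[col]][sel], ddof = ddof)
  }
  intensity$z <- z
  intensity$grouping_scope <- paste(paste(keys, collapse = "+"),
                                    as.character(pool))
  intensity
}
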