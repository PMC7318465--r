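stats_result <- function(test_name, comparison, statistic, p_raw,
                         p_adjusted = NA_real_, adjustment_method = "none",
                         n_per_group = "") {
  data.frame(test_name = test_name, comparison = comparison,
             statistic = statistic, p_raw = p_raw, p_adjusted = p_adjusted,
             adjustment_method = adjustment_method,
             n_per_group = n_per_group, stringsAsFactors = FALSE)
}

#' Mann-Whitney U test with exact enumeration or tie-corrected normal p
#'
#' Rank-sum test for two independent samples, the standard choice for
#' strongly right-skewed per-cell inclusion counts. The U statistic is
#' computed from midranks (so ties are handled exactly). The two-sided p
#' value is obtained by full enumeration of all `choose(n1+n2, n1)` group
#' assignments when `mode = "exact"` (auto-selected for `n1 + n2 <= 12`),
#' otherwise by the normal approximation with tie-corrected variance and a
#' continuity correction. Unlike [stats::wilcox.test()], the exact mode
#' remains available in the presence of ties.
#'
#' @param x,y numeric samples (non-empty).
#' @param mode `"auto"`, `"exact"`, or `"normal"`.
#' @param comparison label stored in the result.
#' @return a one-row `StatsResult` data frame; `statistic` is `U` of `x`
#'   (rank sum of `x` minus its minimum).
#' @export
mann_whitney <- function(x, y, mode = c("auto", "exact", "normal"),
                         comparison = "x vs y") {
  mode <- match.arg(mode)
  if (!length(x) || !length(y)) stop_input("both samples must be non-empty")
  if (!all(is.finite(c(x, y)))) stop_input("samples must be finite")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  if (mode == "auto") mode <- if (N <= 12) "exact" else "normal"
  r <- rank(c(x, y)) # midranks
  U1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (mode == "exact") {
    lo <- min(U1, n1 * n2 - U1)
    hi <- max(U1, n1 * n2 - U1)
    combs <- utils::combn(N, n1)
    Us <- colSums(matrix(r[combs], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- min(1, mean(Us <= lo + 1e-9) + mean(Us >= hi - 1e-9))
    test <- "mann_whitney_u_exact"
  } else {
    mu <- n1 * n2 / 2
    tie <- table(c(x, y))
    v <- n1 * n2 / 12 * ((N + 1) - sum(tie^3 - tie) / (N * (N - 1)))
    if (v <= 0) {
      p <- 1
    } else {
      z <- (U1 - mu - sign(U1 - mu) * 0.5) / sqrt(v)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    test <- "mann_whitney_u_normal"
  }
  stats_result(test, comparison, statistic = U1, p_raw = p,
               n_per_group = paste(n1, n2, sep = ","))
}

#' Bonferroni correction
#'
#' Multiplies each p value by the number of comparisons in the family and
#' caps at 1: `p_i' = min(1, m * p_i)` with `m = length(p_values)`.
#'
#' @param p_values numeric vector of raw p values in `[0, 1]`.
#' @return adjusted p values.
#' @export
bonferroni_adjust <- function(p_values) {
  if (!is.numeric(p_values) || any(!is.finite(p_values)) ||
      any(p_values < 0 | p_values > 1))
    stop_input("p values must lie in [0, 1]")
  pmin(1, length(p_values) * p_values)
}

#' One-way ANOVA with Tukey HSD post-hoc comparisons
#'
#' Omnibus F test across groups followed by all pairwise Tukey honest
#' significant difference comparisons (studentized-range p values, which are
#' family-adjusted by construction).
#'
#' @param groups named list of numeric samples, each with >= 2 observations.
#' @param alpha significance level recorded with the results.
#' @return `StatsResult` data frame: first row the omnibus F, then one row
#'   per pair (statistic = difference of means, `p_adjusted` = Tukey p).
#' @export
anova_tukey <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2L)
    stop_input("groups must be a list of >= 2 samples")
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop_input("each group needs >= 2 observations")
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), vapply(groups, length, integer(1)))))
  fit <- stats::aov(value ~ group, data = df)
  tab <- summary(fit)[[1]]
  Fval <- tab[["F value"]][1]
  pF <- tab[["Pr(>F)"]][1]
  if (is.nan(Fval)) { Fval <- 0; pF <- 1 } # zero within- and between-variance
  out <- stats_result("anova_F", "omnibus", statistic = Fval, p_raw = pF,
                      n_per_group = paste(vapply(groups, length, integer(1)),
                                          collapse = ","))
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$group
  pair <- stats_result("tukey_hsd", rownames(tk), statistic = tk[, "diff"],
                       p_raw = tk[, "p adj"], p_adjusted = tk[, "p adj"],
                       adjustment_method = "tukey_hsd",
                       n_per_group = out$n_per_group)
  rownames(pair) <- NULL
  rbind(out, pair)
}

#' Ordinary least-squares regression of intensity on inclusion count
#'
#' Fits `y = intercept + slope * x` and tests the slope against zero with a
#' t statistic on `n - 2` degrees of freedom. Used for the reference-protein
#' immunoreactivity versus inclusion-count relationship.
#'
#' @param x predictor (e.g. per-nucleus inclusion counts), not constant.
#' @param y response (e.g. per-nucleus reference-channel intensity or Z).
#' @return one-row data frame: `slope`, `intercept`, `r_squared`, `p_slope`,
#'   `n`.
#' @export
linear_regression <- function(x, y) {
  if (length(x) != length(y)) stop_input("x and y lengths differ")
  if (length(x) < 3L) stop_input("need n >= 3 observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop_input("inputs must be finite")
  if (stats::sd(x) == 0) stop_input("x is constant; slope is undefined")
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit)) # perfect fits trip a benign warning
  data.frame(slope = unname(stats::coef(fit)[2]),
             intercept = unname(stats::coef(fit)[1]),
             r_squared = sm$r.squared,
             p_slope = sm$coefficients[2, 4],
             n = length(x))
}

#' Two-sample proportion test with exact fallback
#'
#' Compares `k1/n1` against `k2/n2` with the two-sided pooled-variance z
#' test. When any expected 2x2 cell count under the pooled proportion is
#' 5 or less, the normal approximation is unreliable and Fisher's exact test
#' is used instead (the result is labeled accordingly).
#'
#' @param k1,n1,k2,n2 successes and totals (`0 <= k <= n`, `n >= 1`).
#' @param comparison label stored in the result.
#' @return a one-row `StatsResult`; `statistic` is z (or `NA` for Fisher).
#' @export
two_proportion_test <- function(k1, n1, k2, n2, comparison = "p1 vs p2") {
  for (v in list(k1, n1, k2, n2))
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop_input("counts must be single non-negative numbers")
  if (k1 > n1 || k2 > n2) stop_input("successes cannot exceed totals")
  if (n1 < 1 || n2 < 1) stop_input("totals must be >= 1")
  pp <- (k1 + k2) / (n1 + n2)
  expected <- c(n1 * pp, n1 * (1 - pp), n2 * pp, n2 * (1 - pp))
  npg <- paste(n1, n2, sep = ",")
  if (any(expected <= 5)) {
    tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2)
    p <- stats::fisher.test(tab)$p.value
    return(stats_result("fisher_exact", comparison, statistic = NA_real_,
                        p_raw = p, n_per_group = npg))
  }
  d <- k1 / n1 - k2 / n2
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- if (d == 0) 0 else d / se
  stats_result("two_proportion_z", comparison, statistic = z,
               p_raw = min(1, 2 * stats::pnorm(-abs(z))), n_per_group = npg)
}

sem <- function(x) if (length(x) < 2L) NA_real_ else stats::sd(x) / sqrt(length(x))

#' Table-style per-group summary of a study
#'
#' Aggregates per-field cell counts and per-nucleus inclusion counts into
#' the summary schema used for tissue immunohistochemistry: subjects, total
#' cells, mean/SEM cells per field, and mean/SEM inclusions per cell.
#' The cells-per-field SEM is over fields; the inclusions-per-cell SEM is
#' over cells (both denominators are recorded in the column names'
#' documentation since summary tables of this kind rarely state them).
#'
#' @param field_table data frame with one row per field: `field_id`,
#'   `subject_id`, `cell_count`.
#' @param nucleus_table optional data frame with one row per cell carrying
#'   `focus_count` and, when available, an externally supplied
#'   `cytoplasmic_count` column (cytoplasmic inclusions are counted
#'   manually, outside this pipeline). `NULL` leaves the per-cell statistics
#'   `NA`.
#' @param group_label label for the output row.
#' @return one-row data frame (`GroupSummary`).
#' @export
summarize_group <- function(field_table, nucleus_table = NULL,
                            group_label = "group") {
  stopifnot(is.data.frame(field_table))
  if (!nrow(field_table)) stop_input("field_table has zero fields")
  if (!all(c("subject_id", "cell_count") %in% names(field_table)))
    stop_input("field_table needs subject_id and cell_count columns")
  nuc_mean <- nuc_sem <- cyt_mean <- cyt_sem <- NA_real_
  if (!is.null(nucleus_table) && nrow(nucleus_table)) {
    stopifnot("focus_count" %in% names(nucleus_table))
    nuc_mean <- mean(nucleus_table$focus_count)
    nuc_sem <- sem(nucleus_table$focus_count)
    if ("cytoplasmic_count" %in% names(nucleus_table)) {
      cyt_mean <- mean(nucleus_table$cytoplasmic_count)
      cyt_sem <- sem(nucleus_table$cytoplasmic_count)
    }
  }
  data.frame(group_label = group_label,
             n_subjects = length(unique(field_table$subject_id)),
             n_fields = nrow(field_table),
             total_cells = sum(field_table$cell_count),
             mean_cells_per_field = mean(field_table$cell_count),
             sem_cells_per_field = sem(field_table$cell_count),
             mean_nuclear_inclusions_per_cell = nuc_mean,
             sem_nuclear_inclusions_per_cell = nuc_sem,
             mean_cytoplasmic_inclusions_per_cell = cyt_mean,
             sem_cytoplasmic_inclusions_per_cell = cyt_sem)
}
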