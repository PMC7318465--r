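options(nsbquant.verbose = FALSE)

test_that("Mann-Whitney exact p matches enumeration on the worked examples", {
  r1 <- mann_whitney(1, 2, mode = "exact")
  expect_equal(r1$statistic, 0)
  expect_equal(r1$p_raw, 1.0)
  r2 <- mann_whitney(c(1, 2), c(3, 4), mode = "exact")
  expect_equal(r2$statistic, 0)
  expect_equal(r2$p_raw, 2 / 6)
  expect_error(mann_whitney(numeric(0), 1), "non-empty")
})

test_that("Mann-Whitney exact p equals the enumeration oracle over a seeded grid", {
  set.seed(103)
  for (rep in 1:30) {
    n1 <- sample(1:5, 1); n2 <- sample(1:5, 1)
    # half the draws from a small integer support to force ties
    if (rep %% 2 == 0) {
      x <- sample(0:3, n1, replace = TRUE); y <- sample(0:3, n2, replace = TRUE)
    } else {
      x <- rnorm(n1); y <- rnorm(n2)
    }
    got <- mann_whitney(x, y, mode = "exact")$p_raw
    expect_equal(got, mwu_enumeration_oracle(x, y))
  }
})

test_that("Mann-Whitney agrees with wilcox.test where both are defined", {
  set.seed(107)
  # tie-free exact
  for (rep in 1:5) {
    x <- rnorm(5); y <- rnorm(6)
    got <- mann_whitney(x, y, mode = "exact")
    ref <- wilcox.test(x, y, exact = TRUE)
    expect_equal(got$statistic, unname(ref$statistic))
    expect_equal(got$p_raw, ref$p.value)
  }
  # large-sample normal with ties: tie-corrected, continuity-corrected
  x <- rpois(40, 2); y <- rpois(45, 3)
  got <- mann_whitney(x, y, mode = "normal")
  ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(got$p_raw, ref$p.value, tolerance = 1e-10)
})

test_that("Bonferroni correction multiplies, caps, and matches p.adjust", {
  expect_equal(bonferroni_adjust(0.03), 0.03)
  expect_equal(bonferroni_adjust(c(0.01, 0.04)), c(0.02, 0.08))
  expect_equal(bonferroni_adjust(c(0.6, 0.7)), c(1, 1))
  expect_error(bonferroni_adjust(c(0.5, 1.2)), "0, 1")
  set.seed(109)
  for (i in 1:5) {
    p <- runif(sample(2:8, 1))
    expect_equal(bonferroni_adjust(p), p.adjust(p, "bonferroni"))
  }
  # monotone in the input
  p <- sort(runif(6))
  expect_true(all(diff(bonferroni_adjust(p)) >= 0))
})

test_that("ANOVA + Tukey: degenerate, separated, and two-group equivalence", {
  res0 <- anova_tukey(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(res0$statistic[1], 0)
  expect_equal(res0$p_raw[1], 1)
  set.seed(113)
  res1 <- anova_tukey(list(a = c(0, 0, 0) + rnorm(3, 0, 1e-3),
                           b = c(10, 10, 10) + rnorm(3, 0, 1e-3)))
  expect_lt(res1$p_raw[1], 1e-6)
  # for two groups Tukey HSD reduces to the pooled-variance comparison
  # through the studentized range: q = |t| * sqrt(2)
  x <- rnorm(8); y <- rnorm(9, 1)
  res2 <- anova_tukey(list(x = x, y = y))
  tt <- t.test(x, y, var.equal = TRUE)
  q <- abs(tt$statistic) * sqrt(2)
  p_tukey <- ptukey(q, nmeans = 2, df = 15, lower.tail = FALSE)
  expect_equal(res2$p_adjusted[2], unname(p_tukey), tolerance = 1e-9)
  expect_equal(res2$p_raw[1], tt$p.value, tolerance = 1e-9) # omnibus F == t^2
  expect_error(anova_tukey(list(a = 1, b = c(1, 2))), ">= 2 observations")
})

test_that("linear regression matches hand least squares and recovers sign", {
  r1 <- linear_regression(c(0, 1, 2), c(0, 1, 2))
  expect_equal(r1$slope, 1)
  expect_equal(r1$intercept, 0, tolerance = 1e-12)
  expect_equal(r1$r_squared, 1)
  r2 <- linear_regression(c(0, 1, 2), c(1, 1, 3))
  expect_equal(r2$slope, 1)
  expect_equal(r2$intercept, 2 / 3, tolerance = 1e-12)
  expect_error(linear_regression(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(linear_regression(c(1, 2), c(1, 2)), "n >= 3")
  # negative coupling recovered as a significantly negative slope
  set.seed(127)
  k <- rpois(150, 2)
  y <- 0.55 - 0.04 * k + rnorm(150, 0, 0.04)
  fit <- linear_regression(k, y)
  expect_lt(fit$slope, 0)
  expect_lt(fit$p_slope, 0.05)
  expect_equal(fit$slope, -0.04, tolerance = 0.25)
})

test_that("two-proportion test: z on large counts, Fisher on sparse ones", {
  r0 <- two_proportion_test(50, 100, 50, 100)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_raw, 1)
  # hypergeometric oracle for the all-or-none table
  r1 <- two_proportion_test(0, 10, 10, 10)
  expect_equal(r1$test_name, "fisher_exact")
  expect_equal(r1$p_raw, 2 * dhyper(0, 10, 10, 10), tolerance = 1e-12)
  # pooled z is the square root of the (uncorrected) chi-square statistic
  r2 <- two_proportion_test(30, 100, 52, 110)
  tab <- matrix(c(30, 70, 52, 58), 2)
  expect_equal(r2$test_name, "two_proportion_z")
  expect_equal(r2$p_raw, chisq.test(tab, correct = FALSE)$p.value,
               tolerance = 1e-12)
  # and agrees with the continuity-corrected chi-square to ~0.01 here
  expect_lt(abs(r2$p_raw - chisq.test(tab, correct = TRUE)$p.value), 0.01)
  expect_error(two_proportion_test(5, 3, 1, 10), "exceed")
})

test_that("group summaries reproduce the published cells-per-field arithmetic", {
  # 4,145 cells over 10 subjects x 8 fields -> 51.81 cells/field
  mk_fields <- function(total, subjects, per = 8) {
    n <- subjects * per
    base <- rep(total %/% n, n)
    base[seq_len(total %% n)] <- base[seq_len(total %% n)] + 1
    data.frame(field_id = sprintf("f%03d", seq_len(n)),
               subject_id = rep(sprintf("s%02d", seq_len(subjects)), each = per),
               cell_count = base)
  }
  ctrl <- summarize_group(mk_fields(4145, 10), group_label = "Control")
  expect_equal(ctrl$total_cells, 4145)
  expect_equal(round(ctrl$mean_cells_per_field, 2), 51.81)
  ad <- summarize_group(mk_fields(1590, 5), group_label = "AD")
  expect_equal(round(ad$mean_cells_per_field, 2), 39.75)
  # zero-cell field: totals zero, per-cell statistics empty-marked
  z <- summarize_group(data.frame(field_id = "f", subject_id = "s",
                                  cell_count = 0),
                       data.frame(focus_count = integer(0)))
  expect_equal(z$total_cells, 0)
  expect_equal(z$mean_cells_per_field, 0)
  expect_true(is.na(z$mean_nuclear_inclusions_per_cell))
  expect_error(summarize_group(data.frame()), "zero fields")
})

test_that("summaries conserve totals and per-cell means from nucleus tables", {
  set.seed(131)
  fields <- data.frame(field_id = sprintf("f%d", 1:8),
                       subject_id = rep(c("s1", "s2"), each = 4),
                       cell_count = rpois(8, 40))
  nuclei <- data.frame(
    field_id = rep(fields$field_id, fields$cell_count),
    focus_count = rpois(sum(fields$cell_count), 1.2),
    cytoplasmic_count = rbinom(sum(fields$cell_count), 1, 0.05))
  s <- summarize_group(fields, nuclei, "g")
  expect_equal(s$total_cells, sum(fields$cell_count))
  expect_equal(s$n_subjects, 2)
  expect_equal(s$mean_nuclear_inclusions_per_cell, mean(nuclei$focus_count))
  expect_equal(s$sem_nuclear_inclusions_per_cell,
               sd(nuclei$focus_count) / sqrt(nrow(nuclei)))
  expect_equal(s$mean_cytoplasmic_inclusions_per_cell,
               mean(nuclei$cytoplasmic_count))
  expect_equal(s$sem_cells_per_field, sd(fields$cell_count) / sqrt(8))
})

test_that("ordered inclusion burdens are recovered by pairwise tests", {
  # draw per-cell counts at the four preset burdens (the generator's count
  # model) at study scale and check every pairwise comparison separates them
  set.seed(137)
  pars <- list(control = c(0.60, 1.100), AD = c(0.44, 1.750),
               ALS = c(0.35, 2.292), FTLD = c(0.20, 2.975))
  counts <- lapply(pars, function(p) rzip(700, p[1], p[2]))
  means <- vapply(counts, mean, numeric(1))
  expect_true(all(diff(means) > 0)) # control < AD < ALS < FTLD
  pairs <- combn(names(pars), 2, simplify = FALSE)
  p <- vapply(pairs, function(pr)
    mann_whitney(counts[[pr[1]]], counts[[pr[2]]],
                 comparison = paste(pr, collapse = " vs "))$p_raw, numeric(1))
  expect_true(all(bonferroni_adjust(p) < 0.05))
})
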