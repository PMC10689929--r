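# Contingency and rank-sum engines against enumeration oracles, plus the
# two study-specific constructions.

test_that("fisher enrichment handles balanced, extreme and zero tables", {
  bal <- fisher_enrichment(matrix(c(5, 5, 5, 5), 2))
  expect_equal(bal$odds_ratio_sample, 1)
  expect_equal(bal$p_two_sided, 1)

  t2 <- matrix(c(10, 2, 5, 10), 2, byrow = TRUE)
  r2 <- fisher_enrichment(t2)
  expect_equal(r2$odds_ratio_sample, 10)
  expect_equal(r2$p_two_sided, oracle_fisher_p(t2), tolerance = 1e-12)
  expect_true(r2$ci_low <= r2$odds_ratio_cmle &&
              r2$odds_ratio_cmle <= r2$ci_high)

  # Haldane--Anscombe 0.5 correction on a zero cell
  r0 <- fisher_enrichment(matrix(c(0, 5, 5, 5), 2, byrow = TRUE))
  expect_equal(r0$odds_ratio_sample, (0.5 * 5.5) / (5.5 * 5.5))
  expect_gt(r0$odds_ratio_sample, 0)

  expect_error(fisher_enrichment(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "degenerate")
  expect_error(fisher_enrichment(matrix(c(1.5, 1, 1, 1), 2)), "integer")
})

test_that("row swap inverts the odds ratio and preserves the p-value", {
  set.seed(21)
  for (rep in 1:25) {
    tab <- matrix(rpois(4, 6) + 1, 2)
    swapped <- tab[2:1, ]
    a <- fisher_enrichment(tab)
    b <- fisher_enrichment(swapped)
    expect_equal(a$odds_ratio_sample, 1 / b$odds_ratio_sample,
                 tolerance = 1e-12)
    expect_equal(a$p_two_sided, b$p_two_sided, tolerance = 1e-12)
    expect_equal(a$p_two_sided, oracle_fisher_p(tab), tolerance = 1e-10)
  }
})

test_that("rank-sum comparisons match enumeration and are rank-invariant", {
  same <- wilcoxon_ranksum(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_two_sided, 1)

  sep <- wilcoxon_ranksum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$p_two_sided, 0.1)          # 2/20 orderings
  expect_equal(sep$method, "exact")

  # shifting both samples leaves the p-value unchanged
  a <- c(0.3, 1.9, 4.4, 2.2); b <- c(1.1, 5.3, 6.7)
  expect_equal(wilcoxon_ranksum(a + 13, b + 13)$p_two_sided,
               wilcoxon_ranksum(a, b)$p_two_sided)

  # exact p equals the full rank-assignment enumeration, several sizes
  set.seed(31)
  for (sizes in list(c(3, 3), c(4, 5), c(6, 6), c(2, 9))) {
    x <- sample(seq_len(50), sizes[1])
    y <- sample(setdiff(seq_len(50), x), sizes[2])
    got <- wilcoxon_ranksum(x, y)
    expect_equal(got$method, "exact")
    expect_equal(got$p_two_sided, oracle_wilcox_p(x, y), tolerance = 1e-12)
  }

  # large or tied samples switch to the corrected normal approximation
  big <- wilcoxon_ranksum(rnorm(15), rnorm(15))
  expect_equal(big$method, "normal_approx")
  expect_error(wilcoxon_ranksum(numeric(0), 1:3), "non-empty")
})

test_that("bonferroni caps and scales", {
  expect_equal(bonferroni(c(0.01, 0.02, 0.03)), c(0.03, 0.06, 0.09))
  expect_equal(bonferroni(0.5), 0.5)
  expect_equal(bonferroni(c(0.4, 0.001), m = 10), c(1, 0.01))
  expect_error(bonferroni(1.2), "\\[0, 1\\]")
  # adjusted never below raw
  p <- runif(20)
  expect_true(all(bonferroni(p, m = 7) >= p | p > 1 / 7))
})

test_that("severity-by-activity builds the right table and drops 'other'", {
  patients <- tibble::tibble(
    activity_group = c(rep("complete_lof", 6), rep("moderate_lof", 5),
                       rep("wildtype_like", 5), "complete_lof", NA),
    severity = c(rep("severe", 5), "non_severe",
                 rep(c("severe", "non_severe"), c(2, 3)),
                 rep("non_severe", 5), "other", "severe"))
  res <- severity_by_activity(patients)
  expect_equal(unname(res$table["complete_lof", ]), c(5, 1))
  expect_equal(unname(res$table["moderate_or_wildtype", ]), c(2, 8))
  expect_equal(res$n_excluded_other, 1)
  expect_equal(res$n_excluded_unscored, 1)
  expect_gt(res$odds_ratio_sample, 1)

  all_severe <- tibble::tibble(
    activity_group = c("complete_lof", "wildtype_like"),
    severity = c("severe", "severe"))
  expect_error(severity_by_activity(all_severe), "degenerate")
})

test_that("planted severity rates are recovered by the contingency CMLE", {
  # Bernoulli generation: P(severe) 0.55 for complete-LoF carriers versus
  # 0.21 otherwise, a planted odds ratio of ~4.6
  planted <- (0.55 / 0.45) / (0.21 / 0.79)
  set.seed(41)
  reps <- 400
  ors <- replicate(reps, {
    patients <- tibble::tibble(
      activity_group = rep(c("complete_lof", "moderate_lof"), c(60, 120)),
      severity = ifelse(
        stats::rbinom(180, 1, rep(c(0.55, 0.21), c(60, 120))) == 1,
        "severe", "non_severe"))
    severity_by_activity(patients)$odds_ratio_cmle
  })
  lo <- stats::quantile(log(ors), 0.025)
  hi <- stats::quantile(log(ors), 0.975)
  expect_gt(log(planted), lo)
  expect_lt(log(planted), hi)
  expect_equal(median(ors), planted, tolerance = 0.25)
})

test_that("domain enrichment is null on identical sets, excludes unassigned", {
  m <- domain_map(tibble::tibble(
    start_pos = c(1, 11), end_pos = c(10, 20),
    domain_label = c("TM1/6", "EL4")))
  v <- tibble::tibble(pos = c(1:8, 11:14), ref_aa = "A", alt_aa = "V")
  res <- domain_enrichment(v, v, m)
  expect_true(all(abs(res$odds_ratio_sample - 1) < 1e-12))
  expect_true(all(res$p == 1))
  expect_equal(res$m, rep(2L, 2))

  # positions outside the map drop out of both margins
  v2 <- dplyr::bind_rows(v, tibble::tibble(pos = c(50, 60), ref_aa = "A",
                                           alt_aa = "V"))
  res2 <- domain_enrichment(v2, v2, m)
  expect_equal(res2$n_patient_in + res2$n_patient_out, rep(12L, 2))

  # unique-variant level deduplicates recurrent variants
  v3 <- dplyr::bind_rows(v, v[1, ], v[1, ])
  res3 <- domain_enrichment(v3, v, m, level = "unique_variant")
  expect_equal(res3$n_patient_in + res3$n_patient_out, rep(12L, 2))
  res4 <- domain_enrichment(v3, v, m, level = "patient")
  expect_equal(res4$n_patient_in + res4$n_patient_out, rep(14L, 2))
})

test_that("distance comparisons cover all pairs with logged correction", {
  set.seed(51)
  df <- tibble::tibble(
    activity_group = rep(c("complete_lof", "moderate_lof", "wildtype_like"),
                         each = 12),
    d_ligand = c(rnorm(12, 8), rnorm(12, 11), rnorm(12, 15)))
  cmp <- distance_group_comparison(df, "d_ligand")
  expect_equal(nrow(cmp), 3)
  expect_equal(cmp$m, rep(3L, 3))
  expect_true(all(cmp$p_bonferroni >= cmp$p))
  expect_true(all(cmp$p_bonferroni <= 1))
  i <- cmp$group_a == "complete_lof" & cmp$group_b == "wildtype_like"
  expect_lt(cmp$mean_a[i], cmp$mean_b[i])
})
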