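test_that("Mann-Whitney U and exact p match hand-checkable cases", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)              # 2/20 rank assignments as extreme
  expect_identical(r$method, "exact")

  # swapping the samples leaves p unchanged
  r2 <- mann_whitney(c(4, 5, 6), c(1, 2, 3))
  expect_equal(r2$U, 9)
  expect_equal(r2$p, r$p)

  # identical samples under the tie-corrected approximation
  r3 <- mann_whitney(c(5, 7, 9), c(5, 7, 9))
  expect_identical(r3$method, "normal_approx")
  expect_equal(r3$p, 1)

  expect_error(mann_whitney(numeric(0), 1), "non-empty")
})

test_that("exact branch equals exhaustive enumeration for all n <= 10 splits", {
  set.seed(23)
  for (nx in 1:5) {
    for (ny in nx:(10 - nx)) {
      vals <- sample(seq_len(40), nx + ny)   # distinct -> tie-free
      x <- vals[seq_len(nx)]
      y <- vals[-seq_len(nx)]
      expect_equal(mann_whitney(x, y)$p, mwu_enum_p(x, y),
                   info = sprintf("nx=%d ny=%d", nx, ny))
    }
  }
})

test_that("Kruskal-Wallis matches hand computation and stats::kruskal.test", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(round(kw$H, 3), 3.857)
  expect_equal(kw$p, 0.0495, tolerance = 1e-3)

  expect_equal(kruskal_wallis(list(c(1, 4), c(2, 3)))$H, 0)
  expect_equal(kruskal_wallis(list(c(1, 4), c(2, 3)))$p, 1)

  # two groups, no ties: equivalent to the MWU normal approximation
  set.seed(29)
  x <- rnorm(12); y <- rnorm(15) + 0.5
  kw2 <- kruskal_wallis(list(x, y))
  mw <- mann_whitney(x, y, exact = FALSE, correct = FALSE)
  expect_equal(kw2$p, mw$p, tolerance = 1e-6)

  # tie-corrected H agrees with the reference implementation
  set.seed(31)
  g <- list(sample(1:5, 8, TRUE), sample(1:5, 9, TRUE), sample(1:5, 7, TRUE))
  ref <- stats::kruskal.test(unlist(g), rep(1:3, lengths(g)))
  kw3 <- kruskal_wallis(g)
  expect_equal(kw3$H, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(kw3$p, ref$p.value, tolerance = 1e-12)

  expect_error(kruskal_wallis(list(c(1, 1), c(1, 1, 1))), "identical")
  expect_error(kruskal_wallis(list(1)), "2 non-empty")
})

test_that("BH adjustment reproduces the published per-electrode table", {
  adj <- bh_fdr(table3_p)
  expect_equal(round_half_up(adj, 3), table3_p_fdr)
  # the six smallest all collapse to 0.048 and P9 stays at its raw value
  expect_equal(unname(round_half_up(adj["P10"], 3)), 0.048)
  expect_equal(unname(adj["P9"]), 0.222)
})

test_that("BH equals the brute-force step-up definition", {
  expect_equal(bh_fdr(0.3), 0.3)              # single p unchanged
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04, 0.05)), rep(0.05, 5))
  set.seed(37)
  for (i in 1:250) {
    n <- sample(1:50, 1)
    p <- round(runif(n), sample(c(1, 2, 3, 6), 1))  # induce ties sometimes
    expect_equal(bh_fdr(p), bh_brute(p), tolerance = 1e-12)
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Lilliefors normality screen separates normal from lognormal", {
  normal_ok <- 0; lognormal_flagged <- 0
  for (s in 1:50) {
    set.seed(s)
    if (ks_normality(rnorm(1000))$is_normal) normal_ok <- normal_ok + 1
    if (!ks_normality(rlnorm(1000))$is_normal) {
      lognormal_flagged <- lognormal_flagged + 1
    }
  }
  expect_gte(normal_ok, 45)          # >= 90% of seeds
  expect_gte(lognormal_flagged, 48)  # >= 95% of seeds
  r <- ks_normality(rnorm(50))
  expect_gte(r$statistic, 0); expect_lte(r$statistic, 1)
  expect_error(ks_normality(rep(2, 10)), "degenerate")
  expect_error(ks_normality(rnorm(4)), "n >= 5")
})

test_that("compare_groups assembles medians, IQRs, MWU and ROI-family FDR", {
  tab <- make_metric_table(seed = 41)
  cmp <- compare_groups(tab)
  expect_s3_class(cmp, "group_comparison")
  expect_identical(cmp$table$electrode, roi_electrodes())
  expect_equal(cmp$table$p_fdr, bh_fdr(cmp$table$p_raw))
  expect_true(all(cmp$table$p_fdr >= cmp$table$p_raw))
  el <- "P3"
  v <- tab[[paste0("alpha_", el)]]
  expect_equal(cmp$table$median_case[cmp$table$electrode == el],
               median(v[tab$group == "case"]))
  q <- quantile(v[tab$group == "control"], c(.25, .75), type = 7)
  expect_equal(cmp$table$iqr_control[cmp$table$electrode == el],
               unname(q[2] - q[1]))
  # identical groups: p ~ 1 everywhere, nothing significant
  tab2 <- tab
  tab2[tab2$group == "control", -(1:3)] <- tab2[tab2$group == "case", -(1:3)]
  cmp2 <- compare_groups(tab2)
  expect_true(all(cmp2$table$p_raw >= 0.9))
  expect_false(any(cmp2$table$p_fdr < 0.05))
  expect_true(cmp2$nonconfirmatory)
})

test_that("compare_groups is invariant to row order and common rescaling", {
  tab <- make_metric_table(seed = 43, shift = c(rep(0.6, 4), rep(1, 7)))
  cmp <- compare_groups(tab)
  perm <- tab[sample(nrow(tab)), ]
  cmp_perm <- compare_groups(perm)
  expect_equal(cmp_perm$table$p_raw, cmp$table$p_raw)
  expect_equal(cmp_perm$omnibus_p, cmp$omnibus_p)
  scaled <- tab
  ac <- grep("^alpha_", names(scaled))
  scaled[, ac] <- scaled[, ac] * 1e4
  cmp_scaled <- compare_groups(scaled)
  expect_equal(cmp_scaled$table$p_raw, cmp$table$p_raw)
  expect_equal(cmp_scaled$table$p_fdr, cmp$table$p_fdr)
  expect_equal(cmp_scaled$table$median_case, 1e4 * cmp$table$median_case)
})

test_that("comparison output formats round to 3 decimals half-up", {
  tab <- make_metric_table(seed = 47)
  cmp <- compare_groups(tab)
  fmt <- format(cmp)
  expect_named(fmt, c("Electrode", "Median case", "Median control",
                      "IQR case", "IQR control", "p", "p_FDR"))
  expect_equal(fmt$p, round_half_up(cmp$table$p_raw, 3))
  expect_equal(round_half_up(0.1045, 3), 0.105)  # half-up, not half-even
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_comparison(cmp, f1)
  write_comparison(cmp, f2)
  expect_equal(nrow(read.delim(f1)), 11)
  expect_equal(length(jsonlite::read_json(f2)$table), 11)
})

test_that("IAF comparison gates post-hoc tests on the omnibus", {
  tab <- make_metric_table(seed = 53)
  res <- iaf_comparison(tab)
  expect_setequal(unique(res$summaries$electrode), c("O1", "O2"))
  expect_true(all(c("median", "min", "max", "iqr") %in% names(res$summaries)))
  # identical IAF distributions: omnibus rarely significant, and when not,
  # the post-hoc table stays empty
  if (all(res$omnibus$p >= 0.05)) expect_equal(nrow(res$posthoc), 0)

  # strong stratified effect -> omnibus fires and post-hoc rows appear
  tab2 <- tab
  sel <- tab2$group == "case" & !tab2$migraine
  tab2$iaf_O1[sel] <- tab2$iaf_O1[sel] + 3
  res2 <- iaf_comparison(tab2)
  expect_lt(res2$omnibus$p[res2$omnibus$electrode == "O1"], 0.05)
  expect_gt(nrow(res2$posthoc), 0)

  # all-migraine cohort: absent stratum flagged, no crash
  tab3 <- tab
  tab3$migraine <- TRUE
  res3 <- iaf_comparison(tab3)
  expect_s3_class(res3$omnibus, "data.frame")
})

test_that("cohort demographics reproduce matched-design arithmetic", {
  mf <- data.frame(
    subject_id = sprintf("s%d", 1:42),
    group = rep(c("case", "control"), each = 21),
    age = rep(round(rnorm(21, 33, 10)), 2),
    sex = rep(rep(c("M", "F"), c(13, 8)), 2),
    migraine = rep(rep(c(TRUE, FALSE), c(14, 7)), 2),
    stringsAsFactors = FALSE
  )
  dem <- cohort_demographics(mf)
  expect_match(dem$table$case[dem$table$characteristic == "Migraine - no. (%)"],
               "14 \\(66.7\\)")
  dem_tr <- cohort_demographics(mf, percent = "truncate")
  expect_match(dem_tr$table$case[dem_tr$table$characteristic == "Migraine - no. (%)"],
               "14 \\(66.6\\)")
  # 20 of 21 -> 95.2 under both conventions
  expect_equal(round_half_up(100 * 20 / 21, 1), 95.2)
  # identical age vectors: t = 0, p = 1, symmetric CI, df = 40
  expect_equal(dem$age_test$t, 0)
  expect_equal(dem$age_test$p, 1)
  expect_equal(dem$age_test$df, 40)
  expect_equal(dem$age_test$ci[1], -dem$age_test$ci[2])
})
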