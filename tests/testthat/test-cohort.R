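cohort_from_diffs <- function(diffs, control = 100, contrast = "T2",
                              metric = "ss_value") {
  n <- length(diffs)
  mk <- function(vals) lapply(vals, function(v) stats::setNames(v, metric))
  paired_cohort(sprintf("S%02d", seq_len(n)),
                mk(rep(control, n)), mk(control + diffs), contrast)
}

test_that("effect size from mean -13.3, sd 9.3 differences rounds to d = 1.4", {
  diffs <- moments_vector(-13.3, 9.3, 10)
  st <- paired_analysis(cohort_from_diffs(diffs), "ss_value")
  expect_equal(st$mean_diff, -13.3, tolerance = 1e-12)
  expect_equal(st$sd_diff, 9.3, tolerance = 1e-12)
  expect_equal(round(st$cohens_d, 1), 1.4)
})

test_that("identical pairs trigger the degenerate-variance error", {
  expect_error(paired_analysis(cohort_from_diffs(rep(2.5, 6)), "ss_value"),
               "degenerate variance")
})

test_that("textbook small-sample t on differences 1..5", {
  st <- paired_analysis(cohort_from_diffs(1:5), "ss_value")
  expect_equal(st$t_stat, 3 / (stats::sd(1:5) / sqrt(5)), tolerance = 1e-12)
  expect_equal(st$t_stat, 4.2426, tolerance = 1e-4)
  expect_equal(st$p_value, 2 * stats::pt(-st$t_stat, df = 4),
               tolerance = 1e-12)
  expect_equal(round(st$p_value, 4), 0.0132)
  expect_equal(st$cohens_d, 1.897, tolerance = 1e-3)
})

test_that("paired analysis matches stats::t.test as an independent oracle", {
  set.seed(5)
  for (rep in 1:5) {
    ctrl <- rnorm(10, 90, 10)
    isch <- ctrl + rnorm(10, -8, 6)
    co <- paired_cohort(sprintf("S%02d", 1:10),
                        lapply(ctrl, function(v) c(ss_value = v)),
                        lapply(isch, function(v) c(ss_value = v)), "T2")
    st <- paired_analysis(co, "ss_value")
    tt <- stats::t.test(isch, ctrl, paired = TRUE)
    one <- stats::t.test(isch - ctrl)
    expect_equal(st$t_stat, unname(tt$statistic), tolerance = 1e-12)
    expect_equal(st$p_value, tt$p.value, tolerance = 1e-12)
    expect_equal(st$ci95_low, tt$conf.int[1], tolerance = 1e-12)
    expect_equal(st$ci95_high, tt$conf.int[2], tolerance = 1e-12)
    expect_equal(st$t_stat, unname(one$statistic), tolerance = 1e-12)
  }
})

test_that("d and t are invariant under affine unit changes of both arms", {
  set.seed(17)
  ctrl <- rnorm(10, 90, 10)
  isch <- ctrl + rnorm(10, -8, 6)
  mk <- function(a, b, vals) lapply(a * vals + b, function(v) c(ss_value = v))
  st1 <- paired_analysis(paired_cohort(1:10, mk(1, 0, ctrl), mk(1, 0, isch),
                                       "T2"), "ss_value")
  st2 <- paired_analysis(paired_cohort(1:10, mk(3.7, 12, ctrl),
                                       mk(3.7, 12, isch), "T2"), "ss_value")
  expect_equal(st2$cohens_d, st1$cohens_d, tolerance = 1e-12)
  expect_equal(st2$t_stat, st1$t_stat, tolerance = 1e-12)
})

test_that("percent change is per-subject-then-averaged", {
  ctrl <- c(100, 200)
  isch <- c(110, 180)   # +10% and -10%
  co <- paired_cohort(c("a", "b"),
                      lapply(ctrl, function(v) c(ss_value = v)),
                      lapply(isch, function(v) c(ss_value = v)), "T2")
  st <- paired_analysis(co, "ss_value")
  expect_equal(st$pct_change_mean, 0)
  expect_equal(st$pct_change_sd, stats::sd(c(10, -10)))
})

test_that("summarize_cohort covers the 4 x 6 grid and flags significance", {
  set.seed(31)
  ref <- reference_effects()
  cohorts <- lapply(CONTRASTS, function(ct) {
    sub <- ref[ref$contrast == ct, ]
    spec <- cohort_spec(10,
                        stats::setNames(sub$control_mean, sub$metric),
                        stats::setNames(sub$control_sd, sub$metric),
                        stats::setNames(sub$diff_mean, sub$metric),
                        stats::setNames(sub$diff_sd, sub$metric),
                        seed = 100 + match(ct, CONTRASTS))
    as_paired_cohort(generate_paired_cohort(spec), ct)
  })
  out <- summarize_cohort(cohorts)
  expect_equal(nrow(out), 24L)
  expect_equal(attr(out, "n_tests"), 24L)
  expect_setequal(unique(out$contrast), CONTRASTS)
  expect_setequal(unique(out$metric), MORPHOMETRY_METRICS)
  expect_identical(out$significant, out$p_value < 0.05)
  fmt <- format_summary_table(out)
  expect_equal(nrow(fmt), 24L)
  # thicknesses print at 2 decimals, relaxation times at 1
  expect_match(fmt$control[fmt$metric == "ss_thickness"][1],
               "^\\d+\\.\\d{2} ")
  expect_match(fmt$control[fmt$metric == "ss_value"][1], "^\\d+\\.\\d ")
})

test_that("missing cells are reported, not skipped", {
  co <- cohort_from_diffs(1:5)          # only ss_value present
  expect_error(summarize_cohort(list(co)), "missing or degenerate")
})

test_that("cohort generator recovers its own difference parameters", {
  spec <- cohort_spec(500, c(ss_value = 92), c(ss_value = 12),
                      c(ss_value = -13.3), c(ss_value = 9.3), seed = 8)
  tab <- generate_paired_cohort(spec)
  expect_equal(nrow(tab), 500L)
  expect_equal(mean(tab$ischemic - tab$control), -13.3,
               tolerance = 0.15)       # 3 SE at n = 500
  expect_equal(sd(tab$ischemic - tab$control), 9.3, tolerance = 0.1)
  # determinism
  expect_identical(tab, generate_paired_cohort(spec))
})

test_that("degenerate zero-sd cohorts propagate to the variance error", {
  spec <- cohort_spec(2, c(ss_value = 92), c(ss_value = 0),
                      c(ss_value = -5), c(ss_value = 0), seed = 1)
  co <- as_paired_cohort(generate_paired_cohort(spec), "T2")
  expect_error(paired_analysis(co, "ss_value"), "degenerate variance")
})
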