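# independent U for one observed split, by pair counting rather than ranks
pair_count_u <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

test_that("strategies assign the published doses to boundary patients", {
  who <- band_strategy(who_band_table(), name = "WHO")
  allo <- allometric_strategy()
  co <- tiny_cohort(25.0)
  expect_equal(assign_doses(co, who)$assigned_dose_mg, 600)
  a <- assign_doses(co, allo)
  expect_equal(a$assigned_dose_mg, 300)
  expect_equal(a$tablet_label, "2.5")
  expect_equal(a$exact_dose_mg, 600 * (25 / 70)^0.75)
  expect_equal(a$tablets, 2.5)
  # allometric band table at its first edge
  allo_tab <- band_strategy(
    build_allometric_bands(abc_model(), abc3tc_formulary()),
    name = "allometric bands")
  expect_equal(assign_doses(tiny_cohort(8.2), allo_tab)$assigned_dose_mg,
               120)
})

test_that("dose distributions count every patient and report the adult fraction", {
  allo <- allometric_strategy()
  d70 <- dose_distribution(assign_doses(tiny_cohort(rep(70, 8)), allo))
  expect_equal(d70$adult_fraction$pct_adult, 100)
  tab <- band_strategy(build_allometric_bands(abc_model(),
                                              abc3tc_formulary()))
  small <- dose_distribution(
    assign_doses(tiny_cohort(c(4.1, 5.0, 7.7, 8.2)), tab))
  expect_equal(small$histogram$tablet_label, "1")
  expect_equal(small$histogram$count, 4L)
  expect_equal(small$adult_fraction$pct_adult, 0)
  expect_equal(sum(small$histogram$count), 4L)
})

test_that("rank-sum test matches hand-enumerated exact p values", {
  t1 <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(t1$U, 0)
  expect_equal(t1$method, "exact")
  expect_equal(t1$p_value, 2 * (1 / 20))  # 2 of C(6,3)=20 splits as extreme
  t2 <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(t2$p_value, 2 / 6)
  same <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$U, 9 / 2)
  expect_equal(same$p_value, 1)
})

test_that("U and its complement always sum to n_x * n_y", {
  set.seed(21)
  for (i in 1:50) {
    x <- sample(1:8, sample(2:9, 1), replace = TRUE)
    y <- sample(1:8, sample(2:9, 1), replace = TRUE)
    t <- mann_whitney_u(x, y, method = "normal")
    expect_equal(t$U + t$U_prime, length(x) * length(y))
    expect_equal(t$U, pair_count_u(x, y))
  }
})

test_that("normal approximation agrees with the reference implementation", {
  set.seed(31)
  for (i in 1:25) {
    x <- rnorm(sample(5:40, 1))
    y <- rnorm(sample(5:40, 1), mean = 0.5)
    ours <- mann_whitney_u(x, y, method = "normal")
    ref <- suppressWarnings(
      wilcox.test(x, y, exact = FALSE, correct = TRUE))
    expect_equal(ours$p_value, unname(ref$p.value), tolerance = 1e-12)
    expect_equal(ours$U, unname(ref$statistic), tolerance = 1e-12)
  }
})

test_that("degenerate samples yield p = 1 with a warning", {
  expect_warning(t <- mann_whitney_u(rep(2, 5), rep(2, 7)),
                 "variance is zero")
  expect_equal(t$p_value, 1)
  expect_true(is.na(t$z))
})

test_that("pearson correlation handles exact fits and rejects degenerate input", {
  a <- c(1, 2, 3, 5, 8)
  expect_equal(pearson_r(a, 2 * a + 1)$r, 1)
  expect_equal(pearson_r(a, -a)$r, -1)
  r <- pearson_r(a, c(2, 1, 5, 4, 9))
  expect_equal(r$r2, r$r^2)
  expect_equal(r$r, cor(a, c(2, 1, 5, 4, 9)))
  expect_error(pearson_r(a, rep(3, 5)), "zero variance")
  expect_error(pearson_r(a, 1:3), "equal length")
  expect_error(pearson_r(1:2, 2:3), "at least 3")
})

test_that("permuted pairs show no spurious correlation", {
  set.seed(17)
  hits <- vapply(1:100, function(i) {
    a <- rnorm(1000)
    abs(pearson_r(a, sample(a))$r) < 0.1
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("comparing a strategy with itself gives no difference", {
  co <- generate_cohort(default_cohort_spec(), seed = 2)
  s <- allometric_strategy()
  s2 <- allometric_strategy(name = "allometric-2")
  cmp <- run_comparison(co, strategies = list(s, s2))
  expect_equal(diff(cmp$summary$mean), 0)
  expect_gt(cmp$test$p_value, 0.9)
})

test_that("a full comparison reports both strategies coherently", {
  co <- generate_cohort(default_cohort_spec(), seed = 5)
  cmp <- run_comparison(co)
  expect_s3_class(cmp, "strategy_comparison")
  # histogram counts sum to the cohort size per strategy
  counts <- tapply(cmp$histogram$count, cmp$histogram$strategy, sum)
  expect_true(all(counts == nrow(co)))
  expect_true(cmp$test$p_value >= 0 && cmp$test$p_value <= 1)
  expect_equal(cmp$correlation$r2, cmp$correlation$r^2)
  # nearest-policy assignment never strays more than one step from exact
  a <- cmp$assignments[cmp$assignments$strategy == "allometric", ]
  steps <- abc3tc_formulary()$steps$dose_mg
  gap <- max(diff(steps))
  expect_true(all(abs(a$assigned_dose_mg - a$exact_dose_mg) < gap))
  # JSON report round trip
  path <- withr::local_tempfile(fileext = ".json")
  write_comparison_json(cmp, path)
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(rep$test$p_value, cmp$test$p_value, tolerance = 1e-12)
  expect_equal(rep$correlation$r, cmp$correlation$r, tolerance = 1e-12)
})

test_that("a single-patient cohort yields a report with the test skipped", {
  co <- tiny_cohort(25.0)
  w <- capture_warnings(cmp <- run_comparison(co))
  expect_match(w, "skipped", all = FALSE)
  expect_null(cmp$test)
  expect_equal(nrow(cmp$summary), 2L)
  expect_true(is.na(cmp$correlation$r))
})
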