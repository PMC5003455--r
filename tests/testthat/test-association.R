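test_that("exact rank-sum p agrees with stats::wilcox.test when untied", {
  set.seed(83)
  for (rep in 1:10) {
    x <- rnorm(8); y <- rnorm(8, mean = rep %% 3)
    got <- wilcoxon_exact(x, y)$p.value
    want <- wilcox.test(x, y, exact = TRUE)$p.value
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("exact rank-sum p agrees with the bitmask oracle under ties", {
  cases <- list(
    list(x = c(3, 4, 5, 4, 3, 5, 4, 4), y = c(2, 3, 2, 3, 2, 2, 3, 3)),
    list(x = c(0, 0, 0, 1, 1, 2, 2, 2), y = c(0, 0, 1, 1, 1, 1, 2, 2)),
    list(x = rep(1, 8), y = rep(1, 8))
  )
  for (cs in cases) {
    expect_equal(wilcoxon_exact(cs$x, cs$y)$p.value,
                 oracle_wilcoxon_p(cs$x, cs$y), tolerance = 1e-12)
  }
})

test_that("rank-sum degenerate and extreme cases behave exactly", {
  expect_equal(wilcoxon_exact(rep(5, 8), rep(5, 8))$p.value, 1)
  # complete separation: the two most extreme of 12870 assignments
  p_min <- wilcoxon_exact(rep(0.30, 8) + (1:8) * 1e-9,
                          rep(0.00, 8) + (1:8) * 1e-9)$p.value
  expect_equal(p_min, 2 / 12870, tolerance = 1e-12)
  # label swap leaves the two-sided p unchanged
  x <- c(3, 4, 5, 4, 3, 5, 4, 4); y <- c(2, 3, 2, 3, 2, 2, 3, 3)
  expect_equal(wilcoxon_exact(x, y)$p.value, wilcoxon_exact(y, x)$p.value)
})

test_that("Welch p matches Student p when group spreads are equal", {
  set.seed(89)
  x <- rnorm(8)
  y <- x + 0.7  # identical sample SDs by construction
  expect_equal(welch_p(x, y),
               t.test(x, y, var.equal = TRUE)$p.value, tolerance = 1e-6)
  expect_true(is.na(welch_p(rep(1, 8), rep(1, 8))))
})

test_that("burden analysis stratifies, counts and tests per-pool loads", {
  manifest <- fixture_manifest()
  # give case pools 3,4,5,4,3,5,4,4 gain calls >= 100 kb and controls
  # 2,3,2,3,2,2,3,3; place them far apart so each is its own unique region
  case_n <- c(3, 4, 5, 4, 3, 5, 4, 4)
  ctrl_n <- c(2, 3, 2, 3, 2, 2, 3, 3)
  mk <- function(pool, k, offset) {
    if (k == 0) return(NULL)
    do.call(rbind, lapply(seq_len(k), function(i)
      fixture_call(pool_id = pool, start = offset + i * 1e6,
                   end = offset + i * 1e6 + 150000)))
  }
  calls <- do.call(rbind, c(
    lapply(1:8, function(i) mk(sprintf("case%02d", i), case_n[i], 0)),
    lapply(1:8, function(i) mk(sprintf("ctrl%02d", i), ctrl_n[i], 0))))
  b <- burden_analysis(calls, manifest)
  row <- b[b$size_min_kb == 100 & b$type == "gain", ]
  expect_equal(row$mean_per_case_pool, mean(case_n))
  expect_equal(row$mean_per_control_pool, mean(ctrl_n))
  # calls at the same offsets collapse to one unique region per slot
  expect_equal(row$n_unique_case, max(case_n))
  expect_equal(row$n_unique_control, max(ctrl_n))
  expect_equal(row$p_wilcoxon, oracle_wilcoxon_p(case_n, ctrl_n),
               tolerance = 1e-12)
  # no loss calls anywhere: loss strata are NA
  expect_true(is.na(b$p_wilcoxon[b$type == "loss" & b$size_min_kb == 500]))
  expect_equal(b$n_unique_case[b$type == "loss" & b$size_min_kb == 100], 0L)
  # identical load in both groups gives p = 1
  calls_eq <- do.call(rbind, c(
    lapply(1:8, function(i) mk(sprintf("case%02d", i), 2, 0)),
    lapply(1:8, function(i) mk(sprintf("ctrl%02d", i), 2, 0))))
  b_eq <- burden_analysis(calls_eq, manifest)
  expect_equal(b_eq$p_wilcoxon[b_eq$type == "both" & b_eq$size_min_kb == 100], 1)
  expect_warning(burden_analysis(calls, manifest[1:10, ]), "expected 8")
})

test_that("region signal test compares per-pool medians inside the region", {
  lrr <- matrix(0, 50, 16)
  lrr[21:30, 1:8] <- 0.30  # cases carry the event, controls sit at 0
  ds <- fixture_dataset(lrr)
  region <- list(chrom = "1", start = ds$markers$position[21],
                 end = ds$markers$position[30])
  st <- region_signal_test(region, ds)
  expect_equal(unname(st$case_medians), rep(0.30, 8))
  expect_equal(unname(st$control_medians), rep(0, 8))
  expect_equal(st$n_markers, 10L)
  expect_equal(st$p_wilcoxon, 2 / 12870, tolerance = 1e-12)
  # all medians equal: Wilcoxon 1, t undefined
  st0 <- region_signal_test(list(chrom = "1", start = 1, end = 5000), ds)
  expect_equal(st0$p_wilcoxon, 1)
  expect_true(is.na(st0$p_t))
  expect_error(region_signal_test(list(chrom = "9", start = 1, end = 2), ds),
               "no QC-retained markers")
})

test_that("analytic t-test power matches reference implementations", {
  # null case: power equals the significance level
  expect_equal(power_two_sample_t(0, 1, 8, 0.05), 0.05, tolerance = 1e-12)
  # against stats::power.t.test across a grid: power.t.test drops the
  # opposite-tail rejection probability, so it equals our exact two-sided
  # power minus exactly that lower-tail mass
  for (d in c(0.5, 1, 2)) for (n in c(4, 8, 20)) {
    df <- 2 * n - 2
    lower_tail <- pt(-qt(0.975, df), df, ncp = d * sqrt(n / 2))
    expect_equal(power_two_sample_t(d, 1, n, 0.05) - lower_tail,
                 power.t.test(n = n, delta = d, sd = 1,
                              sig.level = 0.05)$power, tolerance = 1e-5)
  }
  # monotone in effect size and in sample size
  pw_d <- vapply(seq(0, 3, by = 0.5), power_two_sample_t, 0,
                 sd = 1, n_per_group = 8)
  expect_true(all(diff(pw_d) > 0))
  pw_n <- vapply(c(2, 4, 8, 16, 32), function(n)
    power_two_sample_t(1, 1, n), 0)
  expect_true(all(diff(pw_n) > 0))
  expect_error(power_two_sample_t(1, 0, 8), "sd")
  expect_error(power_two_sample_t(1, 1, 8, alpha = 1.5), "alpha")
})

test_that("analytic power matches a Monte-Carlo oracle", {
  set.seed(97)
  n <- 8; delta <- 2; reps <- 20000
  rej <- mean(replicate(reps, {
    t.test(rnorm(n, delta), rnorm(n), var.equal = TRUE)$p.value < 0.05
  }))
  expect_equal(power_two_sample_t(delta, 1, n, 0.05), rej, tolerance = 0.015)
})
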