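test_that("inclusive length arithmetic reproduces printed region lengths", {
  expect_equal(region_length_kb(24193894, 24282139), 88.246)
  expect_equal(region_length_kb(13224130, 13256233), 32.104)
  expect_equal(format_kb(13224130, 13256233, digits = 2), "32.10")
  expect_equal(region_length_kb(5, 5), 0.001)
  expect_error(region_length_kb(10, 5), "start")
})

test_that("overlap_bp uses inclusive coordinates", {
  expect_equal(overlap_bp(10, 20, 15, 30), 6)
  expect_equal(overlap_bp(10, 20, 21, 30), 0)
  expect_equal(overlap_bp(10, 20, 10, 20), 11)
})

test_that("minimum-marker filter keeps calls at the 20-marker boundary", {
  calls <- rbind(fixture_call(start = 1, end = 100, n_markers = 19),
                 fixture_call(start = 200, end = 300, n_markers = 20))
  kept <- filter_min_markers(calls)
  expect_equal(kept$n_markers, 20L)
  expect_equal(nrow(filter_min_markers(calls[0, ])), 0L)
})

test_that("gain-quality filters act on gains only", {
  calls <- rbind(
    fixture_call(start = 1, end = 10, status = "gain", mean_lrr = 0.015, sd_lrr = 0.1),
    fixture_call(start = 20, end = 30, status = "gain", mean_lrr = 0.03, sd_lrr = 0.25),
    fixture_call(start = 40, end = 50, status = "gain", mean_lrr = 0.03, sd_lrr = 0.1),
    fixture_call(start = 60, end = 70, status = "loss", mean_lrr = -0.5, sd_lrr = 0.3)
  )
  kept <- filter_gain_quality(calls)
  expect_equal(kept$start, c(40, 60))
  # the two pointwise filters commute
  p <- region_filter_params()
  a <- filter_gain_quality(filter_min_markers(calls, p), p)
  b <- filter_min_markers(filter_gain_quality(calls, p), p)
  expect_identical(a, b)
})

test_that("gap-ratio merge follows the 0.2 rule and conserves markers", {
  # 100 kb + 100 kb with a 30 kb gap: 30/200 = 0.15 < 0.2 -> merge
  a <- fixture_call(start = 1, end = 100000, n_markers = 40,
                    mean_lrr = 0.04, sd_lrr = 0.05)
  b <- fixture_call(start = 130001, end = 230000, n_markers = 60,
                    mean_lrr = 0.06, sd_lrr = 0.07)
  m <- merge_gaps(rbind(a, b))
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start, m$end), c(1, 230000))
  expect_equal(m$n_markers, 100L)

  # 50 kb gap: 50/200 = 0.25 -> keep apart
  b2 <- b; b2$start <- 150001; b2$end <- 250000
  expect_equal(nrow(merge_gaps(rbind(a, b2))), 2L)

  # abutting calls (gap 0) always merge
  b3 <- b; b3$start <- 100001; b3$end <- 200000
  expect_equal(nrow(merge_gaps(rbind(a, b3))), 1L)

  # different status never merges, regardless of gap
  b4 <- b3; b4$status <- "loss"
  expect_equal(nrow(merge_gaps(rbind(a, b4))), 2L)

  expect_error(merge_gaps(rbind(a, fixture_call(start = 50, end = 150))),
               "overlapping")
})

test_that("merged call statistics equal moments over the union of markers", {
  set.seed(53)
  lrr_a <- rnorm(30, 0.05, 0.03)
  lrr_b <- rnorm(45, 0.07, 0.04)
  a <- fixture_call(start = 1, end = 1000, n_markers = 30,
                    mean_lrr = mean(lrr_a), sd_lrr = sd(lrr_a))
  b <- fixture_call(start = 1100, end = 2100, n_markers = 45,
                    mean_lrr = mean(lrr_b), sd_lrr = sd(lrr_b))
  m <- merge_gaps(rbind(a, b))
  expect_equal(m$mean_lrr, mean(c(lrr_a, lrr_b)))
  expect_equal(m$sd_lrr, sd(c(lrr_a, lrr_b)))
})

test_that("gap merging is idempotent and chains through merged calls", {
  calls <- do.call(rbind, lapply(0:4, function(k)
    fixture_call(start = 1 + k * 12000, end = 10000 + k * 12000,
                 n_markers = 25)))  # gaps 1999, ratio ~0.1 each
  m1 <- merge_gaps(calls)
  expect_equal(nrow(m1), 1L)
  expect_identical(merge_gaps(m1), m1)
  expect_equal(m1$n_markers, sum(calls$n_markers))
})

test_that("cross-pool union matches the transitive-closure oracle", {
  set.seed(61)
  manifest <- fixture_manifest()
  for (rep in 1:20) {
    k <- sample(2:20, 1)
    starts <- sample(1:5000, k) * 100
    calls <- do.call(rbind, lapply(seq_len(k), function(i)
      fixture_call(pool_id = sample(manifest$pool_id, 1),
                   chrom = sample(c("1", "2"), 1),
                   start = starts[i],
                   end = starts[i] + sample(100:20000, 1),
                   status = sample(c("gain", "loss"), 1))))
    got <- union_regions(calls, manifest)
    comp <- oracle_union_clusters(calls)
    expect_equal(nrow(got), length(unique(comp)))
    # each oracle cluster's span appears exactly once in the output
    for (cl in unique(comp)) {
      m <- calls[comp == cl, ]
      hit <- got$chrom == m$chrom[1] & got$start == min(m$start) &
        got$end == max(m$end)
      expect_equal(sum(hit), 1L)
      row <- got[hit, ]
      expect_equal(row$case_count + row$control_count,
                   length(unique(m$pool_id)))
    }
    # invariance to input row order
    got_shuf <- union_regions(calls[sample(k), ], manifest)
    expect_equal(got_shuf, got, ignore_attr = TRUE)
  }
})

test_that("union records presence, statuses and group counts", {
  manifest <- fixture_manifest()
  same <- rbind(fixture_call(pool_id = "case01", start = 100, end = 200),
                fixture_call(pool_id = "case02", start = 100, end = 200))
  r <- union_regions(same, manifest)
  expect_equal(nrow(r), 1L)
  expect_equal(r$case_count, 2L)
  expect_equal(r$control_count, 0L)
  expect_equal(r$case01, "gain")
  expect_equal(r$ctrl01, "absent")

  # overlapping case/control calls of different status form one region
  cc <- rbind(fixture_call(pool_id = "case01", start = 100000, end = 200000,
                           status = "loss"),
              fixture_call(pool_id = "ctrl03", start = 150000, end = 250000,
                           status = "gain"))
  r2 <- union_regions(cc, manifest)
  expect_equal(nrow(r2), 1L)
  expect_equal(c(r2$start, r2$end), c(100000, 250000))
  expect_equal(c(r2$case_count, r2$control_count), c(1L, 1L))
  expect_equal(r2$case_status, "loss")
  expect_equal(r2$control_status, "gain")

  # 1 bp of separation is not an overlap
  apart <- rbind(fixture_call(pool_id = "case01", start = 100, end = 200),
                 fixture_call(pool_id = "case02", start = 202, end = 300))
  expect_equal(nrow(union_regions(apart, manifest)), 2L)
  # but sharing a single base is
  abut <- rbind(fixture_call(pool_id = "case01", start = 100, end = 200),
                fixture_call(pool_id = "case02", start = 200, end = 300))
  expect_equal(nrow(union_regions(abut, manifest)), 1L)

  expect_error(union_regions(fixture_call(pool_id = "ghost", start = 1, end = 2),
                             manifest), "missing from manifest")
})
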