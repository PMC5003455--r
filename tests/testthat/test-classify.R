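ref1 <- data.frame(chrom = "1", start = 150, end = 400, status = "gain",
                   source = "test", stringsAsFactors = FALSE)

test_that("reference-map membership uses any-overlap", {
  r <- fixture_region(start = 100, end = 200)
  expect_true(in_reference_map(r, ref1))
  expect_false(in_reference_map(fixture_region(start = 100, end = 149), ref1))
  expect_false(in_reference_map(r, ref1[0, ]))
  # same coordinates on another chromosome do not count
  r2 <- fixture_region(chrom = "2", start = 100, end = 200)
  expect_false(in_reference_map(r2, ref1))
})

test_that("the four informative-region criteria classify as documented", {
  far <- ref1[0, ]
  # case-only, novel -> important in cases
  expect_equal(classify_region(
    fixture_region(case_count = 1, case_status = "gain"), far)$category,
    "important_in_cases")
  # control-only, known -> important in controls
  expect_equal(classify_region(
    fixture_region(start = 150, end = 300, control_count = 2,
                   control_status = "gain"), ref1)$category,
    "important_in_controls")
  # status conflict trumps everything else
  expect_equal(classify_region(
    fixture_region(case_count = 1, control_count = 1,
                   case_status = "loss", control_status = "gain"),
    far)$category, "different_status")
  # frequency difference of 4 with both groups present -> enrichment
  got <- classify_region(
    fixture_region(case_count = 5, control_count = 1,
                   case_status = "gain", control_status = "gain"), far)
  expect_equal(got$category, "enriched_in_cases")
  expect_equal(got$freq_diff, 4L)
  # case-only but already in the reference map -> uninformative
  expect_equal(classify_region(
    fixture_region(start = 150, end = 300, case_count = 1,
                   case_status = "gain"), ref1)$category,
    "uninformative")
  expect_error(classify_region(fixture_region(), ref1), "no pool")
})

test_that("classification matches a truth-table oracle on count grids", {
  far <- ref1[0, ]
  for (ca in 0:8) for (co in 0:8) {
    if (ca + co == 0) next
    for (in_ref in c(FALSE, TRUE)) {
      for (conflict in c(FALSE, TRUE)) {
        if (conflict && (ca == 0 || co == 0)) next
        cs <- if (ca > 0) "gain" else ""
        os <- if (co > 0) { if (conflict) "loss" else "gain" } else ""
        reg <- fixture_region(start = if (in_ref) 150 else 500,
                              end = if (in_ref) 300 else 600,
                              case_count = ca, control_count = co,
                              case_status = cs, control_status = os)
        got <- classify_region(reg, ref1)$category
        # independent restatement of the decision rules
        want <- if (ca >= 1 && co >= 1 && conflict) "different_status"
          else if (co == 0 && !in_ref) "important_in_cases"
          else if (ca == 0 && in_ref) "important_in_controls"
          else if (ca >= 1 && co >= 1 && abs(ca - co) >= 3)
            if (ca > co) "enriched_in_cases" else "enriched_in_controls"
          else "uninformative"
        expect_equal(got, want,
                     info = sprintf("ca=%d co=%d ref=%d conf=%d",
                                    ca, co, in_ref, conflict))
      }
    }
  }
})

test_that("raising the frequency threshold never adds enriched regions", {
  far <- ref1[0, ]
  regions <- do.call(rbind, lapply(1:8, function(ca)
    fixture_region(start = ca * 1000, end = ca * 1000 + 100,
                   case_count = ca, control_count = 1,
                   case_status = "gain", control_status = "gain")))
  n_enriched <- vapply(1:8, function(thr) {
    cl <- classify_regions(regions, far, freq_diff_threshold = thr)
    sum(grepl("^enriched", cl$category))
  }, 0)
  expect_true(all(diff(n_enriched) <= 0))
})

test_that("category summaries count, break down and total correctly", {
  far <- ref1[0, ]
  regions <- rbind(
    fixture_region(start = 1000, end = 2000, case_count = 1,
                   case_status = "gain"),
    fixture_region(start = 3000, end = 4000, case_count = 1,
                   case_status = "loss"),
    fixture_region(start = 5000, end = 6000, case_count = 1, control_count = 5,
                   case_status = "gain", control_status = "gain"))
  cl <- classify_regions(regions, far)
  s <- summarize_categories(cl)
  tab <- s$table
  expect_equal(tab$n[tab$category == "important_in_cases"], 2L)
  expect_equal(tab$n_gain[tab$category == "important_in_cases"], 1L)
  expect_equal(tab$n_loss[tab$category == "important_in_cases"], 1L)
  expect_equal(tab$n[tab$category == "enriched_in_controls"], 1L)
  expect_equal(s$n_informative, 3L)
  expect_equal(tab$mean_length_kb[tab$category == "important_in_cases"], 1.001)

  empty <- summarize_categories(classify_regions(regions[0, ], far))
  expect_true(all(empty$table$n == 0L))
  expect_equal(empty$n_informative, 0L)
})

test_that("every classified region gets exactly one category", {
  set.seed(71)
  far <- ref1[0, ]
  regions <- do.call(rbind, lapply(1:40, function(i) {
    ca <- sample(0:8, 1); co <- if (ca == 0) sample(1:8, 1) else sample(0:8, 1)
    fixture_region(start = i * 1e4, end = i * 1e4 + 5000,
                   case_count = ca, control_count = co,
                   case_status = if (ca) sample(c("gain", "loss"), 1) else "",
                   control_status = if (co) sample(c("gain", "loss"), 1) else "")
  }))
  cl <- classify_regions(regions, far)
  s <- summarize_categories(cl)
  expect_equal(s$n_informative + sum(cl$category == "uninformative"),
               nrow(regions))
})
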