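test_that("cumulate reproduces the printed cumulative frequencies", {
  tab <- speak_listen_fixture()
  cum <- cumulate(tab)
  expect_equal(cum["Sep", ">=4"], 267, ignore_attr = TRUE)
  expect_equal(cum["Sep", ">=1"], 470, ignore_attr = TRUE)
  expect_equal(cum["Aug", ">=5"], 24, ignore_attr = TRUE)
  expect_equal(unname(cum[, ">=1"]), unname(rowSums(tab$counts)))
  # monotone non-increasing across severity within each row
  expect_true(all(apply(cum, 1, function(r) all(diff(r) <= 0))))
  # all-zero row cumulates to zeros
  g2 <- birth_grid(c(180, 185))
  z <- cumulate(rating_table(g2, matrix(0, 2, 3)))
  expect_true(all(z == 0))
})

test_that("reverse coding is an involution that flips the level order", {
  tab <- speak_listen_fixture()
  rev1 <- reverse_code(tab)
  expect_identical(rev1$levels, rev(tab$levels))
  expect_equal(unname(rev1$counts), unname(tab$counts[, 5:1]))
  expect_true(rev1$reverse_scored)
  rev2 <- reverse_code(rev1)
  expect_equal(rev2$counts, tab$counts)
  expect_false(rev2$reverse_scored)
})

test_that("probit transform reproduces every printed probability and z-score", {
  pts <- to_probit_points(speak_listen_fixture())
  expect_equal(nrow(pts), 48)
  expect_equal(nrow(excluded_points(pts)), 0)
  p_mat <- matrix(pts$p, 12, 4)
  z_mat <- matrix(pts$z, 12, 4)
  expect_printed(p_mat, unname(table2_p), 4)
  expect_printed(z_mat, unname(table2_z), 4)
  expect_printed(matrix(pts$t_B, 12, 4)[, 1], table2_tmid, 4)
  # z is always the upper-tail probit of p
  expect_equal(pts$z, probit_upper(pts$p), tolerance = 1e-12)
  # the ">= lowest" column (p = 1 for everyone) is never transformed
  expect_equal(sort(unique(pts$level)), c("2", "3", "4", "5"))
})

test_that("degenerate proportions follow the zero-cell policy", {
  g <- birth_grid(c(120, 120, 125))
  counts <- matrix(c(5, 10, 0,
                     4,  6, 5,
                     9,  0, 0), nrow = 3, byrow = TRUE)
  tab <- rating_table(g, counts, levels = c("lo", "mid", "hi"))
  pts <- to_probit_points(tab)   # default: exclude
  ex <- excluded_points(pts)
  expect_setequal(ex$reason, "degenerate proportion")
  # row 3: mid+hi count 0 -> p = 0 at levels mid? no: >=mid is 0 -> excluded
  expect_true(all(c("I1", "I3") %in% ex$interval))
  corr <- to_probit_points(tab, zero_cell = "correct")
  expect_equal(nrow(corr), 6)
  expect_equal(nrow(excluded_points(corr)), 0)
  # continuity correction p* = (x + 0.5) / (n + 1) for the zero cell
  i3_hi <- corr[corr$interval == "I3" & corr$level == "hi", ]
  expect_equal(i3_hi$p, 0.5 / 10)
  # a zero row total is excluded with a warning
  tab0 <- rating_table(g, rbind(counts[1:2, ], 0))
  expect_warning(pts0 <- to_probit_points(tab0), "zero row total")
  expect_false("I3" %in% pts0$interval)
})

test_that("selection points reproduce the printed tercile z-scores", {
  g <- tercile_grid(c(33736, 32378, 33886))
  pts <- selection_points(g, c(0.57, 0.29, 0.14), total_selected = 320)
  expect_printed(pts$z, c(2.548, 2.763, 3.006), 3)
  # the first ratio prints as 0.005410 but 182.4/33736 = 0.005407; the
  # downstream z agrees to 3 d.p. either way
  expect_printed(pts$p, c(0.005410, 0.002866, 0.001322), 5)
  # fractional counts give identical points to shares x total
  pts2 <- selection_points(g, c(182.4, 92.8, 44.8))
  expect_equal(pts2$z, pts$z, tolerance = 1e-12)
  # equal probabilities give equal z
  g3 <- tercile_grid(c(1000, 1000, 1000))
  pts3 <- selection_points(g3, c(10, 10, 10))
  expect_equal(diff(pts3$z), c(0, 0))
  expect_error(selection_points(g, c(40000, 1, 1)), "exceeds pool")
  expect_error(selection_points(tercile_grid(), c(1, 2, 3)), "pools")
})

test_that("rating tables round-trip through CSV exactly", {
  tab <- speak_listen_fixture()
  f <- withr::local_tempfile(fileext = ".csv")
  write_rating_table(tab, f)
  back <- read_rating_table(f, year_length = 365, cohort_start = "Sep")
  expect_equal(back$counts, tab$counts)
  expect_equal(back$grid$t_mid, tab$grid$t_mid)
  # with pools attached
  g <- tercile_grid(c(100, 110, 120))
  tab2 <- rating_table(g, matrix(1:9, 3, 3))
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_rating_table(tab2, f2)
  back2 <- read_rating_table(f2, grid = tercile_grid())
  expect_equal(back2$grid$pool, c(100, 110, 120))
  expect_equal(unname(back2$counts), unname(tab2$counts))
})

test_that("probit point sets round-trip through the regression-ready CSV", {
  pts <- to_probit_points(speak_listen_fixture())
  f <- withr::local_tempfile(fileext = ".csv")
  write_probit_points(pts, f)
  back <- read_probit_points(f)
  expect_equal(back$z, pts$z, tolerance = 1e-12)
  expect_equal(back$t_B, pts$t_B, tolerance = 1e-12)
  expect_equal(back$level_index, pts$level_index)
})

test_that("malformed CSVs are rejected with a descriptive error", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("month,1,2", "Sep,3,4"), f)
  expect_error(read_rating_table(f), "first column must be 'interval'")
  writeLines(c("interval,1,2", paste0(month_labels, ",", 1:12, ",-3")), f)
  expect_error(read_rating_table(f), "negative")
  writeLines(c("interval,1,2", paste0(rev(month_labels), ",1,2")), f)
  expect_error(read_rating_table(f), "labels do not match")
})

test_that("configs read from JSON and YAML with unknown keys flagged", {
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(year_length = 365, cohort_start = "Sep",
                            zero_cell_policy = "exclude"),
                       f, auto_unbox = TRUE)
  cfg <- read_config(f)
  expect_equal(cfg$year_length, 365)
  jsonlite::write_json(list(bogus = 1), f, auto_unbox = TRUE)
  expect_warning(read_config(f), "unknown config key")
  skip_if_not_installed("yaml")
  fy <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("year_length: 365.25", "pool_total: 100000"), fy)
  cfgy <- read_config(fy)
  expect_equal(cfgy$pool_total, 100000)
})
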