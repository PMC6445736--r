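test_that("read_long_csv parses, sorts within subject and counts measurements", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,time,value", "s1,0,118", "s1,6,122", "s1,3,120"), path)
  d <- read_long_csv(path)
  expect_s3_class(d, "longitudinal_data")
  expect_equal(nrow(d), 3L)
  expect_equal(d$time, c(0, 3, 6))           # re-sorted ascending
  expect_equal(d$value, c(118, 120, 122))
})

test_that("malformed long CSVs raise informative errors", {
  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,time,value", "s1,0,118", "s1,0,119"), dup)
  expect_error(read_long_csv(dup), "duplicate.*s1.*0")

  miss <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,when,value", "s1,0,118"), miss)
  expect_error(read_long_csv(miss), "missing required column")

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,time,value", "s1,0,118", "s1,abc,120"), bad)
  expect_error(read_long_csv(bad), "non-numeric 'time' in row 2")
})

test_that("CSV write/read round-trips values to full precision", {
  set.seed(4)
  long <- longitudinal_data(id = rep(sprintf("s%02d", 1:5), each = 4),
                            time = rep(sort(runif(4) * 10), 5),
                            value = rnorm(20, 120, 13.77) + pi * 1e-8)
  surv <- survival_data(id = sprintf("s%02d", 1:5),
                        time = rexp(5) + 0.1, status = c(1, 0, 1, 1, 0))
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_long_csv(long, p1)
  write_surv_csv(surv, p2)
  expect_identical(read_long_csv(p1)$value, long$value)
  expect_identical(read_long_csv(p1)$time, long$time)
  expect_identical(read_surv_csv(p2)$time, surv$time)
  expect_identical(read_surv_csv(p2)$status, surv$status)
})

test_that("separate_followup drops early events, late measurements and resets the clock", {
  ds <- toy_dataset()
  expect_message(out <- separate_followup(ds, 11.9), "dropped 1 subject")
  # subject A (event at 5 <= 11.9) is gone entirely
  expect_setequal(out$survival$id, c("B", "C"))
  expect_false("A" %in% out$longitudinal$id)
  # survival clock restarts at t_sep
  expect_equal(out$survival$time[out$survival$id == "B"], 15 - 11.9)
  expect_equal(out$survival$time[out$survival$id == "C"], 20 - 11.9)
  expect_equal(out$survival$status, c(1L, 0L))
  # measurements at 12 >= t_sep are dropped, 0 and 6 retained
  expect_equal(sort(unique(out$longitudinal$time)), c(0, 6))
  expect_equal(nrow(out$longitudinal), 4L)
  expect_equal(out$t_sep, 11.9)
})

test_that("separate_followup is idempotent and never grows the data", {
  ds <- toy_dataset()
  once <- separate_followup(ds, 11.9, quiet = TRUE)
  twice <- separate_followup(once, 11.9, quiet = TRUE)
  expect_identical(once, twice)
  expect_error(separate_followup(once, 5), "already separated")
  expect_lte(nrow(once$survival), nrow(ds$survival))
  expect_lte(nrow(once$longitudinal), nrow(ds$longitudinal))
})

test_that("separate_followup boundary cases", {
  ds <- toy_dataset()
  expect_error(separate_followup(ds, 25), "no survival follow-up remains")
  # measurements exactly at t_sep are excluded (half-open window)
  out <- separate_followup(ds, 6, quiet = TRUE)
  expect_equal(sort(unique(out$longitudinal$time)), 0)
  # t_sep just above 0: all subjects keep survival follow-up, measurements
  # at t = 0 are retained (0 < t_sep)
  out0 <- separate_followup(ds, 1e-9, quiet = TRUE)
  expect_equal(nrow(out0$survival), 3L)
  expect_true(all(out0$longitudinal$time == 0))
})

test_that("analysis_dataset validates subject consistency", {
  expect_error(analysis_dataset(toy_long(),
                                survival_data("A", 5, 1)),
               "no survival record")
  expect_error(survival_data(c("A", "A"), c(1, 2), c(0, 1)), "duplicated")
  expect_error(survival_data("A", 0, 1), "must be > 0")
  expect_error(survival_data("A", 1, 2), "status")
})
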