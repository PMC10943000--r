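test_that("well-formed cohort ingests with visits ascending and round-trips", {
  dir <- write_tiny_cohort(withr::local_tempdir())
  bundles <- read_cohort(dir)
  expect_length(bundles, 3)
  expect_equal(attr(bundles, "issues"), character(0))
  for (b in bundles) {
    expect_false(is.unsorted(b$visits$gestational_age, strictly = TRUE))
  }
  # subject C's visits arrive out of order in the file
  expect_equal(bundles$C$visits$gestational_age, c(84L, 245L))
  expect_true(bundles$B$interview_history_hypertension)

  out <- withr::local_tempdir()
  write_cohort(bundles, out)
  again <- read_cohort(out)
  for (id in names(bundles)) {
    expect_equal(again[[id]]$visits, bundles[[id]]$visits)
    expect_equal(again[[id]]$delivery, bundles[[id]]$delivery)
  }
})

test_that("dipstick aliases resolve and unknown tokens fail with a row index", {
  expect_equal(dipstick_grade(c("negative", "trace", "1+", "4+")), c(0L, 1L, 2L, 5L))
  expect_equal(dipstick_grade("+-", aliases = c("+-" = "trace")), 1L)
  expect_equal(dipstick_grade(c(NA, "", "2+")), c(NA, NA, 3L))
  expect_error(dipstick_grade(c("1+", "??")), "row 2")
})

test_that("missing mandatory columns are reported by name", {
  dir <- write_tiny_cohort(withr::local_tempdir())
  writeLines(c("subject_id,ga,sbp,dbp,dipstick", "A,84,110,70,negative"),
             file.path(dir, "visits.csv"))
  expect_error(read_cohort(dir), "gestational_age")
})

test_that("duplicate visit rows collapse; conflicts merge toward detection", {
  v <- rbind(make_visits(c(100, 150)), make_visits(100))  # identical dup at 100
  b <- subject_bundle("X", visits = v)
  expect_equal(nrow(b$visits), 2)
  expect_equal(attr(b$visits, "conflicts"), integer(0))

  v2 <- rbind(make_visits(100, sbp = 118, dbp = 70, dipstick = 0L),
              make_visits(100, sbp = 142, dbp = 68, dipstick = 2L))
  b2 <- subject_bundle("Y", visits = v2)
  expect_equal(nrow(b2$visits), 1)
  expect_equal(b2$visits$sbp, 142)
  expect_equal(b2$visits$dipstick, 2L)
  expect_equal(attr(b2$visits, "conflicts"), 100L)
})

test_that("inclusion filter partitions the cohort and logs every reason", {
  full <- subject_bundle("ok", visits = make_visits(c(84, 168)),
                         delivery = delivery_record(273, 3100, "male", TRUE))
  no_del <- subject_bundle("nodel", visits = make_visits(84))
  no_pu <- subject_bundle("nopu",
                          visits = make_visits(84, dipstick = NA),
                          delivery = delivery_record(273, 3000, "female", TRUE))
  stillbirth <- subject_bundle("sb", visits = make_visits(84),
                               delivery = delivery_record(200, 800, "male", FALSE))
  gone <- subject_bundle("wd", visits = make_visits(84),
                         delivery = delivery_record(273, 3000, "male", TRUE))
  bundles <- list(full, no_del, no_pu, stillbirth, gone)
  res <- apply_inclusion_filters(bundles, withdrawn_ids = "wd")
  expect_equal(vapply(res$included, `[[`, "", "subject_id"), "ok")
  ex <- res$exclusions
  expect_setequal(ex$reason[ex$subject_id == "nodel"], "no_delivery_record")
  expect_setequal(ex$reason[ex$subject_id == "nopu"], "no_bp_pu_data")
  expect_setequal(ex$reason[ex$subject_id == "sb"], "no_live_birth")
  expect_setequal(ex$reason[ex$subject_id == "wd"], "withdrawn")
  # partition: included + excluded ids = all ids, disjoint
  inc_ids <- vapply(res$included, `[[`, "", "subject_id")
  expect_setequal(c(inc_ids, unique(ex$subject_id)),
                  vapply(bundles, `[[`, "", "subject_id"))
  expect_length(intersect(inc_ids, ex$subject_id), 0)
})

test_that("percentages round half-up at two decimals with exact arithmetic", {
  expect_equal(format_percentage(1781, 22452), 7.93)
  expect_equal(format_percentage(1813, 22452), 8.08)  # 8.07500445 rounds up
  expect_equal(format_percentage(0, 10), 0)
  expect_equal(format_percentage(1, 800), 0.13)       # exact tie 0.125 -> up
  expect_equal(format_percentage(1, 3), 33.33)
  expect_error(format_percentage(1, 0), "positive")
  expect_error(format_percentage(5, 3), "count")
  # complement property on a sweep
  for (total in c(3, 7, 252, 22452)) {
    for (count in unique(round(seq(0, total, length.out = 11)))) {
      s <- format_percentage(count, total) + format_percentage(total - count, total)
      expect_gte(s, 99.99); expect_lte(s, 100.01)
    }
  }
})

test_that("visit and delivery invariants reject impossible values", {
  expect_error(visit(0), "gestational_age")
  expect_error(visit(350), "gestational_age")
  expect_error(visit(100, sbp = 90, dbp = 95), "dbp")
  expect_error(delivery_record(100, live_birth = TRUE), "delivery_ga")
  expect_silent(delivery_record(100, live_birth = FALSE))
})
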