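t_def <- hdp_thresholds()

test_that("hypertension onset is the first qualifying visit", {
  expect_true(is.na(detect_hypertension_onset(
    make_visits(c(84, 168), sbp = c(112, 118), dbp = c(68, 72)), t_def)))
  expect_equal(detect_hypertension_onset(
    make_visits(210, sbp = 142, dbp = 88), t_def), 210L)  # 142 >= 140
  expect_equal(detect_hypertension_onset(
    make_visits(c(130, 200), sbp = c(150, 152), dbp = c(95, 96)), t_def), 130L)
  # diastolic alone qualifies; missing BP is skipped
  expect_equal(detect_hypertension_onset(
    make_visits(c(100, 150), sbp = c(NA, 120), dbp = c(NA, 92)), t_def), 150L)
  # configurable k-visit confirmation
  t2 <- hdp_thresholds(bp_repeat_count = 2)
  expect_equal(detect_hypertension_onset(
    make_visits(c(130, 200), sbp = c(150, 152), dbp = c(95, 96)), t2), 200L)
})

test_that("proteinuria rules include the early-pregnancy exclusion", {
  # repeat criterion completes at day 120 < 140: channel disabled
  pu <- assess_proteinuria(make_visits(c(100, 120), dipstick = 2L), t_def)
  expect_true(pu$early_pu); expect_true(is.na(pu$pu_onset_ga))
  # single 2+ at day 220
  pu <- assess_proteinuria(make_visits(220, dipstick = 3L), t_def)
  expect_equal(pu$pu_onset_ga, 220L); expect_false(pu$early_pu)
  # trace never qualifies
  pu <- assess_proteinuria(make_visits(220, dipstick = 1L), t_def)
  expect_true(is.na(pu$pu_onset_ga)); expect_false(pu$early_pu)
  # repeat criterion straddling the boundary completes late: onset kept
  pu <- assess_proteinuria(make_visits(c(100, 150), dipstick = 2L), t_def)
  expect_equal(pu$pu_onset_ga, 150L); expect_false(pu$early_pu)
  # an early single 2+ disables the channel even with later positives
  pu <- assess_proteinuria(make_visits(c(100, 200), dipstick = 3L), t_def)
  expect_true(pu$early_pu); expect_true(is.na(pu$pu_onset_ga))
})

test_that("PE-related conditions fire on labs and dated notes only", {
  b <- subject_bundle("x", visits = make_visits(230, serum_creatinine = 1.3))
  expect_equal(detect_pe_related_conditions(b, t_def),
               c(renal_dysfunction_lab = 230L))
  # boundary conventions: platelets strictly <, creatinine strictly >
  b2 <- subject_bundle("y", visits = make_visits(230, platelet_count = 100,
                                                 serum_creatinine = 1.1))
  expect_length(detect_pe_related_conditions(b2, t_def), 0)
  b3 <- subject_bundle("z", visits = make_visits(230, platelet_count = 99.9))
  expect_equal(names(detect_pe_related_conditions(b3, t_def)), "thrombocytopenia")
  # transaminases above 2 x ULN
  b4 <- subject_bundle("w", visits = make_visits(c(200, 240), ast = c(50, 70)))
  expect_equal(detect_pe_related_conditions(b4, t_def),
               c(hepatic_dysfunction_lab = 240L))
  # dated non-negated headache note fires; undated does not
  mk <- function(notes) {
    b <- subject_bundle("n", visits = make_visits(200), notes = notes)
    b$flags <- aggregate_flags(b$notes, test_dict())
    b
  }
  dated <- mk(data.frame(gestational_age = 250L, text = "severe headache"))
  expect_equal(detect_pe_related_conditions(dated, t_def),
               c(new_onset_headache = 250L))
  undated <- mk(data.frame(gestational_age = NA_integer_,
                           text = "severe headache"))
  expect_length(detect_pe_related_conditions(undated, t_def), 0)
})

test_that("hand-traced subjects get the expected labels and onsets", {
  # no history, hypertension at 240, proteinuria at 245: late-onset PE
  b <- subject_bundle("a", visits = {
    v <- make_visits(c(100, 240, 245), sbp = c(112, 150, 152),
                     dbp = c(70, 95, 96))
    v$dipstick[3] <- 3L
    v
  })
  r <- classify_algorithm1(b, t_def)
  expect_equal(r$label, "PE_LO")
  expect_equal(r$onset_ga, 245L)

  # history, never proteinuric, any BP: chronic hypertension
  b2 <- subject_bundle("b", interview_history_hypertension = TRUE,
                       visits = make_visits(c(100, 200), sbp = 152, dbp = 96))
  expect_equal(classify_algorithm1(b2, t_def)$label, "CH")

  # no hypertension, no history: normotensive
  b3 <- subject_bundle("c", visits = make_visits(c(100, 200)))
  expect_equal(classify_algorithm1(b3, t_def)$label, "NT")
  expect_error(classify_algorithm1(list(visits = NULL)), "visit")
})

test_that("algorithm 2 upgrades GH to PE and CH to SPE", {
  # light-for-date upgrades GH: onset keeps the hypertension day (230 < 238)
  gh <- subject_bundle("g", visits = make_visits(c(100, 230), sbp = c(112, 152),
                                                 dbp = c(70, 96)))
  r <- classify_algorithm2(gh, t_def, lfd = TRUE)
  expect_equal(r$label, "PE_EO")
  expect_equal(r$onset_ga, 230L)

  # chronic hypertension with epigastralgia at day 250: late-onset SPE
  ch <- subject_bundle("h", interview_history_hypertension = TRUE,
                       visits = make_visits(c(100, 200), sbp = 152, dbp = 96),
                       notes = data.frame(gestational_age = 250L,
                                          text = "epigastralgia"))
  ch$flags <- aggregate_flags(ch$notes, test_dict(), TRUE)
  r2 <- classify_algorithm2(ch, t_def, lfd = FALSE)
  expect_equal(r2$label, "SPE_LO")
  expect_equal(r2$onset_ga, 250L)

  # no upgrade trigger: identical to algorithm 1
  r3a <- classify_algorithm1(gh, t_def)
  r3b <- classify_algorithm2(gh, t_def, lfd = FALSE)
  expect_equal(r3b$label, r3a$label)
  expect_equal(r3b$onset_ga, r3a$onset_ga)
})

test_that("light-for-date lookup is strict and covered by the table", {
  tab <- read_lfd_table()
  expect_equal(tab, make_lfd_reference())  # shipped file matches generator
  row <- tab[tab$week == 38 & tab$sex == "male", ]
  expect_false(is_light_for_date(row$p50, 38 * 7, "male", tab))
  expect_false(is_light_for_date(row$p10, 38 * 7, "male", tab))      # strict <
  expect_true(is_light_for_date(row$p10 - 1, 38 * 7, "male", tab))
  expect_true(is_light_for_date(2000, 266, "male", tab))  # 2000 < p10 = 2467
  expect_error(is_light_for_date(3000, 150, "male", tab), "not covered")
  # cross-check cutoffs against a linear interpolation oracle on half-weeks
  for (sex in c("male", "female")) {
    s <- tab[tab$sex == sex, ]
    interp <- stats::approx(s$week, s$p10, xout = s$week)$y
    expect_equal(interp, s$p10)
    expect_true(all(diff(s$p10) > 0))  # percentiles increase with gestation
    expect_true(all(s$p03 < s$p10 & s$p10 < s$p50 & s$p50 < s$p90))
  }
})

test_that("both classifiers agree with the exhaustive truth-table oracle", {
  for (history in c(FALSE, TRUE)) {
    for (htn in c("none", "pre20", "eo", "lo")) {
      for (pu in c("none", "early", "late")) {
        for (cond in c("none", "lab", "organ")) {
          for (lfd in c(FALSE, TRUE)) {
            b <- grid_bundle(history, htn, pu, cond)
            htn_day <- switch(htn, none = NA, pre20 = 120, eo = 170, lo = 260)
            pu_arg <- if (pu == "late") 245 else pu
            cond_day <- if (cond == "lab") 250 else NA
            organ_day <- if (cond == "organ") 250 else NA
            exp1 <- oracle_classify(1, history, htn_day, pu_arg, cond_day,
                                    organ_day, lfd = FALSE, delivery = 287)
            exp2 <- oracle_classify(2, history, htn_day, pu_arg, cond_day,
                                    organ_day, lfd = lfd, delivery = 287)
            info <- sprintf("history=%s htn=%s pu=%s cond=%s lfd=%s",
                            history, htn, pu, cond, lfd)
            expect_equal(classify_algorithm1(b, t_def)$label, exp1, info = info)
            expect_equal(classify_algorithm2(b, t_def, lfd = lfd)$label, exp2,
                         info = info)
          }
        }
      }
    }
  }
})

test_that("label properties hold on a noisy random cohort", {
  sim <- simulate_cohort(sim_config(n_subjects = 400, seed = 7))
  bundles <- mine_cohort(sim$bundles)
  r1 <- classify_cohort(bundles, t_def, algorithm = 1)
  r2 <- classify_cohort(bundles, t_def, algorithm = 2)
  # exactly one label each; counts sum to cohort size
  expect_true(all(r1$label %in% HDP_LABELS))
  expect_equal(sum(table(factor(r1$label, HDP_LABELS))), length(bundles))
  # EO iff onset before the cut; CH/NT carry no timing suffix
  for (r in list(r1, r2)) {
    eo <- grepl("_EO$", r$label); lo <- grepl("_LO$", r$label)
    expect_true(all(r$onset_ga[eo] < t_def$eo_lo_cut))
    expect_true(all(r$onset_ga[lo] >= t_def$eo_lo_cut))
    expect_false(any(grepl("_(EO|LO)$", r$label[r$label %in% c("CH", "NT")])))
  }
  # raising the BP cuts never increases the number of non-NT labels
  t_hi <- hdp_thresholds(sbp_cut = 160, dbp_cut = 110)
  r_hi <- classify_cohort(bundles, t_hi, algorithm = 1)
  expect_lte(sum(r_hi$label != "NT"), sum(r1$label != "NT"))
  # algorithm 1 HDP subjects are contained in algorithm 2's
  hdp1 <- r1$subject_id[binarize(r1$label, "HDP")]
  hdp2 <- r2$subject_id[binarize(r2$label, "HDP")]
  expect_true(all(hdp1 %in% hdp2))
  # discordances lie only on GH->PE and CH->SPE edges
  comp <- compare_algorithms(r1, r2)
  base <- function(x) sub("_(EO|LO)$", "", x)
  edges <- paste(base(comp$discordant$label1), base(comp$discordant$label2))
  expect_true(all(edges %in% c("GH PE", "CH SPE")))
})

test_that("algorithm comparison cross-tabulates and explains discordance", {
  r1 <- data.frame(subject_id = c("a", "b"), label = c("GH_EO", "NT"),
                   onset_ga = c(200L, NA), evidence = c("gh", "nt"))
  expect_equal(nrow(compare_algorithms(r1, r1)$discordant), 0)
  r2 <- r1
  r2$label[1] <- "PE_EO"
  r2$evidence[1] <- "gh;light_for_date;upgrade_GH_to_PE"
  comp <- compare_algorithms(r1, r2)
  expect_equal(sum(comp$table) - sum(diag(comp$table)), 1)
  expect_equal(comp$discordant$rule, "light_for_date;upgrade_GH_to_PE")
  expect_error(compare_algorithms(r1, r2[1, ]), "different subjects")
})
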