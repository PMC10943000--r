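# Builders for hand-crafted subjects and tiny on-disk cohorts.

make_visits <- function(ga, sbp = 112, dbp = 68, dipstick = 0L, ...) {
  n <- length(ga)
  data.frame(gestational_age = as.integer(ga),
             sbp = rep_len(sbp, n), dbp = rep_len(dbp, n),
             dipstick = as.integer(rep_len(dipstick, n)),
             platelet_count = rep_len(list(...)$platelet_count %||% NA_real_, n),
             serum_creatinine = rep_len(list(...)$serum_creatinine %||% NA_real_, n),
             ast = rep_len(list(...)$ast %||% NA_real_, n),
             alt = rep_len(list(...)$alt %||% NA_real_, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A subject realizing one cell of the discretized feature grid.
# htn: "none", "pre20" (day 120), "eo" (day 170), "lo" (day 260)
# pu:  "none", "early" (1+ at days 100 and 120), "late" (2+ at day 245)
# cond: "none", "lab" (creatinine 1.4 at day 250),
#       "organ" (epigastralgia note at day 250)
grid_bundle <- function(history, htn, pu, cond) {
  days <- c(84, 100, 120, 170, 200, 245, 250, 260, 280)
  htn_day <- switch(htn, none = Inf, pre20 = 120, eo = 170, lo = 260)
  v <- make_visits(days)
  hi <- v$gestational_age >= htn_day
  v$sbp[hi] <- 152; v$dbp[hi] <- 96
  if (pu == "early") v$dipstick[v$gestational_age %in% c(100, 120)] <- 2L
  if (pu == "late") v$dipstick[v$gestational_age == 245] <- 3L
  if (cond == "lab") v$serum_creatinine[v$gestational_age == 250] <- 1.4
  notes <- if (cond == "organ") {
    data.frame(gestational_age = 250L, text = "epigastralgia reported")
  } else NULL
  b <- subject_bundle("G1", interview_history_hypertension = history,
                      visits = v,
                      delivery = delivery_record(287, 3100, "male", TRUE),
                      notes = notes)
  b$flags <- aggregate_flags(b$notes, test_dict(), history)
  b
}

# dictionary compiled once per test file load
test_dict <- local({
  d <- NULL
  function() {
    if (is.null(d)) d <<- flag_dictionary()
    d
  }
})

# Write a well-formed three-subject cohort to dir and return the paths.
write_tiny_cohort <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(c("subject_id,history_hypertension",
               "A,false", "B,true", "C,false"),
             file.path(dir, "subjects.csv"))
  writeLines(c("subject_id,gestational_age,sbp,dbp,dipstick,platelet_count,serum_creatinine,ast,alt",
               "A,84,110,70,negative,,,,",
               "A,168,114,72,negative,,,,",
               "B,84,150,95,negative,,,,",
               "B,168,152,96,1+,,,,",
               "C,245,142,88,2+,,,,",
               "C,84,108,66,negative,,,,"),
             file.path(dir, "visits.csv"))
  writeLines(c("subject_id,delivery_ga,birth_weight,infant_sex,live_birth,parity",
               "A,273,3100,male,true,0",
               "B,266,2900,female,true,1",
               "C,280,3000,male,true,0"),
             file.path(dir, "delivery.csv"))
  writeLines(c("subject_id,gestational_age,text",
               "B,84,\"chronic hypertension, on medication\"",
               "C,250,\"no headache today\""),
             file.path(dir, "notes.csv"))
  dir
}

# Planted-error 252-subject label pair mirroring a chart-review comparison:
# the diagnosed set has no GH_EO, and a known list of discordant subjects.
planted_252 <- function() {
  truth <- c(rep("NT", 203), rep("CH", 13), rep("GH_LO", 9),
             rep("PE_EO", 5), rep("PE_LO", 10),
             rep("SPE_EO", 6), rep("SPE_LO", 6))
  stopifnot(length(truth) == 252)
  pred <- truth
  pred[204] <- "SPE_LO"   # CH missed as superimposed PE
  pred[217] <- "NT"       # GH_LO missed
  pred[218] <- "NT"       # GH_LO missed
  pred[225] <- "PE_LO"    # PE_EO timing shifted
  pred[230] <- "NT"       # PE_LO missed
  pred[231] <- "GH_LO"    # PE_LO called GH
  pred[241] <- "SPE_LO"   # SPE_EO timing shifted
  pred[247] <- "CH"       # SPE_LO missed as plain chronic hypertension
  pred[1] <- "GH_LO"      # false-positive GH in a normotensive
  ids <- sprintf("D%03d", seq_len(252))
  list(pred = data.frame(subject_id = ids, label = pred),
       truth = data.frame(subject_id = ids, label = truth))
}
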