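#' Simulation configuration for a synthetic pregnancy cohort
#'
#' Defines the generative model: per-class prevalences and early-onset
#' fractions (defaults follow the subtype mix reported for a large Japanese
#' birth-cohort application of these rule engines: GH 3.96%, SPE 1.35%,
#' PE 2.61%, CH 2.41%, normotensive remainder; EO fractions 356/890, 207/304
#' and 140/587), the prenatal visit schedule (every 4 weeks to week 23,
#' every 2 weeks to week 35, weekly thereafter), blood-pressure and dipstick
#' emission models, organ-dysfunction and light-for-date probabilities, and
#' the delivery model.
#'
#' @param n_subjects Number of pregnancies.
#' @param seed Integer RNG seed.
#' @param prevalence Named probabilities over generative classes
#'   `NT`, `CH`, `GH`, `PE`, `SPE` (must sum to 1).
#' @param eo_fraction Named fractions of `GH`, `PE`, `SPE` with early onset.
#' @param schedule_weeks Completed weeks of the checkup schedule.
#' @param bp Blood-pressure model: subject baseline means/sds, per-visit sd,
#'   and post-onset elevation mean/sd for each of sbp and dbp.
#' @param dipstick_pos_probs Post-onset dipstick grade probabilities
#'   (named by canonical token) for proteinuric subjects.
#' @param dipstick_noise_probs Background grade probabilities at
#'   non-proteinuric visits.
#' @param condition_frac Fraction of PE/SPE whose qualifying feature is an
#'   elevated serum creatinine rather than dipstick proteinuria.
#' @param organ_flag_prob Named per-class probability of a dated
#'   organ-dysfunction note (epigastralgia etc.) after onset.
#' @param lfd_prob Named per-class probability that the infant is
#'   light-for-date; birth weight is drawn consistently with that status
#'   from the percentile reference.  Defaults concentrate light-for-date in
#'   PE/SPE, where it proxies placental dysfunction.
#' @param ch_history_only_frac Fraction of CH/SPE whose chronic hypertension
#'   is documented by history (interview flag or note) with controlled BP,
#'   rather than by elevated measurements from the first visit.
#' @param decoy_prob Probability of a negated decoy mention ("no headache")
#'   in a subject's notes.
#' @param delivery_mean,delivery_sd Delivery gestational age model, days.
#' @param noise_free When `TRUE`, all sds are zero and emissions are
#'   deterministic class-conditional values, so classifier output equals the
#'   generative truth up to the documented structural edge cases.
#' @return A list of class `hdp_simconfig`.
#' @export
sim_config <- function(n_subjects = 1000, seed = 1L,
                       prevalence = c(NT = 0.8967, CH = 0.0241, GH = 0.0396,
                                      PE = 0.0261, SPE = 0.0135),
                       eo_fraction = c(GH = 356 / 890, PE = 140 / 587,
                                       SPE = 207 / 304),
                       schedule_weeks = c(8, 12, 16, 20, seq(24, 34, 2),
                                          seq(36, 42, 1)),
                       bp = list(sbp_mean = 110, sbp_sd = 8, dbp_mean = 68,
                                 dbp_sd = 5, visit_sd = 4,
                                 elev_sbp = 45, elev_sbp_sd = 6,
                                 elev_dbp = 30, elev_dbp_sd = 4),
                       dipstick_pos_probs = c("1+" = 0.15, "2+" = 0.55,
                                              "3+" = 0.25, "4+" = 0.05),
                       dipstick_noise_probs = c("negative" = 0.95,
                                                "trace" = 0.04, "1+" = 0.01),
                       condition_frac = 0.2,
                       organ_flag_prob = c(NT = 0, CH = 0, GH = 0,
                                           PE = 0.15, SPE = 0.15),
                       lfd_prob = c(NT = 0.02, CH = 0.02, GH = 0.02,
                                    PE = 0.3, SPE = 0.3),
                       ch_history_only_frac = 0.3, decoy_prob = 0.1,
                       delivery_mean = 273, delivery_sd = 9,
                       noise_free = FALSE) {
  if (abs(sum(prevalence) - 1) > 1e-8)
    stop("prevalence must sum to 1", call. = FALSE)
  if (any(prevalence < 0)) stop("prevalence must be non-negative", call. = FALSE)
  if (is.unsorted(schedule_weeks, strictly = TRUE))
    stop("schedule must be strictly increasing", call. = FALSE)
  cfg <- list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
              prevalence = prevalence, eo_fraction = eo_fraction,
              schedule_weeks = schedule_weeks, bp = bp,
              dipstick_pos_probs = dipstick_pos_probs,
              dipstick_noise_probs = dipstick_noise_probs,
              condition_frac = condition_frac,
              organ_flag_prob = organ_flag_prob, lfd_prob = lfd_prob,
              ch_history_only_frac = ch_history_only_frac,
              decoy_prob = decoy_prob, delivery_mean = delivery_mean,
              delivery_sd = delivery_sd, noise_free = isTRUE(noise_free))
  structure(cfg, class = "hdp_simconfig")
}

rnormd <- function(n, mean, sd, noise_free) {
  if (noise_free || sd == 0) rep(mean, n) else stats::rnorm(n, mean, sd)
}

sample_grade <- function(n, probs, noise_free) {
  if (noise_free) {
    rep(dipstick_grade(names(probs)[which.max(probs)]), n)
  } else {
    dipstick_grade(sample(names(probs), n, replace = TRUE, prob = probs))
  }
}

#' Generate a synthetic cohort with ground truth
#'
#' Deterministic given the config seed.  Class-conditional structure: chronic
#' hypertension is hypertensive from the first visit or documented by a
#' history note/interview; GH and PE become hypertensive at an onset day
#' drawn on the visit schedule at/after 20 weeks; PE additionally shows
#' dipstick proteinuria (or an elevated creatinine, for the condition
#' fraction) from onset; superimposed preeclampsia is chronic hypertension
#' plus the same new-onset feature.  Light-for-date status is drawn per
#' class and birth weight sampled consistently with it from the percentile
#' reference.
#'
#' @param config An [sim_config()].
#' @param lfd_table Percentile reference (defaults to the shipped synthetic
#'   table).
#' @return List: `bundles` (flags not yet mined; see [mine_cohort()]) and
#'   `truth` (data frame: `subject_id`, `class`, `label`, `onset_ga`,
#'   `lfd`, `condition_route`, `organ_flag`).
#' @export
simulate_cohort <- function(config = sim_config(), lfd_table = read_lfd_table()) {
  stopifnot(inherits(config, "hdp_simconfig"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  nf <- config$noise_free
  schedule <- as.integer(config$schedule_weeks * 7)
  classes <- sample(names(config$prevalence), config$n_subjects,
                    replace = TRUE, prob = config$prevalence)
  ids <- sprintf("S%05d", seq_len(config$n_subjects))

  organ_terms <- c("epigastralgia", "hellp syndrome", "eclampsia",
                   "fetal growth restriction")

  bundles <- vector("list", config$n_subjects)
  truth <- vector("list", config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    cls <- classes[i]
    # delivery day, then onset on the visit schedule
    delivery_ga <- as.integer(round(rnormd(1, config$delivery_mean,
                                           config$delivery_sd, nf)))
    delivery_ga <- min(max(delivery_ga, 259L), 294L)
    onset <- NA_integer_
    eo <- NA
    if (cls %in% c("GH", "PE", "SPE")) {
      eo <- stats::runif(1) < config$eo_fraction[[cls]]
      win <- if (eo) schedule[schedule >= 140L & schedule < 238L]
      else schedule[schedule >= 238L & schedule <= delivery_ga - 7L]
      if (!length(win)) {
        delivery_ga <- 294L
        win <- schedule[schedule >= 238L & schedule <= delivery_ga - 7L]
      }
      onset <- if (length(win) == 1L) win else sample(win, 1)
    }
    visits_ga <- schedule[schedule < delivery_ga]
    nv <- length(visits_ga)

    history_only <- cls %in% c("CH", "SPE") &&
      stats::runif(1) < config$ch_history_only_frac
    hypertensive_from <- switch(cls,
                                NT = Inf,
                                CH = if (history_only) Inf else visits_ga[1],
                                SPE = if (history_only) Inf else visits_ga[1],
                                GH = onset, PE = onset)

    bpm <- config$bp
    sbp_base <- rnormd(1, bpm$sbp_mean, bpm$sbp_sd, nf)
    dbp_base <- rnormd(1, bpm$dbp_mean, bpm$dbp_sd, nf)
    elev <- visits_ga >= hypertensive_from
    sbp <- sbp_base + rnormd(nv, 0, bpm$visit_sd, nf) +
      ifelse(elev, rnormd(nv, bpm$elev_sbp, bpm$elev_sbp_sd, nf), 0)
    dbp <- dbp_base + rnormd(nv, 0, bpm$visit_sd, nf) +
      ifelse(elev, rnormd(nv, bpm$elev_dbp, bpm$elev_dbp_sd, nf), 0)
    sbp <- round(pmax(sbp, 80)); dbp <- round(pmin(pmax(dbp, 45), sbp - 10))

    condition_route <- cls %in% c("PE", "SPE") &&
      stats::runif(1) < config$condition_frac
    proteinuric_from <- if (cls %in% c("PE", "SPE") && !condition_route) onset else Inf
    dip <- sample_grade(nv, config$dipstick_noise_probs, nf)
    pos <- visits_ga >= proteinuric_from
    if (any(pos)) dip[pos] <- sample_grade(sum(pos), config$dipstick_pos_probs, nf)
    # avoid accidental early completion of the repeat rule in background noise
    early <- visits_ga < 140L & !pos
    if (sum(dip[early] >= 2L, na.rm = TRUE) >= 2L)
      dip[early][which(dip[early] >= 2L)[-1]] <- 1L

    creat <- rep(NA_real_, nv)
    if (condition_route) creat[visits_ga >= onset] <- if (nf) 1.4 else
      stats::runif(sum(visits_ga >= onset), 1.2, 1.8)

    # notes: history documentation, organ-dysfunction flags, negated decoys
    notes <- data.frame(gestational_age = integer(0), text = character(0))
    interview_flag <- FALSE
    if (history_only || (cls %in% c("CH", "SPE") && stats::runif(1) < 0.5)) {
      if (stats::runif(1) < 0.5) interview_flag <- TRUE
      else notes <- rbind(notes, data.frame(
        gestational_age = visits_ga[1],
        text = "chronic hypertension on medication since before pregnancy"))
      if (history_only && !interview_flag && !nrow(notes)) interview_flag <- TRUE
    }
    organ_flag <- cls %in% c("PE", "SPE") &&
      stats::runif(1) < config$organ_flag_prob[[cls]]
    if (organ_flag) {
      term <- if (nf) organ_terms[1] else sample(organ_terms, 1)
      day <- min(max(onset, 140L) + 7L, delivery_ga - 1L)
      notes <- rbind(notes, data.frame(
        gestational_age = day, text = paste(term, "noted at checkup")))
    }
    if (!nf && stats::runif(1) < config$decoy_prob) {
      notes <- rbind(notes, data.frame(
        gestational_age = sample(visits_ga, 1),
        text = "no headache, denies visual disturbance"))
    }

    lfd <- stats::runif(1) < config$lfd_prob[[cls]]
    sex <- if (nf) "male" else sample(c("male", "female"), 1)
    ref <- lfd_table[lfd_table$week == delivery_ga %/% 7L &
                       lfd_table$sex == sex, ]
    bw <- if (lfd) {
      if (nf) (ref$p03 + ref$p10) / 2 else stats::runif(1, ref$p03, ref$p10 - 1)
    } else {
      if (nf) ref$p50 else stats::runif(1, ref$p10, ref$p90)
    }

    vis <- data.frame(gestational_age = visits_ga, sbp = sbp, dbp = dbp,
                      dipstick = dip, platelet_count = NA_real_,
                      serum_creatinine = creat, ast = NA_real_, alt = NA_real_)
    bundles[[i]] <- subject_bundle(
      ids[i], interview_history_hypertension = interview_flag, visits = vis,
      delivery = delivery_record(delivery_ga, round(bw), sex, TRUE),
      notes = notes)
    label <- switch(cls, NT = "NT", CH = "CH",
                    paste0(cls, if (onset < 238L) "_EO" else "_LO"))
    truth[[i]] <- data.frame(subject_id = ids[i], class = cls, label = label,
                             onset_ga = onset, lfd = lfd,
                             condition_route = condition_route,
                             organ_flag = organ_flag)
  }
  names(bundles) <- ids
  list(bundles = bundles, truth = do.call(rbind, truth))
}

#' Blank fields at configured missingness rates
#'
#' Degrades a generated cohort in place: each named field is set to missing
#' independently at its rate.  Recognised fields: the visit columns `sbp`,
#' `dbp`, `dipstick`, `platelet_count`, `serum_creatinine`, `ast`, `alt`,
#' and `birth_weight`.  Truth records are never touched.  Deterministic
#' given `seed`.
#'
#' @param bundles List of `hdp_subject`.
#' @param rates Named numeric vector of per-field missingness probabilities
#'   in `[0, 1]`.
#' @param seed Integer seed.
#' @return Degraded bundles.
#' @export
inject_missingness <- function(bundles, rates, seed = 1L) {
  stopifnot(all(rates >= 0 & rates <= 1))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  visit_fields <- c("sbp", "dbp", "dipstick", "platelet_count",
                    "serum_creatinine", "ast", "alt")
  lapply(bundles, function(b) {
    for (f in intersect(names(rates), visit_fields)) {
      if (rates[[f]] == 0 || !nrow(b$visits)) next
      drop <- stats::runif(nrow(b$visits)) < rates[[f]]
      b$visits[[f]][drop] <- NA
    }
    if ("birth_weight" %in% names(rates) && !is.null(b$delivery) &&
        stats::runif(1) < rates[["birth_weight"]]) {
      b$delivery$birth_weight <- NA_real_
    }
    b
  })
}

#' Write a simulated cohort plus ground truth to CSV
#'
#' @param sim Result of [simulate_cohort()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_simulated_cohort <- function(sim, dir) {
  write_cohort(sim$bundles, dir)
  utils::write.csv(sim$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}
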