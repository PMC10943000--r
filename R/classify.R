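#' Phenotype labels
#'
#' The eight mutually exclusive output labels: gestational hypertension,
#' superimposed preeclampsia and preeclampsia in early-/late-onset form,
#' chronic hypertension, and normotensive.
#' @export
HDP_LABELS <- c("GH_EO", "GH_LO", "SPE_EO", "SPE_LO", "PE_EO", "PE_LO",
                "CH", "NT")

#' Gestational age of hypertension onset
#'
#' The first visit at which systolic BP `>=` the systolic cut or diastolic BP
#' `>=` the diastolic cut.  With `bp_repeat_count > 1`, the day of the k-th
#' qualifying visit.
#'
#' @param visits Visit data frame sorted ascending by `gestational_age`.
#' @param t An [hdp_thresholds()].
#' @return Integer day, or `NA` if no visit qualifies.
#' @export
detect_hypertension_onset <- function(visits, t = hdp_thresholds()) {
  if (!nrow(visits)) return(NA_integer_)
  hi <- (!is.na(visits$sbp) & visits$sbp >= t$sbp_cut) |
    (!is.na(visits$dbp) & visits$dbp >= t$dbp_cut)
  idx <- which(cumsum(hi) >= t$bp_repeat_count)
  if (!length(idx)) NA_integer_ else visits$gestational_age[idx[1]]
}

#' Proteinuria assessment with the early-pregnancy exclusion rule
#'
#' A dipstick series becomes PU-positive on the first day `d` at which either
#' a single grade `>=` `pu_single_grade` occurs, or grades `>=`
#' `pu_repeat_grade` have occurred at `pu_repeat_count` distinct visits (`d`
#' being the day of the last of them).  Proteinuria confined to, or first
#' completed in, early pregnancy is attributed to pre-existing renal disease
#' rather than HDP: if any qualifying pattern completes before the
#' 20-week boundary the proteinuria channel is disabled for the whole
#' pregnancy (`early_pu = TRUE`, onset `NA`).
#'
#' @param visits Visit data frame sorted ascending.
#' @param t An [hdp_thresholds()].
#' @return List `pu_onset_ga` (integer day or `NA`) and `early_pu` (logical).
#' @export
assess_proteinuria <- function(visits, t = hdp_thresholds()) {
  if (!nrow(visits)) return(list(pu_onset_ga = NA_integer_, early_pu = FALSE))
  g <- visits$dipstick
  single <- !is.na(g) & g >= t$pu_single_grade
  repeat_hit <- !is.na(g) & g >= t$pu_repeat_grade
  d_single <- if (any(single)) visits$gestational_age[which(single)[1]] else NA_integer_
  idx_rep <- which(cumsum(repeat_hit) >= t$pu_repeat_count)
  d_repeat <- if (length(idx_rep)) visits$gestational_age[idx_rep[1]] else NA_integer_
  d <- suppressWarnings(min(d_single, d_repeat, na.rm = TRUE))
  if (!is.finite(d)) return(list(pu_onset_ga = NA_integer_, early_pu = FALSE))
  if (d < t$ch_boundary) {
    list(pu_onset_ga = NA_integer_, early_pu = TRUE)
  } else {
    list(pu_onset_ga = as.integer(d), early_pu = FALSE)
  }
}

#' Onset days of PE-related clinical conditions
#'
#' Laboratory categories fire at the first visit where platelets are below
#' `platelet_low` (strict `<`), creatinine above `creatinine_high` (strict
#' `>`) or AST/ALT above `transaminase_uln_multiplier` times its upper limit
#' of normal.  Note-based categories (new-onset headache, visual disturbance,
#' pulmonary edema) fire at the earliest dated non-negated mention; undated
#' mentions cannot establish new onset and are not used.  A missing
#' laboratory value never fires a category.
#'
#' @param bundle An `hdp_subject` with `$flags` populated.
#' @param t An [hdp_thresholds()].
#' @return Named integer vector: category -> onset day (categories that never
#'   fire are absent).
#' @export
detect_pe_related_conditions <- function(bundle, t = hdp_thresholds()) {
  v <- bundle$visits
  onsets <- integer(0)
  first_day <- function(hit) {
    if (any(hit)) v$gestational_age[which(hit)[1]] else NULL
  }
  if (nrow(v)) {
    lab <- list(
      thrombocytopenia = !is.na(v$platelet_count) & v$platelet_count < t$platelet_low,
      renal_dysfunction_lab = !is.na(v$serum_creatinine) &
        v$serum_creatinine > t$creatinine_high,
      hepatic_dysfunction_lab =
        (!is.na(v$ast) & v$ast > t$transaminase_uln_multiplier * t$ast_uln) |
        (!is.na(v$alt) & v$alt > t$transaminase_uln_multiplier * t$alt_uln))
    for (nm in names(lab)) {
      d <- first_day(lab[[nm]])
      if (!is.null(d)) onsets[nm] <- d
    }
  }
  if (!is.null(bundle$flags)) {
    for (nm in c("new_onset_headache", "visual_disturbance", "pulmonary_edema")) {
      f <- bundle$flags[[nm]]
      if (isTRUE(f$present) && !is.na(f$earliest_mention_ga))
        onsets[nm] <- f$earliest_mention_ga
    }
  }
  onsets
}

# Organ-dysfunction flag onsets (JSOG upgrade evidence): earliest dated
# non-negated note mention per flag in ORGAN_DYSFUNCTION_FLAGS.
organ_dysfunction_onsets <- function(bundle) {
  onsets <- integer(0)
  if (is.null(bundle$flags)) return(onsets)
  for (nm in ORGAN_DYSFUNCTION_FLAGS) {
    f <- bundle$flags[[nm]]
    if (isTRUE(f$present) && !is.na(f$earliest_mention_ga))
      onsets[nm] <- f$earliest_mention_ga
  }
  onsets
}

new_result <- function(label, onset_ga, evidence) {
  structure(list(label = label, onset_ga = onset_ga, evidence = evidence),
            class = "hdp_result")
}

eo_lo <- function(base, onset, t) {
  stopifnot(!is.na(onset))
  paste0(base, if (onset < t$eo_lo_cut) "_EO" else "_LO")
}

#' Phenotype one subject with the ACOG-concept rule engine (algorithm 1)
#'
#' Decision order: (1) chronic-hypertension status is established by a
#' hypertensive disease history (interview or note) or hypertension onset
#' before 20 weeks; (2) subjects with neither hypertension at any visit nor
#' chronic status are normotensive; (3) chronic hypertension with new-onset
#' proteinuria (at/after 20 weeks) or a PE-related condition at/after 20
#' weeks is superimposed preeclampsia, otherwise chronic hypertension;
#' (4) new-onset hypertension at/after 20 weeks with proteinuria or a
#' PE-related condition is preeclampsia, otherwise gestational hypertension;
#' (5) GH/SPE/PE carry EO when the disorder onset — the day the last defining
#' criterion is first met — is before 34 weeks, LO otherwise.
#'
#' @param bundle An `hdp_subject` (visits ingested; `$flags` populated for
#'   note-based conditions).
#' @param t An [hdp_thresholds()].
#' @return An `hdp_result`: `label`, `onset_ga`, `evidence` (fired rules in
#'   order).
#' @export
classify_algorithm1 <- function(bundle, t = hdp_thresholds()) {
  if (is.null(bundle$visits))
    stop("bundle has no visit table", call. = FALSE)
  htn_onset <- detect_hypertension_onset(bundle$visits, t)
  pu <- assess_proteinuria(bundle$visits, t)
  conds <- detect_pe_related_conditions(bundle, t)
  conds <- conds[conds >= t$ch_boundary]
  history <- isTRUE(bundle$interview_history_hypertension) ||
    (!is.null(bundle$flags) &&
       isTRUE(bundle$flags$history_of_hypertension$present))

  ev <- character(0)
  if (pu$early_pu) ev <- c(ev, "early_pu_channel_disabled")
  chronic <- history || (!is.na(htn_onset) && htn_onset < t$ch_boundary)
  if (chronic)
    ev <- c(ev, if (history) "history_of_hypertension" else "htn_before_20w")

  has_pu <- !is.na(pu$pu_onset_ga)
  has_cond <- length(conds) > 0
  superimposing_day <- suppressWarnings(
    min(c(pu$pu_onset_ga, unname(conds)), na.rm = TRUE))

  if (!chronic && is.na(htn_onset)) {
    return(new_result("NT", NA_integer_, c(ev, "no_hypertension")))
  }
  if (chronic) {
    if (has_pu || has_cond) {
      ev <- c(ev, if (has_pu) "new_onset_proteinuria",
              if (has_cond) paste0("condition:", names(conds)))
      onset <- as.integer(superimposing_day)
      return(new_result(eo_lo("SPE", onset, t), onset, c(ev, "spe")))
    }
    return(new_result("CH", htn_onset, c(ev, "ch")))
  }
  # new-onset hypertension at/after the 20-week boundary
  ev <- c(ev, "htn_at_or_after_20w")
  if (has_pu || has_cond) {
    ev <- c(ev, if (has_pu) "new_onset_proteinuria",
            if (has_cond) paste0("condition:", names(conds)))
    onset <- as.integer(max(htn_onset, superimposing_day))
    return(new_result(eo_lo("PE", onset, t), onset, c(ev, "pe")))
  }
  new_result(eo_lo("GH", htn_onset, t), htn_onset, c(ev, "gh"))
}

#' Phenotype one subject with the JSOG-concept rule engine (algorithm 2)
#'
#' Identical to [classify_algorithm1()] except for the upgrade paths for
#' hypertensive subjects without proteinuria: a subject algorithm 1 labels
#' GH is relabelled PE, and one labelled CH is relabelled SPE, when at least
#' one maternal organ-dysfunction flag (epigastralgia, HELLP syndrome,
#' eclampsia, FGR, renal dysfunction, hepatic dysfunction) is present with
#' onset at/after 20 weeks, or the infant is light-for-date.  EO/LO is
#' re-evaluated from the upgraded disorder's onset day: the later of the
#' hypertension onset and the earliest qualifying flag.  Light-for-date is
#' ascertained at delivery and contributes no antepartum timing; an upgrade
#' with no dated trigger falls back to the hypertension onset, or to the
#' delivery day when chronic hypertension rests on history alone.
#'
#' @inheritParams classify_algorithm1
#' @param lfd Logical light-for-date status; when `NULL` it is computed from
#'   the delivery record via [is_light_for_date()] with `lfd_table`.
#' @param lfd_table Percentile reference used when `lfd` is `NULL`.
#' @return An `hdp_result`.
#' @export
classify_algorithm2 <- function(bundle, t = hdp_thresholds(), lfd = NULL,
                                lfd_table = NULL) {
  res <- classify_algorithm1(bundle, t)
  base <- sub("_(EO|LO)$", "", res$label)
  if (!base %in% c("GH", "CH")) return(res)

  if (is.null(lfd)) {
    d <- bundle$delivery
    lfd <- !is.null(d) &&
      is_light_for_date(d$birth_weight, d$delivery_ga, d$infant_sex,
                        table = lfd_table %||% read_lfd_table(),
                        percentile = t$lfd_percentile)
  }
  od <- organ_dysfunction_onsets(bundle)
  od <- od[od >= t$ch_boundary]
  if (!length(od) && !isTRUE(lfd)) return(res)

  ev <- c(res$evidence,
          if (length(od)) paste0("organ_dysfunction:", names(od)),
          if (isTRUE(lfd)) "light_for_date")
  trigger <- suppressWarnings(min(unname(od)))
  onset <- if (base == "GH") {
    if (is.finite(trigger)) max(res$onset_ga, trigger) else res$onset_ga
  } else if (is.finite(trigger)) {
    trigger
  } else if (!is.na(res$onset_ga) && res$onset_ga >= t$ch_boundary) {
    res$onset_ga
  } else {
    bundle$delivery$delivery_ga
  }
  onset <- as.integer(onset)
  up <- if (base == "GH") "PE" else "SPE"
  new_result(eo_lo(up, onset, t), onset, c(ev, paste0("upgrade_", base, "_to_", up)))
}

#' Phenotype a whole cohort
#'
#' @param bundles List of `hdp_subject` with flags populated (see
#'   [mine_cohort()]).
#' @param t An [hdp_thresholds()].
#' @param algorithm 1 (ACOG concepts) or 2 (JSOG concepts).
#' @param lfd_table Percentile reference for algorithm 2.
#' @return Data frame: `subject_id`, `label`, `onset_ga`, `evidence`
#'   (rule ids joined by `;`).
#' @export
classify_cohort <- function(bundles, t = hdp_thresholds(), algorithm = 1,
                            lfd_table = NULL) {
  if (algorithm == 2 && is.null(lfd_table)) lfd_table <- read_lfd_table()
  rows <- lapply(bundles, function(b) {
    r <- if (algorithm == 2) classify_algorithm2(b, t, lfd_table = lfd_table)
    else classify_algorithm1(b, t)
    data.frame(subject_id = b$subject_id, label = r$label,
               onset_ga = if (is.null(r$onset_ga)) NA_integer_ else r$onset_ga,
               evidence = paste(r$evidence, collapse = ";"))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cross-tabulate and reconcile the two algorithms' labels
#'
#' @param results1,results2 Label data frames from [classify_cohort()] for
#'   algorithms 1 and 2 on the same subjects.
#' @return List: `table` (8 x 8 cross-tabulation, algorithm 1 rows), and
#'   `discordant` (data frame `subject_id`, `label1`, `label2`, `rule` —
#'   the upgrade rule responsible, from the algorithm-2 evidence trail).
#' @export
compare_algorithms <- function(results1, results2) {
  if (!setequal(results1$subject_id, results2$subject_id) ||
      nrow(results1) != nrow(results2))
    stop("the two result sets cover different subjects", call. = FALSE)
  results2 <- results2[match(results1$subject_id, results2$subject_id), ]
  l1 <- factor(results1$label, levels = HDP_LABELS)
  l2 <- factor(results2$label, levels = HDP_LABELS)
  tab <- table(algorithm1 = l1, algorithm2 = l2)
  dis <- which(as.character(l1) != as.character(l2))
  discordant <- data.frame(
    subject_id = results1$subject_id[dis],
    label1 = as.character(l1)[dis], label2 = as.character(l2)[dis],
    rule = vapply(dis, function(i) {
      ev <- strsplit(results2$evidence[i], ";", fixed = TRUE)[[1]]
      hit <- grep("^(organ_dysfunction:|light_for_date|upgrade_)", ev, value = TRUE)
      paste(hit, collapse = ";")
    }, ""))
  list(table = tab, discordant = discordant)
}
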