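#' Classification thresholds
#'
#' All numeric cut points used by the rule engines, each a config field.
#' Defaults follow the ACOG/JSOG guideline values: hypertension at
#' 140/90 mmHg; the chronic-hypertension boundary at 20 weeks (140 days);
#' the early-/late-onset split at 34 weeks (238 days); proteinuria at a
#' single dipstick 2+ or 1+ at two distinct visits; thrombocytopenia at
#' platelets < 100 x 10^3/uL; renal dysfunction at creatinine > 1.1 mg/dL;
#' hepatic dysfunction at transaminases > 2 x the upper limit of normal;
#' light-for-date below the 10th percentile.
#'
#' @param sbp_cut,dbp_cut Blood-pressure cuts, mmHg (inclusive, `>=`).
#' @param ch_boundary Chronic-hypertension boundary, days ("before 20 weeks"
#'   means `< 140`).
#' @param eo_lo_cut Early-/late-onset cut, days (early iff onset `< 238`).
#' @param pu_single_grade Dipstick rank qualifying at a single visit
#'   (default 3 = "2+").
#' @param pu_repeat_grade,pu_repeat_count Dipstick rank (default 2 = "1+")
#'   qualifying when seen at `pu_repeat_count` distinct visits.
#' @param bp_repeat_count Number of qualifying visits required for the
#'   hypertension predicate (default 1; cohort visit spacing rarely supports
#'   the guidelines' short-interval re-measurement clause).
#' @param platelet_low Platelet cut, 10^3/uL (strict `<`).
#' @param creatinine_high Creatinine cut, mg/dL (strict `>`).
#' @param transaminase_uln_multiplier Multiplier over the upper limits of
#'   normal `ast_uln` / `alt_uln` (U/L; strict `>`).
#' @param lfd_percentile Percentile cut for light-for-date (strict `<` the
#'   table cutoff).
#' @return A list of class `hdp_thresholds`.
#' @export
hdp_thresholds <- function(sbp_cut = 140, dbp_cut = 90, ch_boundary = 140L,
                           eo_lo_cut = 238L, pu_single_grade = 3L,
                           pu_repeat_grade = 2L, pu_repeat_count = 2L,
                           bp_repeat_count = 1L, platelet_low = 100,
                           creatinine_high = 1.1,
                           transaminase_uln_multiplier = 2,
                           ast_uln = 30, alt_uln = 30, lfd_percentile = 10L) {
  t <- list(sbp_cut = sbp_cut, dbp_cut = dbp_cut,
            ch_boundary = as.integer(ch_boundary),
            eo_lo_cut = as.integer(eo_lo_cut),
            pu_single_grade = as.integer(pu_single_grade),
            pu_repeat_grade = as.integer(pu_repeat_grade),
            pu_repeat_count = as.integer(pu_repeat_count),
            bp_repeat_count = as.integer(bp_repeat_count),
            platelet_low = platelet_low, creatinine_high = creatinine_high,
            transaminase_uln_multiplier = transaminase_uln_multiplier,
            ast_uln = ast_uln, alt_uln = alt_uln,
            lfd_percentile = as.integer(lfd_percentile))
  stopifnot(t$sbp_cut > 0, t$dbp_cut > 0, t$ch_boundary > 0,
            t$pu_single_grade >= t$pu_repeat_grade,
            t$ch_boundary < t$eo_lo_cut)
  structure(t, class = "hdp_thresholds")
}

#' Load thresholds from a YAML file
#' @param path YAML file whose keys are [hdp_thresholds()] arguments.
#' @return An `hdp_thresholds`.
#' @export
read_thresholds <- function(path) {
  do.call(hdp_thresholds, yaml::read_yaml(path))
}

#' Synthetic birth-weight percentile reference
#'
#' Builds the light-for-date reference table shipped at
#' `inst/extdata/lfd_reference_synthetic.csv`.  This is a synthetic stand-in
#' for national neonatal anthropometric charts: median weight by completed
#' gestational week follows a Gompertz growth curve reaching about 3000 g at
#' 40 weeks, with a +/-3% sex offset and normal-theory percentiles at a 12%
#' coefficient of variation.  It exists so that the light-for-date predicate
#' is fully exercisable without access to a published chart; substitute a
#' real chart via the `table` argument of [is_light_for_date()] for
#' production use.
#'
#' @param weeks Completed gestational weeks covered (default 22:42).
#' @return Data frame: `week`, `sex`, `p03`, `p10`, `p50`, `p90`.
#' @export
make_lfd_reference <- function(weeks = 22:42) {
  median_g <- function(w) 3500 * exp(-exp(-0.155 * (w - 28)))
  cv <- 0.12
  grid <- expand.grid(week = weeks, sex = c("male", "female"),
                      stringsAsFactors = FALSE)
  mult <- ifelse(grid$sex == "male", 1.03, 0.97)
  m <- median_g(grid$week) * mult
  z <- function(p) stats::qnorm(p / 100)
  data.frame(week = grid$week, sex = grid$sex,
             p03 = round(m * (1 + z(3) * cv)),
             p10 = round(m * (1 + z(10) * cv)),
             p50 = round(m),
             p90 = round(m * (1 + z(90) * cv)))
}

#' Read the light-for-date percentile table
#'
#' @param path CSV with columns `week`, `sex` and percentile columns named
#'   `pNN`; defaults to the shipped synthetic reference.
#' @return Data frame.
#' @export
read_lfd_table <- function(path = system.file("extdata",
                                              "lfd_reference_synthetic.csv",
                                              package = "hdpheno")) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Light-for-date predicate
#'
#' TRUE iff the birth weight is strictly below the configured percentile
#' cutoff for the infant's completed gestational week and sex.  Weight exactly
#' at the cutoff is not light-for-date.  An `"unknown"` sex is assessed
#' against the stricter (lower, female) cutoff so that the predicate never
#' fires on a weight a known sex would not have flagged.
#'
#' @param birth_weight Grams (`NA` returns `FALSE`: no data, no flag).
#' @param delivery_ga Gestational age at delivery, days.
#' @param sex `"male"`, `"female"` or `"unknown"`.
#' @param table Percentile reference (see [read_lfd_table()]).
#' @param percentile Percentile cut (column `pNN` must exist).
#' @return Logical scalar.
#' @export
is_light_for_date <- function(birth_weight, delivery_ga, sex = "unknown",
                              table = read_lfd_table(), percentile = 10L) {
  if (is.na(birth_weight)) return(FALSE)
  week <- as.integer(delivery_ga) %/% 7L
  col <- sprintf("p%02d", as.integer(percentile))
  if (!col %in% names(table))
    stop("percentile column ", col, " not in reference table", call. = FALSE)
  sexes <- if (sex == "unknown") c("male", "female") else sex
  rows <- table[table$week == week & table$sex %in% sexes, , drop = FALSE]
  if (!nrow(rows) || length(unique(table$sex[table$week == week])) <
      length(unique(sexes)))
    stop(sprintf("gestational week %d (%s) not covered by the reference table",
                 week, sex), call. = FALSE)
  cutoff <- min(rows[[col]])
  birth_weight < cutoff
}
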