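#' Urine-protein dipstick grades
#'
#' Canonical ordinal scale for the urine-protein dipstick readout recorded at
#' prenatal checkups, from `negative` (rank 0) to `4+` (rank 5).
#'
#' @format Character vector of the six canonical tokens in ascending order.
#' @export
DIPSTICK_LEVELS <- c("negative", "trace", "1+", "2+", "3+", "4+")

#' Convert dipstick tokens to ordinal ranks
#'
#' Maps dipstick tokens to integer ranks 0 (negative) .. 5 (4+).  Tokens are
#' matched case-insensitively against the canonical scale plus any aliases
#' supplied (e.g. `"+-" = "trace"`, `"-" = "negative"`).
#'
#' @param x Character vector of dipstick tokens (`NA` and `""` pass through
#'   as `NA`).
#' @param aliases Named character vector mapping source tokens to canonical
#'   tokens.
#' @return Integer vector of ranks; `NA` where the input was missing.
#' @export
dipstick_grade <- function(x, aliases = NULL) {
  x <- trimws(tolower(as.character(x)))
  x[x == ""] <- NA_character_
  if (length(aliases)) {
    names(aliases) <- tolower(names(aliases))
    hit <- x %in% names(aliases)
    x[hit] <- tolower(unname(aliases[x[hit]]))
  }
  out <- match(x, DIPSTICK_LEVELS) - 1L
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad)) {
    stop(sprintf("unparseable dipstick token '%s' at row %d", x[bad[1]], bad[1]),
         call. = FALSE)
  }
  out
}

#' Construct a prenatal visit record
#'
#' @param gestational_age Integer days since last menstrual period
#'   (0 < ga <= 315).
#' @param sbp,dbp Systolic and diastolic blood pressure, mmHg (positive;
#'   `NA` when not measured).
#' @param dipstick Dipstick rank 0..5 or canonical token, `NA` when missing.
#' @param platelet_count Platelets, 10^3/uL (optional).
#' @param serum_creatinine Serum creatinine, mg/dL (optional).
#' @param ast,alt Transaminases, U/L (optional).
#' @return One-row data frame with the visit fields.
#' @export
visit <- function(gestational_age, sbp = NA, dbp = NA, dipstick = NA,
                  platelet_count = NA, serum_creatinine = NA,
                  ast = NA, alt = NA) {
  ga <- as.integer(gestational_age)
  if (is.na(ga) || ga <= 0L || ga > 315L)
    stop("gestational_age must be in (0, 315] days", call. = FALSE)
  if (is.character(dipstick)) dipstick <- dipstick_grade(dipstick)
  sbp <- as.numeric(sbp); dbp <- as.numeric(dbp)
  if (!is.na(sbp) && sbp <= 0) stop("sbp must be positive", call. = FALSE)
  if (!is.na(dbp) && dbp <= 0) stop("dbp must be positive", call. = FALSE)
  if (!is.na(sbp) && !is.na(dbp) && dbp >= sbp)
    stop("dbp must be below sbp", call. = FALSE)
  data.frame(gestational_age = ga, sbp = sbp, dbp = dbp,
             dipstick = as.integer(dipstick),
             platelet_count = as.numeric(platelet_count),
             serum_creatinine = as.numeric(serum_creatinine),
             ast = as.numeric(ast), alt = as.numeric(alt))
}

#' Construct a delivery record
#'
#' @param delivery_ga Gestational age at delivery, integer days.
#' @param birth_weight Birth weight, grams (`NA` allowed).
#' @param infant_sex `"male"`, `"female"` or `"unknown"`.
#' @param live_birth Logical.
#' @param parity Non-negative integer or `NA`.
#' @return A list of class `hdp_delivery`.
#' @export
delivery_record <- function(delivery_ga, birth_weight = NA,
                            infant_sex = "unknown", live_birth = TRUE,
                            parity = NA) {
  ga <- as.integer(delivery_ga)
  live_birth <- isTRUE(live_birth)
  if (live_birth && (is.na(ga) || ga < 140L || ga > 315L))
    stop("delivery_ga must be in [140, 315] days for live births", call. = FALSE)
  bw <- as.numeric(birth_weight)
  if (!is.na(bw) && bw <= 0) stop("birth_weight must be positive", call. = FALSE)
  infant_sex <- match.arg(infant_sex, c("male", "female", "unknown"))
  structure(list(delivery_ga = ga, birth_weight = bw, infant_sex = infant_sex,
                 live_birth = live_birth, parity = as.integer(parity)),
            class = "hdp_delivery")
}

#' Construct a subject bundle
#'
#' One pregnancy: the interview history flag, the ordered visit table, the
#' delivery record and the free-text notes.  Visits are sorted by gestational
#' age; duplicated visit days are collapsed (identical rows de-duplicated;
#' conflicting rows merged conservatively toward detection by keeping the
#' higher BP / dipstick grade and the more abnormal laboratory value, with the
#' conflict logged in `attr(visits, "conflicts")`).
#'
#' @param subject_id Opaque string, unique within a cohort.
#' @param interview_history_hypertension Logical: hypertensive disease history
#'   from the first-visit interview.
#' @param visits Data frame of visit rows (see [visit()]).
#' @param delivery [delivery_record()] or `NULL`.
#' @param notes Data frame with columns `gestational_age` (days or `NA`) and
#'   `text`, or `NULL`.
#' @param flags Optional pre-computed [aggregate_flags()] result.
#' @return A list of class `hdp_subject`.
#' @export
subject_bundle <- function(subject_id, interview_history_hypertension = FALSE,
                           visits = NULL, delivery = NULL, notes = NULL,
                           flags = NULL) {
  if (is.null(visits)) {
    visits <- visit(1)[0, ]
  }
  visits <- collapse_visits(visits)
  if (is.null(notes)) {
    notes <- data.frame(gestational_age = integer(0), text = character(0))
  }
  structure(list(subject_id = as.character(subject_id),
                 interview_history_hypertension = isTRUE(interview_history_hypertension),
                 visits = visits, delivery = delivery, notes = notes,
                 flags = flags),
            class = "hdp_subject")
}

# Sort visits ascending by gestational age; collapse same-day rows.
# Conflicting same-day values merge toward detection: max BP and dipstick,
# min platelets, max creatinine/AST/ALT.  Conflicts are recorded on the
# returned data frame as attr "conflicts".
collapse_visits <- function(visits) {
  if (!nrow(visits)) return(visits)
  visits <- visits[order(visits$gestational_age), , drop = FALSE]
  conflicts <- integer(0)
  if (anyDuplicated(visits$gestational_age)) {
    pick <- function(v, f) if (all(is.na(v))) v[1] else f(v, na.rm = TRUE)
    merged <- lapply(split(visits, visits$gestational_age), function(g) {
      if (nrow(unique(g)) > 1L) conflicts <<- c(conflicts, g$gestational_age[1])
      data.frame(gestational_age = g$gestational_age[1],
                 sbp = pick(g$sbp, max), dbp = pick(g$dbp, max),
                 dipstick = as.integer(pick(g$dipstick, max)),
                 platelet_count = pick(g$platelet_count, min),
                 serum_creatinine = pick(g$serum_creatinine, max),
                 ast = pick(g$ast, max), alt = pick(g$alt, max))
    })
    visits <- do.call(rbind, merged)
  }
  rownames(visits) <- NULL
  attr(visits, "conflicts") <- conflicts
  visits
}

#' Default column mapping and dipstick aliases for cohort files
#'
#' The schema configuration names, for each of the four cohort files, the
#' source column holding each field the pipeline needs, plus a dipstick alias
#' table for site-specific tokens.  Override entries to ingest files with
#' different headers.
#'
#' @param ... Named overrides merged over the defaults (e.g.
#'   `dipstick_aliases = c("+-" = "trace")`).
#' @return A list of class `hdp_schema`.
#' @export
cohort_schema <- function(...) {
  schema <- list(
    subjects = c(subject_id = "subject_id",
                 interview_history_hypertension = "history_hypertension"),
    visits = c(subject_id = "subject_id", gestational_age = "gestational_age",
               sbp = "sbp", dbp = "dbp", dipstick = "dipstick",
               platelet_count = "platelet_count",
               serum_creatinine = "serum_creatinine", ast = "ast", alt = "alt"),
    delivery = c(subject_id = "subject_id", delivery_ga = "delivery_ga",
                 birth_weight = "birth_weight", infant_sex = "infant_sex",
                 live_birth = "live_birth", parity = "parity"),
    notes = c(subject_id = "subject_id", gestational_age = "gestational_age",
              text = "text"),
    optional = c("platelet_count", "serum_creatinine", "ast", "alt", "parity"),
    dipstick_aliases = c("-" = "negative", "+-" = "trace", "+/-" = "trace",
                         "+" = "1+", "++" = "2+", "+++" = "3+", "++++" = "4+")
  )
  dots <- list(...)
  schema[names(dots)] <- dots
  structure(schema, class = "hdp_schema")
}

read_mapped <- function(path, mapping, optional, what) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  need <- mapping[!names(mapping) %in% optional]
  miss <- setdiff(unname(need), names(df))
  if (length(miss)) {
    stop(sprintf("%s file '%s' is missing mandatory column(s): %s",
                 what, path, paste(miss, collapse = ", ")), call. = FALSE)
  }
  out <- lapply(mapping, function(col) {
    if (col %in% names(df)) df[[col]] else rep(NA_character_, nrow(df))
  })
  as.data.frame(out, stringsAsFactors = FALSE)
}

num_or_na <- function(x) suppressWarnings(as.numeric(x))
bool_col <- function(x) tolower(trimws(x)) %in% c("true", "t", "1", "yes")

#' Read a cohort from its four delimited files
#'
#' Ingests the subjects, visits, delivery and notes CSVs (UTF-8, header row)
#' into a list of subject bundles.  Rows that violate the visit or delivery
#' invariants are reported in `attr(result, "issues")` rather than silently
#' dropped; structural problems (missing mandatory column, unparseable
#' dipstick token) stop with an informative error.
#'
#' @param dir Directory containing `subjects.csv`, `visits.csv`,
#'   `delivery.csv`, `notes.csv` (a notes file is optional); alternatively a
#'   named list of the four file paths.
#' @param schema A [cohort_schema()].
#' @return List of `hdp_subject` bundles, `attr` `issues` a character vector
#'   of row-level problems.
#' @export
read_cohort <- function(dir, schema = cohort_schema()) {
  paths <- if (is.list(dir) && !is.null(names(dir))) dir else {
    list(subjects = file.path(dir, "subjects.csv"),
         visits = file.path(dir, "visits.csv"),
         delivery = file.path(dir, "delivery.csv"),
         notes = file.path(dir, "notes.csv"))
  }
  subj <- read_mapped(paths$subjects, schema$subjects, schema$optional, "subjects")
  vis <- read_mapped(paths$visits, schema$visits, schema$optional, "visits")
  del <- read_mapped(paths$delivery, schema$delivery, schema$optional, "delivery")
  notes <- if (!is.null(paths$notes) && file.exists(paths$notes)) {
    read_mapped(paths$notes, schema$notes, schema$optional, "notes")
  } else {
    data.frame(subject_id = character(0), gestational_age = character(0),
               text = character(0))
  }

  if (anyDuplicated(subj$subject_id))
    stop("duplicated subject_id in subjects file", call. = FALSE)

  vis$gestational_age <- as.integer(num_or_na(vis$gestational_age))
  vis$sbp <- num_or_na(vis$sbp); vis$dbp <- num_or_na(vis$dbp)
  vis$dipstick <- dipstick_grade(vis$dipstick, schema$dipstick_aliases)
  for (lab in c("platelet_count", "serum_creatinine", "ast", "alt"))
    vis[[lab]] <- num_or_na(vis[[lab]])
  notes$gestational_age <- as.integer(num_or_na(notes$gestational_age))

  issues <- character(0)
  bad_ga <- which(is.na(vis$gestational_age) | vis$gestational_age <= 0L |
                    vis$gestational_age > 315L)
  if (length(bad_ga)) {
    issues <- c(issues, sprintf("visits row %d: invalid gestational_age", bad_ga))
    vis <- vis[-bad_ga, , drop = FALSE]
  }
  bad_bp <- which(!is.na(vis$sbp) & !is.na(vis$dbp) & vis$dbp >= vis$sbp)
  if (length(bad_bp)) {
    issues <- c(issues, sprintf("visits row %d: dbp >= sbp, BP pair blanked", bad_bp))
    vis$sbp[bad_bp] <- NA_real_; vis$dbp[bad_bp] <- NA_real_
  }

  vis_by <- split(vis[setdiff(names(vis), "subject_id")], vis$subject_id)
  del_by <- split(del, del$subject_id)
  notes_by <- split(notes[setdiff(names(notes), "subject_id")], notes$subject_id)

  bundles <- lapply(seq_len(nrow(subj)), function(i) {
    sid <- subj$subject_id[i]
    dl <- NULL
    if (!is.null(del_by[[sid]]) && nrow(del_by[[sid]])) {
      d <- del_by[[sid]][1, ]
      dl <- tryCatch(
        delivery_record(num_or_na(d$delivery_ga), num_or_na(d$birth_weight),
                        if (is.na(d$infant_sex) || !nzchar(d$infant_sex)) "unknown"
                        else tolower(d$infant_sex),
                        bool_col(d$live_birth), num_or_na(d$parity)),
        error = function(e) {
          issues <<- c(issues, sprintf("delivery for %s: %s", sid, conditionMessage(e)))
          NULL
        })
    }
    v <- vis_by[[sid]]
    if (is.null(v)) v <- visit(1)[0, ]
    subject_bundle(sid, bool_col(subj$interview_history_hypertension[i]),
                   visits = v, delivery = dl, notes = notes_by[[sid]])
  })
  names(bundles) <- subj$subject_id
  attr(bundles, "issues") <- issues
  bundles
}

#' Write a cohort back to the four-file CSV layout
#'
#' Inverse of [read_cohort()] with the default schema; round-tripping a cohort
#' through `write_cohort()` and [read_cohort()] yields identical bundles.
#'
#' @param bundles List of `hdp_subject`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(bundles, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  subj <- data.frame(
    subject_id = vapply(bundles, `[[`, "", "subject_id"),
    history_hypertension = vapply(bundles, `[[`, NA, "interview_history_hypertension"))
  vis <- do.call(rbind, lapply(bundles, function(b) {
    if (!nrow(b$visits)) return(NULL)
    v <- b$visits
    v$dipstick <- ifelse(is.na(v$dipstick), "", DIPSTICK_LEVELS[v$dipstick + 1L])
    cbind(subject_id = b$subject_id, v)
  }))
  del <- do.call(rbind, lapply(bundles, function(b) {
    if (is.null(b$delivery)) return(NULL)
    d <- b$delivery
    data.frame(subject_id = b$subject_id, delivery_ga = d$delivery_ga,
               birth_weight = d$birth_weight, infant_sex = d$infant_sex,
               live_birth = d$live_birth, parity = d$parity)
  }))
  notes <- do.call(rbind, lapply(bundles, function(b) {
    if (is.null(b$notes) || !nrow(b$notes)) return(NULL)
    cbind(subject_id = b$subject_id, b$notes)
  }))
  utils::write.csv(subj, file.path(dir, "subjects.csv"), row.names = FALSE)
  utils::write.csv(vis %||% visit(1)[0, ], file.path(dir, "visits.csv"),
                   row.names = FALSE)
  utils::write.csv(del %||% data.frame(), file.path(dir, "delivery.csv"),
                   row.names = FALSE)
  utils::write.csv(notes %||% data.frame(subject_id = character(0),
                                         gestational_age = integer(0),
                                         text = character(0)),
                   file.path(dir, "notes.csv"), row.names = FALSE)
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply the study-inclusion filter
#'
#' A subject is included iff it has a delivery record, at least one visit with
#' a blood-pressure measurement AND at least one dipstick value, a live birth,
#' and did not withdraw.  Every excluded subject is logged with all applicable
#' reasons.
#'
#' @param bundles List of `hdp_subject`.
#' @param withdrawn_ids Character vector of withdrawn subject ids.
#' @return List with `included` (bundles) and `exclusions` (data frame
#'   `subject_id`, `reason`; one row per reason).
#' @export
apply_inclusion_filters <- function(bundles, withdrawn_ids = character(0)) {
  reasons <- lapply(bundles, function(b) {
    r <- character(0)
    if (is.null(b$delivery)) r <- c(r, "no_delivery_record")
    has_bp <- nrow(b$visits) > 0 && any(!is.na(b$visits$sbp) | !is.na(b$visits$dbp))
    has_pu <- nrow(b$visits) > 0 && any(!is.na(b$visits$dipstick))
    if (!has_bp || !has_pu) r <- c(r, "no_bp_pu_data")
    if (!is.null(b$delivery) && !b$delivery$live_birth) r <- c(r, "no_live_birth")
    if (b$subject_id %in% withdrawn_ids) r <- c(r, "withdrawn")
    r
  })
  keep <- lengths(reasons) == 0L
  excl <- do.call(rbind, lapply(which(!keep), function(i) {
    data.frame(subject_id = bundles[[i]]$subject_id, reason = reasons[[i]])
  }))
  list(included = bundles[keep],
       exclusions = excl %||% data.frame(subject_id = character(0),
                                         reason = character(0)))
}

#' Percentage of a count, rounded half-up to two decimals
#'
#' Exact integer arithmetic: `100 * count / total` rounded half-up at the
#' second decimal, the convention used throughout the reporting tables
#' (e.g. 1813 of 22452 is 8.075004...% and prints as 8.08).
#'
#' @param count Non-negative integer, `count <= total`.
#' @param total Positive integer.
#' @return Numeric percentage with at most two decimals.
#' @export
format_percentage <- function(count, total) {
  count <- as.numeric(count); total <- as.numeric(total)
  if (any(total <= 0)) stop("total must be positive", call. = FALSE)
  if (any(count < 0 | count > total)) stop("count must be in [0, total]", call. = FALSE)
  q <- (10000 * count) %/% total
  r <- (10000 * count) %% total
  (q + (2 * r >= total)) / 100
}
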