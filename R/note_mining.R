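#' Flag categories mined from clinical notes
#'
#' The history flag plus the maternal organ-dysfunction and PE-related
#' conditions the classifiers consume.
#' @export
FLAG_CATEGORIES <- c("history_of_hypertension", "epigastralgia",
                     "hellp_syndrome", "eclampsia", "fgr", "renal_dysfunction",
                     "hepatic_dysfunction", "new_onset_headache",
                     "visual_disturbance", "pulmonary_edema")

#' Organ-dysfunction flags recognised by the JSOG-style upgrade rule
#' @export
ORGAN_DYSFUNCTION_FLAGS <- c("epigastralgia", "hellp_syndrome", "eclampsia",
                             "fgr", "renal_dysfunction", "hepatic_dysfunction")

#' Construct a term dictionary for note mining
#'
#' The engine, not the lexicon, is the contract: every category ships with
#' editable English and Japanese seed terms, and site dictionaries are loaded
#' from YAML with [read_flag_dictionary()].  ASCII terms match at word
#' boundaries; non-ASCII (e.g. Japanese) terms match as substrings since the
#' script has no word delimiters.
#'
#' @param terms Named list: category -> character vector of surface terms.
#'   Categories must cover [FLAG_CATEGORIES]; each needs at least one term.
#' @param negation_cues Cues that negate a hit when found within
#'   `negation_window` characters before the term.
#' @param post_negation_cues Cues that negate when found within the window
#'   after the term (e.g. "ruled out").
#' @param negation_window Window width in characters (default 10).
#' @return A list of class `hdp_dictionary` with normalized terms.
#' @export
flag_dictionary <- function(terms = default_flag_terms(),
                            negation_cues = c("no", "not", "without", "denies",
                                              "negative for", "なし",
                                              "否定"),
                            post_negation_cues = c("ruled out", "not present",
                                                   "なし"),
                            negation_window = 10L) {
  miss <- setdiff(FLAG_CATEGORIES, names(terms))
  if (length(miss))
    stop("dictionary missing categories: ", paste(miss, collapse = ", "),
         call. = FALSE)
  terms <- lapply(terms, function(tt) {
    tt <- unique(normalize_text(tt))
    tt <- tt[nzchar(tt)]
    if (!length(tt)) stop("every category needs at least one non-empty term",
                          call. = FALSE)
    tt
  })
  structure(list(terms = terms,
                 negation_cues = unique(normalize_text(negation_cues)),
                 post_negation_cues = unique(normalize_text(post_negation_cues)),
                 negation_window = as.integer(negation_window)),
            class = "hdp_dictionary")
}

#' Seed terms per flag category (English + Japanese)
#' @return Named list category -> terms.
#' @export
default_flag_terms <- function() {
  list(
    history_of_hypertension = c("history of hypertension", "hypertension",
                                "chronic hypertension", "high blood pressure",
                                "高血圧"),
    epigastralgia = c("epigastralgia", "epigastric pain",
                      "心窩部痛"),
    hellp_syndrome = c("hellp syndrome", "hellp", "ＨＥＬＬＰ"),
    eclampsia = c("eclampsia", "eclamptic seizure", "子癇"),
    fgr = c("fgr", "fetal growth restriction", "iugr",
            "胎児発育不全"),
    renal_dysfunction = c("renal dysfunction", "renal insufficiency",
                          "腎機能障害"),
    hepatic_dysfunction = c("hepatic dysfunction", "liver dysfunction",
                            "肝機能障害"),
    new_onset_headache = c("new-onset headache", "new onset headache",
                           "severe headache", "頭痛"),
    visual_disturbance = c("visual disturbance", "blurred vision", "scotoma",
                           "視力障害"),
    pulmonary_edema = c("pulmonary edema", "pulmonary oedema",
                        "肺水腫")
  )
}

#' Load a term dictionary from a YAML file
#'
#' Expected keys: `terms` (category -> list of terms), and optionally
#' `negation_cues`, `post_negation_cues`, `negation_window`.
#'
#' @param path YAML file path.
#' @return An `hdp_dictionary`.
#' @export
read_flag_dictionary <- function(path) {
  cfg <- yaml::read_yaml(path)
  args <- list(terms = lapply(cfg$terms, unlist))
  for (k in c("negation_cues", "post_negation_cues", "negation_window"))
    if (!is.null(cfg[[k]])) args[[k]] <- unlist(cfg[[k]])
  do.call(flag_dictionary, args)
}

#' Normalize free text for matching
#'
#' Unicode compatibility (NFKC) normalization, case folding and whitespace
#' collapsing; deterministic, and tolerant of full-width Japanese characters
#' (full-width "ＨＥＬＬＰ" normalizes to "hellp").
#'
#' @param text Character vector.
#' @return Normalized character vector of the same length.
#' @export
normalize_text <- function(text) {
  out <- stringi::stri_trans_nfkc(as.character(text))
  out <- stringi::stri_trans_tolower(out)
  out <- gsub("\\s+", " ", out)
  trimws(out)
}

is_ascii_term <- function(x) !grepl("[^\\x01-\\x7f]", x, perl = TRUE)

# All (start, end) spans of `term` in normalized `text`; ASCII terms are
# anchored at word boundaries, non-ASCII terms are plain substrings.
term_spans <- function(text, term) {
  pat <- if (is_ascii_term(term)) {
    paste0("(?<![[:alnum:]])", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", term),
           "(?![[:alnum:]])")
  } else {
    gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", term)
  }
  m <- gregexpr(pat, text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(NULL)
  data.frame(start = as.integer(m), end = as.integer(m) + attr(m, "match.length") - 1L)
}

#' Mine one note for flag-category mentions
#'
#' Reports every occurrence of a dictionary term.  On overlapping matches the
#' longest term wins.  A hit is negated iff a negation cue occurs within the
#' negation window immediately before the term (or a post-positive cue within
#' the window after it).
#'
#' @param text One free-text note.
#' @param dict An [flag_dictionary()].
#' @return Data frame: `category`, `term`, `start`, `end`, `negated`, ordered
#'   by position in the normalized text.
#' @export
mine_note <- function(text, dict) {
  stopifnot(inherits(dict, "hdp_dictionary"))
  ntext <- normalize_text(text)
  empty <- data.frame(category = character(0), term = character(0),
                      start = integer(0), end = integer(0), negated = logical(0))
  if (!nzchar(ntext)) return(empty)
  hits <- do.call(rbind, lapply(names(dict$terms), function(cat) {
    do.call(rbind, lapply(dict$terms[[cat]], function(term) {
      sp <- term_spans(ntext, term)
      if (is.null(sp)) return(NULL)
      cbind(data.frame(category = cat, term = term), sp)
    }))
  }))
  if (is.null(hits) || !nrow(hits)) return(empty)
  # longest term wins on overlap
  hits <- hits[order(hits$end - hits$start, decreasing = TRUE), ]
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    if (!keep[i]) next
    if (i < nrow(hits)) {
      j <- (i + 1):nrow(hits)
      ov <- hits$start[j] <= hits$end[i] & hits$end[j] >= hits$start[i]
      keep[j][ov] <- FALSE
    }
  }
  hits <- hits[keep, , drop = FALSE]
  hits <- hits[order(hits$start, hits$end), , drop = FALSE]

  w <- dict$negation_window
  hits$negated <- vapply(seq_len(nrow(hits)), function(i) {
    pre <- substr(ntext, max(1L, hits$start[i] - w), hits$start[i] - 1L)
    post <- substr(ntext, hits$end[i] + 1L,
                   min(nchar(ntext), hits$end[i] + w))
    any(vapply(dict$negation_cues, function(cue) {
      if (is_ascii_term(cue)) {
        grepl(paste0("(?<![[:alnum:]])", cue, "(?![[:alnum:]])"), pre, perl = TRUE)
      } else grepl(cue, pre, fixed = TRUE)
    }, NA)) ||
      any(vapply(dict$post_negation_cues, function(cue) {
        if (is_ascii_term(cue)) {
          grepl(paste0("(?<![[:alnum:]])", cue, "(?![[:alnum:]])"), post, perl = TRUE)
        } else grepl(cue, post, fixed = TRUE)
      }, NA))
  }, NA)
  rownames(hits) <- NULL
  hits
}

#' Aggregate note hits into per-subject flags
#'
#' A category is present iff it has at least one non-negated hit across the
#' subject's notes; `earliest_mention_ga` is the minimum gestational age over
#' dated non-negated hits (`NA` if every such hit is undated).
#'
#' @param notes Data frame with `gestational_age` (days, `NA` allowed) and
#'   `text`; may have zero rows.
#' @param dict An [flag_dictionary()].
#' @param interview_history_hypertension Logical; OR-combined into the
#'   `history_of_hypertension` flag (history also comes from the self-reported
#'   first-visit interview).
#' @return A list of class `hdp_flags`: per category
#'   `list(present, earliest_mention_ga, evidence)` where evidence rows carry
#'   the note index and matched span.
#' @export
aggregate_flags <- function(notes, dict = flag_dictionary(),
                            interview_history_hypertension = FALSE) {
  flags <- stats::setNames(lapply(FLAG_CATEGORIES, function(cat) {
    list(present = FALSE, earliest_mention_ga = NA_integer_,
         evidence = data.frame(note = integer(0), term = character(0),
                               start = integer(0), end = integer(0)))
  }), FLAG_CATEGORIES)
  if (!is.null(notes) && nrow(notes)) {
    for (i in seq_len(nrow(notes))) {
      hits <- mine_note(notes$text[i], dict)
      hits <- hits[!hits$negated, , drop = FALSE]
      for (j in seq_len(nrow(hits))) {
        cat <- hits$category[j]
        f <- flags[[cat]]
        f$present <- TRUE
        ga <- notes$gestational_age[i]
        if (!is.na(ga)) {
          f$earliest_mention_ga <-
            min(f$earliest_mention_ga, as.integer(ga), na.rm = TRUE)
        }
        f$evidence <- rbind(f$evidence,
                            data.frame(note = i, term = hits$term[j],
                                       start = hits$start[j], end = hits$end[j]))
        flags[[cat]] <- f
      }
    }
  }
  if (isTRUE(interview_history_hypertension))
    flags$history_of_hypertension$present <- TRUE
  structure(flags, class = "hdp_flags")
}

#' Fill note-derived flags for every bundle in a cohort
#'
#' @param bundles List of `hdp_subject`.
#' @param dict An [flag_dictionary()].
#' @return The bundles with `$flags` populated.
#' @export
mine_cohort <- function(bundles, dict = flag_dictionary()) {
  lapply(bundles, function(b) {
    b$flags <- aggregate_flags(b$notes, dict, b$interview_history_hypertension)
    b
  })
}
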