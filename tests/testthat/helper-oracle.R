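# Independent oracles, kept deliberately naive and separate from the
# package's code paths.

# Straight-line restatement of the clinical definitions for one grid cell.
# Arguments describe the cell abstractly (no visit parsing):
#   htn_day  : NA, or day of first sustained hypertension
#   pu       : "none", "early", or a numeric onset day (>= 140)
#   cond_day : NA or day a PE-related condition (lab or dated note) fires
#   organ_day: NA or day of a dated organ-dysfunction mention (algorithm 2)
#   delivery : delivery day (timing fallback for a light-for-date upgrade)
oracle_classify <- function(algorithm, history, htn_day, pu, cond_day,
                            organ_day = NA, lfd = FALSE, delivery = 287,
                            eo_cut = 238) {
  timing <- function(base, day) {
    if (day < eo_cut) paste0(base, "_EO") else paste0(base, "_LO")
  }
  pu_day <- if (is.numeric(pu)) pu else NA
  chronic <- history || (!is.na(htn_day) && htn_day < 140)
  feats <- c(pu_day, if (!is.na(cond_day) && cond_day >= 140) cond_day)
  feats <- feats[!is.na(feats)]

  if (!chronic && is.na(htn_day)) return("NT")

  if (chronic) {
    if (length(feats)) return(timing("SPE", min(feats)))
    label <- "CH"
  } else if (length(feats)) {
    return(timing("PE", max(htn_day, min(feats))))
  } else {
    label <- timing("GH", htn_day)
  }

  if (algorithm == 2) {
    organ_ok <- !is.na(organ_day) && organ_day >= 140
    if (organ_ok || lfd) {
      if (label == "CH") {
        day <- if (organ_ok) organ_day
        else if (!is.na(htn_day) && htn_day >= 140) htn_day
        else delivery
        return(timing("SPE", day))
      }
      day <- if (organ_ok) max(htn_day, organ_day) else htn_day
      return(timing("PE", day))
    }
  }
  label
}

# Naive per-character term scanner with the same boundary semantics as the
# matcher but no overlap resolution: returns category/term/start hits.
brute_scan <- function(text, dict) {
  ntext <- normalize_text(text)
  chars <- strsplit(ntext, "")[[1]]
  is_word <- function(ch) grepl("[[:alnum:]]", ch)
  out <- NULL
  for (cat in names(dict$terms)) {
    for (term in dict$terms[[cat]]) {
      tl <- nchar(term)
      ascii <- !grepl("[^\\x01-\\x7f]", term, perl = TRUE)
      i <- 1
      while (i + tl - 1 <= nchar(ntext)) {
        if (substr(ntext, i, i + tl - 1) == term) {
          ok <- TRUE
          if (ascii) {
            if (i > 1 && is_word(chars[i - 1])) ok <- FALSE
            if (i + tl <= nchar(ntext) && is_word(chars[i + tl])) ok <- FALSE
          }
          if (ok) out <- rbind(out, data.frame(category = cat, term = term,
                                               start = i))
        }
        i <- i + 1
      }
    }
  }
  out
}

# Per-subject tally of a binary comparison, one subject at a time.
brute_confusion <- function(pred, truth) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] && truth[i]) tp <- tp + 1L
    else if (pred[i] && !truth[i]) fp <- fp + 1L
    else if (!pred[i] && truth[i]) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}

# Hand formula for the five metrics, computed independently of metrics().
brute_metrics <- function(cc) {
  na_div <- function(a, b) if (b == 0) NA_real_ else a / b
  c(ppv = na_div(cc$tp, cc$tp + cc$fp),
    npv = na_div(cc$tn, cc$tn + cc$fn),
    accuracy = na_div(cc$tp + cc$tn, cc$tp + cc$fp + cc$tn + cc$fn),
    sensitivity = na_div(cc$tp, cc$tp + cc$fn),
    specificity = na_div(cc$tn, cc$tn + cc$fp))
}
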