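#' Labels evaluated against the reference standard
#'
#' The twelve rows of the performance tables: the HDP aggregate (any of
#' GH/SPE/PE, either timing), the three subgroup aggregates, their EO/LO
#' forms, chronic hypertension and normotensive.
#' @export
VALIDATION_LABELS <- c("HDP", "GH", "GH_EO", "GH_LO", "SPE", "SPE_EO",
                       "SPE_LO", "PE", "PE_EO", "PE_LO", "CH", "NT")

#' Binary membership of subjects in a target label
#'
#' Aggregate targets (`HDP`, `GH`, `SPE`, `PE`) pool their constituent
#' labels; chronic hypertension is outside the HDP aggregate.  Labels may be
#' given at subgroup level (e.g. a diagnosed `"PE"` without an EO/LO suffix),
#' in which case they belong to the subgroup and HDP aggregates but to
#' neither timing-specific target.
#'
#' @param labels Character vector of assigned labels (from [HDP_LABELS] or
#'   their base forms `GH`/`SPE`/`PE`).
#' @param target One of [VALIDATION_LABELS].
#' @return Logical vector.
#' @export
binarize <- function(labels, target) {
  known <- c(HDP_LABELS, "GH", "SPE", "PE")
  if (!target %in% VALIDATION_LABELS)
    stop("unknown target label: ", target, call. = FALSE)
  bad <- setdiff(unique(labels), known)
  if (length(bad))
    stop("unknown label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  base <- sub("_(EO|LO)$", "", labels)
  if (target == "HDP") return(base %in% c("GH", "SPE", "PE"))
  if (target %in% c("GH", "SPE", "PE")) return(base == target)
  labels == target
}

#' Confusion counts for one binary comparison
#'
#' @param pred,truth Logical vectors of equal length, aligned by subject.
#' @return List `tp`, `fp`, `tn`, `fn` (their sum is the number of subjects).
#' @export
confusion <- function(pred, truth) {
  if (length(pred) != length(truth))
    stop("pred and truth differ in length", call. = FALSE)
  list(tp = sum(pred & truth), fp = sum(pred & !truth),
       tn = sum(!pred & !truth), fn = sum(!pred & truth))
}

#' The five diagnostic metrics from confusion counts
#'
#' PPV = TP/(TP+FP), NPV = TN/(TN+FN), accuracy = (TP+TN)/n,
#' sensitivity = TP/(TP+FN), specificity = TN/(TN+FP).  A metric whose
#' denominator is zero is not applicable and reported as `NA` (as the
#' performance tables do when no subject carries the label).
#'
#' @param c Confusion counts from [confusion()].
#' @return Named numeric vector `ppv`, `npv`, `accuracy`, `sensitivity`,
#'   `specificity` in `[0, 1]` or `NA`.
#' @export
metrics <- function(c) {
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  with(c, c(ppv = ratio(tp, tp + fp), npv = ratio(tn, tn + fn),
            accuracy = ratio(tp + tn, tp + fp + tn + fn),
            sensitivity = ratio(tp, tp + fn),
            specificity = ratio(tn, tn + fp)))
}

#' Evaluate phenotyped labels against reference-standard diagnoses
#'
#' One metric row per target in [VALIDATION_LABELS], plus a ledger of
#' discordant subjects (predicted label differs from the diagnosed label).
#' Aggregate rows compare aggregate membership, so an EO/LO disagreement
#' within the same subgroup counts as concordant for the pooled row.
#'
#' @param pred Data frame `subject_id`, `label` (phenotyped).
#' @param truth Data frame `subject_id`, `label` (diagnosed).  Diagnosed
#'   labels may be given at subgroup level (`GH`, `SPE`, `PE`) or with EO/LO
#'   suffixes.
#' @return List: `metrics` (data frame, 12 rows: `label`, `tp`, `fp`, `tn`,
#'   `fn` and the five metrics) and `discordant` (data frame `subject_id`,
#'   `predicted`, `diagnosed`).
#' @export
evaluate_all <- function(pred, truth) {
  if (!setequal(pred$subject_id, truth$subject_id) ||
      nrow(pred) != nrow(truth))
    stop("pred and truth cover different subjects", call. = FALSE)
  truth <- truth[match(pred$subject_id, truth$subject_id), ]
  rows <- lapply(VALIDATION_LABELS, function(tgt) {
    cc <- confusion(binarize(pred$label, tgt), binarize(truth$label, tgt))
    cbind(data.frame(label = tgt), as.data.frame(cc), as.data.frame(t(metrics(cc))))
  })
  dis <- which(pred$label != truth$label)
  list(metrics = do.call(rbind, rows),
       discordant = data.frame(subject_id = pred$subject_id[dis],
                               predicted = pred$label[dis],
                               diagnosed = truth$label[dis]))
}

#' Round metric values half-up to two decimals for display
#'
#' @param x Numeric vector in `[0, 1]` (NA passes through).
#' @return Numeric vector rounded half-up at the second decimal.
#' @export
round_metric <- function(x) {
  ifelse(is.na(x), NA_real_, floor(x * 100 + 0.5) / 100)
}
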