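#' Early/advanced clinical dichotomy
#'
#' A tumor is advanced iff size > 4 cm or N1 nodal disease; NX is grouped
#' with N0 (the N0/NX convention). Size exactly 4.0 cm is early. Missing
#' size or nodal status is an error — the rule is a clinical decision aid
#' and does not impute.
#'
#' @param tumor_size_cm positive tumor size in cm.
#' @param n_stage character vector over `{"N0", "NX", "N1"}`.
#' @return logical vector, `TRUE` = advanced.
#' @export
is_advanced <- function(tumor_size_cm, n_stage) {
  stopifnot(length(tumor_size_cm) == length(n_stage))
  if (any(is.na(tumor_size_cm)) || any(is.na(n_stage)))
    stop("missing tumor size or N stage (no imputation)")
  if (any(tumor_size_cm <= 0)) stop("tumor size must be positive")
  if (!all(n_stage %in% c("N0", "NX", "N1")))
    stop("N stage must be one of N0, NX, N1")
  tumor_size_cm > 4.0 | n_stage == "N1"
}

#' Two-class recurrence risk from subtype plus clinical factors
#'
#' High risk iff molecular Type 3 (regardless of stage) or an advanced
#' tumor (> 4 cm or N1); low risk iff Type 1 or Type 2 with an early tumor.
#'
#' @param subtype factor/character with values "Type 1"/"Type 2"/"Type 3"
#'   (bare 1/2/3 also accepted).
#' @inheritParams is_advanced
#' @return factor with levels `low`, `high`.
#' @export
assign_risk_class <- function(subtype, tumor_size_cm, n_stage) {
  st <- as.character(subtype)
  st[st %in% c("1", "2", "3")] <- paste("Type", st[st %in% c("1", "2", "3")])
  if (!all(st %in% paste("Type", 1:3))) stop("subtype must be Type 1/2/3")
  adv <- is_advanced(tumor_size_cm, n_stage)
  factor(ifelse(st == "Type 3" | adv, "high", "low"),
         levels = c("low", "high"))
}

#' Binarize the ATA three-level risk class
#'
#' The comparison baseline collapses the clinical system to low vs
#' intermediate/high.
#'
#' @param ata_risk character vector over `{"low", "intermediate", "high"}`.
#' @return factor with levels `low`, `not_low`.
#' @export
binarize_ata <- function(ata_risk) {
  if (any(is.na(ata_risk)) || !all(ata_risk %in% c("low", "intermediate", "high")))
    stop("ATA risk must be low/intermediate/high")
  factor(ifelse(ata_risk == "low", "low", "not_low"),
         levels = c("low", "not_low"))
}

#' Calibrated ordinal marker for a categorical predictor
#'
#' Codes each category as its training-set Kaplan-Meier event probability
#' by the horizon, making time-dependent AUROC well-defined for 2- and
#' 3-level predictors without arbitrary integer coding. AUC is invariant
#' to any strictly monotone recoding of the resulting marker.
#'
#' @param classes per-sample training categories.
#' @param time,event training survival outcome.
#' @param horizon months.
#' @param new_classes categories to code (default: the training ones);
#'   unseen categories are an error.
#' @return numeric marker aligned with `new_classes`, with attribute
#'   `rates` (named per-category event probabilities).
#' @export
categorical_marker <- function(classes, time, event, horizon,
                               new_classes = classes) {
  classes <- as.character(classes)
  new_classes <- as.character(new_classes)
  lv <- unique(classes)
  rates <- vapply(lv, function(g) {
    km <- kaplan_meier(time[classes == g], event[classes == g])
    1 - km_surv_at(km, horizon)
  }, numeric(1))
  unseen <- setdiff(unique(new_classes), lv)
  if (length(unseen) > 0)
    stop("categories unseen in training: ", paste(unseen, collapse = ", "))
  structure(unname(rates[new_classes]), rates = rates)
}

#' Compare risk stratifiers by time-dependent AUROC
#'
#' Evaluates (a) the combined subtype + clinical two-class rule, (b) the
#' molecular subtype alone, and (c) the binarized ATA class, each coded by
#' [categorical_marker()] and scored with the IPCW cumulative/dynamic AUC
#' at the horizon (default 60 months, the 5-year convention).
#'
#' @param subtype per-sample molecular subtype (Type 1/2/3).
#' @inheritParams is_advanced
#' @param ata_risk per-sample ATA class (low/intermediate/high).
#' @param time,event survival outcome.
#' @param horizon months (default 60).
#' @return object of class `stratifier_comparison`: `horizon`, `auc`
#'   (named: combined, subtype_only, ata_binary), `markers`, `risk_class`.
#' @export
compare_stratifiers <- function(subtype, tumor_size_cm, n_stage, ata_risk,
                                time, event, horizon = 60) {
  risk <- assign_risk_class(subtype, tumor_size_cm, n_stage)
  ata <- binarize_ata(ata_risk)
  mk <- list(
    combined = categorical_marker(risk, time, event, horizon),
    subtype_only = categorical_marker(as.character(subtype), time, event,
                                      horizon),
    ata_binary = categorical_marker(ata, time, event, horizon))
  auc <- vapply(mk, function(m) {
    cumulative_dynamic_auc(m, time, event, horizon)$auc
  }, numeric(1))
  structure(list(horizon = horizon, auc = auc, markers = mk,
                 risk_class = risk),
            class = "stratifier_comparison")
}

#' @export
print.stratifier_comparison <- function(x, ...) {
  cat(sprintf("Time-dependent AUROC at %g months:\n", x$horizon))
  cat(sprintf("  subtype + size/N stage: %.3f\n", x$auc["combined"]))
  cat(sprintf("  subtype alone:          %.3f\n", x$auc["subtype_only"]))
  cat(sprintf("  binarized ATA:          %.3f\n", x$auc["ata_binary"]))
  invisible(x)
}
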