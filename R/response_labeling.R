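# Responder / non-responder dichotomization.
#
# A patient is a responder on RECIST CR/PR or on progression-free survival
# longer than the cutoff (12 months); a non-responder on SD/PD or on PFS at
# or under the cutoff with a progression event. A survival time censored
# before the cutoff carries no information and leaves the sample
# unevaluable.

LABEL_LEVELS <- c("responder", "non_responder", "unevaluable")
BASIS_LEVELS <- c("recist", "pfs_rule", "os_rule", "none")

#' Configuration of the dichotomization rule
#'
#' @param survival_cutoff_months Positive cutoff in months (default 12): PFS
#'   strictly longer than this makes a responder.
#' @param allow_os_fallback Apply the same rule to overall survival when
#'   neither RECIST nor PFS is available (default `TRUE`; needed for cohorts
#'   annotated with OS only).
#' @param recist_priority When both RECIST and survival are present, RECIST
#'   decides (default `TRUE`).
#' @return A `label_config` list.
#' @export
label_config <- function(survival_cutoff_months = 12,
                         allow_os_fallback = TRUE,
                         recist_priority = TRUE) {
  stopifnot(
    is.numeric(survival_cutoff_months), length(survival_cutoff_months) == 1L,
    survival_cutoff_months > 0
  )
  structure(
    list(
      survival_cutoff_months = survival_cutoff_months,
      allow_os_fallback = isTRUE(allow_os_fallback),
      recist_priority = isTRUE(recist_priority)
    ),
    class = "label_config"
  )
}

# Survival-rule trichotomy. Strict reading of the boundaries: time > cutoff
# is a responder regardless of event; time <= cutoff with an event is a
# non-responder; censored at or before the cutoff is unevaluable.
.survival_label <- function(time, event, cutoff) {
  out <- rep(NA_character_, length(time))
  has <- !is.na(time) & !is.na(event)
  out[has & time > cutoff] <- "responder"
  out[has & time <= cutoff & event == 1] <- "non_responder"
  out[has & time <= cutoff & event == 0] <- "unevaluable"
  out
}

#' Label one annotated sample as responder / non-responder / unevaluable
#'
#' Rule order: (1) RECIST present: CR/PR responder, SD/PD non-responder;
#' (2) else PFS present: the cutoff rule; (3) else, if enabled, the same
#' rule on OS; (4) else unevaluable. Total on valid annotations.
#'
#' @param annotation A single-row clinical data.frame (see [read_clinical()]).
#' @param cfg A [label_config()].
#' @return One-row data.frame: `sample_id`, `label`, `basis`.
#' @export
label_response <- function(annotation, cfg = label_config()) {
  stopifnot(nrow(annotation) == 1L)
  label_cohort(annotation, cfg)$labels
}

#' Label every sample of a clinical table
#'
#' @param clinical Validated clinical data.frame.
#' @param cfg A [label_config()].
#' @return List with `labels` (data.frame `sample_id`/`label`/`basis`) and
#'   `summary` (counts per label and per basis).
#' @export
label_cohort <- function(clinical, cfg = label_config()) {
  stopifnot(inherits(cfg, "label_config"))
  n <- nrow(clinical)
  label <- rep(NA_character_, n)
  basis <- rep(NA_character_, n)
  if (n > 0L) {
    cutoff <- cfg$survival_cutoff_months

    recist_lab <- rep(NA_character_, n)
    recist_lab[clinical$recist %in% c("CR", "PR")] <- "responder"
    recist_lab[clinical$recist %in% c("SD", "PD")] <- "non_responder"
    pfs_lab <- .survival_label(clinical$pfs_months, clinical$pfs_event, cutoff)
    os_lab <- .survival_label(clinical$os_months, clinical$os_event, cutoff)
    if (!cfg$allow_os_fallback) os_lab[] <- NA_character_

    tiers <- if (cfg$recist_priority) {
      list(recist = recist_lab, pfs_rule = pfs_lab, os_rule = os_lab)
    } else {
      list(pfs_rule = pfs_lab, os_rule = os_lab, recist = recist_lab)
    }
    for (b in names(tiers)) {
      take <- is.na(label) & !is.na(tiers[[b]])
      label[take] <- tiers[[b]][take]
      basis[take] <- b
    }
    # a censored-short survival decision is informative of nothing: the
    # sample is unevaluable, with basis "none" per the label/basis invariant
    basis[!is.na(label) & label == "unevaluable"] <- "none"
    basis[is.na(label)] <- "none"
    label[is.na(label)] <- "unevaluable"
  }
  labels <- data.frame(
    sample_id = clinical$sample_id, label = label, basis = basis,
    stringsAsFactors = FALSE
  )
  summary <- list(
    by_label = stats::setNames(
      as.integer(table(factor(label, levels = LABEL_LEVELS))), LABEL_LEVELS
    ),
    by_basis = stats::setNames(
      as.integer(table(factor(basis, levels = BASIS_LEVELS))), BASIS_LEVELS
    )
  )
  list(labels = labels, summary = summary)
}
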