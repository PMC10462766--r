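# Stratification of the labeled, harmonized database into drug-class x
# biopsy-timing cohorts. A combination-therapy sample belongs to every arm
# whose drug class it received; unevaluable samples never enter a cohort.

#' Specify one analysis cohort
#'
#' @param drug_class One of `DRUG_CLASSES`.
#' @param timing One of `TIMING_LEVELS`.
#' @param tumor_types Optional character vector restricting tumor types.
#' @param min_class_size Minimum per-class non-missing values for a gene to
#'   be testable in this cohort (default 3; must be >= 2).
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(drug_class, timing, tumor_types = NULL, min_class_size = 3L) {
  drug_class <- match.arg(drug_class, DRUG_CLASSES)
  timing <- match.arg(timing, TIMING_LEVELS)
  stopifnot(min_class_size >= 2L)
  structure(
    list(
      drug_class = drug_class, timing = timing,
      tumor_types = tumor_types, min_class_size = as.integer(min_class_size)
    ),
    class = "cohort_spec"
  )
}

#' Build an analysis-ready cohort
#'
#' Selects exactly the samples whose drug classes contain the spec's class,
#' whose biopsy timing matches, (optionally) whose tumor type is in the
#' filter set, and whose response label is responder or non-responder.
#' A sample on combination therapy is included by every matching arm.
#'
#' @param cm Harmonized `combined_matrix`.
#' @param clinical Validated clinical data.frame covering the matrix samples.
#' @param labels Labels data.frame from [label_cohort()].
#' @param spec A [cohort_spec()].
#' @return A `cohort`: list with `spec`, `values` (genes x cohort samples),
#'   `labels` (named character, "responder"/"non_responder"),
#'   `sample_datasets`, `n_responder`, `n_nonresponder`.
#' @export
build_cohort <- function(cm, clinical, labels, spec) {
  stopifnot(inherits(cm, "combined_matrix"), inherits(spec, "cohort_spec"))
  ids <- colnames(cm$values)
  missing_ann <- setdiff(ids, clinical$sample_id)
  if (length(missing_ann) > 0L) {
    stop("matrix sample(s) without clinical annotation: ",
         paste(utils::head(missing_ann, 5L), collapse = ", "))
  }
  ann <- clinical[match(ids, clinical$sample_id), ]
  lab <- labels$label[match(ids, labels$sample_id)]

  in_arm <- vapply(
    split_drug_classes(ann$drug_classes),
    function(x) spec$drug_class %in% x, logical(1)
  )
  keep <- in_arm &
    ann$timing == spec$timing &
    lab %in% c("responder", "non_responder")
  if (!is.null(spec$tumor_types)) keep <- keep & ann$tumor_type %in% spec$tumor_types

  sel <- ids[keep]
  lab_sel <- stats::setNames(lab[keep], sel)
  n_r <- sum(lab_sel == "responder")
  n_nr <- sum(lab_sel == "non_responder")
  if (n_r == 0L || n_nr == 0L) {
    stop(
      "degenerate cohort for ", spec$drug_class, " ", spec$timing, ": ",
      n_r, " responder(s), ", n_nr, " non-responder(s)"
    )
  }
  structure(
    list(
      spec = spec,
      values = cm$values[, sel, drop = FALSE],
      labels = lab_sel,
      sample_datasets = cm$sample_datasets[sel],
      n_responder = n_r,
      n_nonresponder = n_nr
    ),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat(
    "<cohort>", x$spec$drug_class, x$spec$timing, "-",
    x$n_responder, "responders /", x$n_nonresponder, "non-responders,",
    nrow(x$values), "genes\n"
  )
  invisible(x)
}

#' Build the six canonical drug-class x timing cohorts
#'
#' Instantiates all combinations of the three drug classes with
#' pre-/on-treatment timing. Degenerate combinations (no responders or no
#' non-responders after labeling) are reported in the summary, not raised.
#'
#' @inheritParams build_cohort
#' @param min_class_size Passed through to each [cohort_spec()].
#' @return List with `cohorts` (named list; `NULL` where degenerate) and
#'   `summary` (data.frame of per-group sizes and degeneracy flags).
#' @export
standard_cohorts <- function(cm, clinical, labels, min_class_size = 3L) {
  grid <- expand.grid(
    timing = TIMING_LEVELS, drug_class = DRUG_CLASSES,
    stringsAsFactors = FALSE
  )[, c("drug_class", "timing")]
  cohorts <- vector("list", nrow(grid))
  names(cohorts) <- paste(grid$drug_class, grid$timing)
  summ <- cbind(
    grid,
    data.frame(n_samples = 0L, n_responder = 0L, n_nonresponder = 0L, degenerate = TRUE)
  )
  for (i in seq_len(nrow(grid))) {
    spec <- cohort_spec(grid$drug_class[i], grid$timing[i], min_class_size = min_class_size)
    co <- tryCatch(
      build_cohort(cm, clinical, labels, spec),
      error = function(e) NULL
    )
    if (!is.null(co)) {
      cohorts[[i]] <- co
      summ$n_samples[i] <- length(co$labels)
      summ$n_responder[i] <- co$n_responder
      summ$n_nonresponder[i] <- co$n_nonresponder
      summ$degenerate[i] <- FALSE
    }
  }
  list(cohorts = cohorts, summary = summ)
}

#' Check the arm-size bookkeeping identity
#'
#' Summing per-arm sample counts over drug classes counts a
#' combination-therapy sample once per arm it belongs to; subtracting the
#' extra memberships must reproduce the number of distinct labeled samples:
#' `sum(arm sizes) - extra multi-arm memberships = distinct samples`.
#'
#' @param clinical Validated clinical data.frame.
#' @param labels Labels data.frame from [label_cohort()].
#' @return List with per-arm sizes (`arm_sizes`), the number of extra
#'   multi-arm memberships (`n_extra_memberships`), the distinct labeled
#'   sample count (`n_distinct`) and the identity residual (`residual`,
#'   0 when the bookkeeping is consistent).
#' @export
arm_sum_check <- function(clinical, labels) {
  lab <- labels$label[match(clinical$sample_id, labels$sample_id)]
  evaluable <- lab %in% c("responder", "non_responder")
  dc <- split_drug_classes(clinical$drug_classes[evaluable])
  arm_sizes <- vapply(
    DRUG_CLASSES,
    function(cl) sum(vapply(dc, function(x) cl %in% x, logical(1))),
    integer(1)
  )
  n_member <- lengths(dc)
  n_extra <- sum(n_member - 1L)
  n_distinct <- sum(evaluable)
  list(
    arm_sizes = arm_sizes,
    n_extra_memberships = n_extra,
    n_distinct = n_distinct,
    residual = sum(arm_sizes) - n_extra - n_distinct
  )
}
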