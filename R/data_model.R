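# Core containers and plain-text I/O: expression matrices, clinical tables,
# dataset manifests and screen result tables.

#' Recognized immune-checkpoint drug classes
#'
#' The three antibody classes a sample can be annotated with. A sample
#' carrying more than one class models combination therapy and belongs to
#' every matching treatment arm.
#' @export
DRUG_CLASSES <- c("anti-PD-1", "anti-PD-L1", "anti-CTLA-4")

#' Biopsy timing levels
#'
#' Samples are taken either before therapy induction ("pre-treatment") or
#' during/after therapy ("on-treatment").
#' @export
TIMING_LEVELS <- c("pre-treatment", "on-treatment")

#' RECIST response categories
#' @export
RECIST_LEVELS <- c("CR", "PR", "SD", "PD")

DIRECTION_LEVELS <- c("higher_in_nonresponder", "higher_in_responder", "tie")

#' Construct an expression matrix for one dataset
#'
#' A thin validated container: a genes x samples matrix of non-negative
#' values tagged with a dataset identifier and a free-text platform label.
#' Missing values (`NA`) mean "gene not measured on this platform" and are
#' distinct from zero expression.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene symbols),
#'   samples in columns (colnames = sample identifiers).
#' @param dataset_id Single string identifying the dataset.
#' @param platform Free-text platform label (e.g. "rnaseq", "nanostring").
#' @return An object of class `expr_matrix`.
#' @examples
#' m <- expression_matrix(
#'   matrix(1:6, 3, 2, dimnames = list(c("A", "B", "C"), c("s1", "s2"))),
#'   dataset_id = "demo"
#' )
#' dim(m$values)
#' @export
expression_matrix <- function(values, dataset_id, platform = "unknown") {
  stopifnot(is.character(dataset_id), length(dataset_id) == 1L)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  obj <- structure(
    list(dataset_id = dataset_id, platform = platform, values = values),
    class = "expr_matrix"
  )
  validate_expression_matrix(obj)
  obj
}

validate_expression_matrix <- function(m) {
  v <- m$values
  if (is.null(rownames(v)) || is.null(colnames(v))) {
    stop("expression matrix must have gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(v))) {
    stop("duplicated gene_ids in dataset '", m$dataset_id, "'")
  }
  if (anyDuplicated(colnames(v))) {
    stop("duplicated sample_ids in dataset '", m$dataset_id, "'")
  }
  neg <- which(!is.na(v) & v < 0, arr.ind = TRUE)
  if (nrow(neg) > 0L) {
    stop(
      "negative expression value in dataset '", m$dataset_id, "' (gene ",
      rownames(v)[neg[1L, 1L]], ", sample ", colnames(v)[neg[1L, 2L]], ")"
    )
  }
  empty <- colSums(!is.na(v)) == 0L
  if (any(empty)) {
    stop(
      "sample(s) with no measured genes in dataset '", m$dataset_id, "': ",
      paste(colnames(v)[empty], collapse = ", ")
    )
  }
  invisible(m)
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(
    "<expr_matrix> dataset:", x$dataset_id, " platform:", x$platform,
    "\n  ", nrow(x$values), "genes x", ncol(x$values), "samples;",
    sum(is.na(x$values)), "missing entries\n"
  )
  invisible(x)
}

#' Read a gene-expression table
#'
#' Reads a tab-separated table whose first column holds gene symbols and
#' whose header row holds sample identifiers. Empty cells are treated as
#' missing (gene absent from the platform). Duplicate gene rows are collapsed
#' by the per-sample maximum, with a warning naming the genes.
#'
#' @param path Path to the TSV file.
#' @param dataset_id Dataset identifier to attach.
#' @param platform Platform label to attach.
#' @return An `expr_matrix`.
#' @export
read_expression <- function(path, dataset_id, platform = "unknown") {
  df <- utils::read.delim(
    path,
    check.names = FALSE, stringsAsFactors = FALSE,
    na.strings = c("", "NA"), colClasses = NA
  )
  if (ncol(df) < 2L) {
    stop("malformed expression table '", path, "': need a gene column and >= 1 sample column")
  }
  genes <- as.character(df[[1L]])
  v <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(v)) {
    bad <- colnames(v)[!vapply(seq_len(ncol(v)), function(j) is.numeric(df[[j + 1L]]), logical(1))]
    stop("non-numeric expression column(s) in '", path, "': ", paste(bad, collapse = ", "))
  }
  rownames(v) <- genes
  if (anyDuplicated(genes)) {
    dups <- unique(genes[duplicated(genes)])
    warning(
      "collapsing duplicated gene row(s) by per-sample maximum: ",
      paste(dups, collapse = ", ")
    )
    keep <- v[!duplicated(genes), , drop = FALSE]
    for (g in dups) {
      rows <- v[genes == g, , drop = FALSE]
      keep[g, ] <- suppressWarnings(apply(rows, 2L, max, na.rm = TRUE))
      keep[g, !is.finite(keep[g, ])] <- NA_real_
    }
    v <- keep
  }
  expression_matrix(v, dataset_id = dataset_id, platform = platform)
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression()]: first column `gene_id`, one column per
#' sample, empty cells for missing values.
#'
#' @param m An `expr_matrix` (or a combined matrix).
#' @param path Output path.
#' @param digits Significant digits used for formatting.
#' @export
write_expression <- function(m, path, digits = 10L) {
  v <- if (inherits(m, "expr_matrix") || inherits(m, "combined_matrix")) m$values else as.matrix(m)
  out <- data.frame(gene_id = rownames(v), check.names = FALSE)
  for (j in seq_len(ncol(v))) {
    col <- ifelse(is.na(v[, j]), "", formatC(signif(v[, j], digits), format = "g", digits = digits))
    out[[colnames(v)[j]]] <- col
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

CLINICAL_REQUIRED <- c(
  "sample_id", "dataset_id", "patient_id", "tumor_type", "drug_classes", "timing"
)
CLINICAL_OPTIONAL <- c("recist", "pfs_months", "pfs_event", "os_months", "os_event")

split_drug_classes <- function(x) strsplit(as.character(x), ";", fixed = TRUE)

#' Read and validate a clinical annotation table
#'
#' Tab-separated, one row per sample. Required columns: `sample_id`,
#' `dataset_id`, `patient_id`, `tumor_type`, `drug_classes`
#' (';'-separated subset of `DRUG_CLASSES`), `timing`. Optional columns:
#' `recist` (case-insensitive CR/PR/SD/PD), `pfs_months`, `pfs_event`,
#' `os_months`, `os_event`. Unknown columns are ignored. A survival time
#' without its event flag is rejected: censoring status is required to apply
#' the 12-month rule.
#'
#' @param path Path to the clinical TSV.
#' @return A data.frame with one validated record per sample.
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(
    path,
    check.names = FALSE, stringsAsFactors = FALSE,
    na.strings = c("", "NA")
  )
  validate_clinical(df)
}

#' Validate a clinical annotation data.frame
#'
#' Applies the same checks as [read_clinical()] to an in-memory table.
#' @param df Data.frame of clinical records.
#' @return The validated (normalized) data.frame.
#' @export
validate_clinical <- function(df) {
  missing_cols <- setdiff(CLINICAL_REQUIRED, names(df))
  if (length(missing_cols) > 0L) {
    stop("clinical table lacks required column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (col in CLINICAL_OPTIONAL) if (!col %in% names(df)) df[[col]] <- NA
  df <- df[, c(CLINICAL_REQUIRED, CLINICAL_OPTIONAL)]

  if (anyDuplicated(df$sample_id)) {
    stop("duplicated sample_id(s): ", paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }

  dc <- split_drug_classes(df$drug_classes)
  bad <- vapply(dc, function(x) length(x) == 0L || any(!x %in% DRUG_CLASSES), logical(1))
  bad <- bad | is.na(df$drug_classes)
  if (any(bad)) {
    stop(
      "invalid or empty drug_classes for sample(s): ",
      paste(df$sample_id[bad], collapse = ", "),
      " (allowed: ", paste(DRUG_CLASSES, collapse = ", "), ")"
    )
  }

  if (any(is.na(df$timing)) || any(!df$timing %in% TIMING_LEVELS)) {
    stop(
      "timing must be one of ", paste(shQuote(TIMING_LEVELS), collapse = "/"),
      " for every sample"
    )
  }

  rec <- toupper(trimws(as.character(df$recist)))
  rec[rec == ""] <- NA_character_
  unknown <- !is.na(rec) & !rec %in% RECIST_LEVELS
  if (any(unknown)) {
    stop("unrecognized RECIST value(s): ", paste(unique(rec[unknown]), collapse = ", "))
  }
  df$recist <- rec

  for (end in c("pfs", "os")) {
    tcol <- paste0(end, "_months")
    ecol <- paste0(end, "_event")
    tm <- suppressWarnings(as.numeric(df[[tcol]]))
    ev <- suppressWarnings(as.numeric(df[[ecol]]))
    orphan <- !is.na(tm) & is.na(ev)
    if (any(orphan)) {
      stop(
        toupper(end), " time without event flag for sample(s): ",
        paste(df$sample_id[orphan], collapse = ", ")
      )
    }
    if (any(!is.na(tm) & tm < 0)) stop("negative ", toupper(end), " time")
    if (any(!is.na(ev) & !ev %in% c(0, 1))) stop(toupper(end), " event flag must be 0/1")
    df[[tcol]] <- tm
    df[[ecol]] <- ev
  }
  rownames(df) <- NULL
  df
}

#' Write a clinical annotation table
#' @param clinical Validated clinical data.frame.
#' @param path Output path.
#' @export
write_clinical <- function(clinical, path) {
  utils::write.table(clinical, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a dataset manifest
#'
#' A manifest is a YAML or JSON list of dataset records with fields
#' `dataset_id`, `expression_path`, `clinical_path`, `platform`,
#' `include` (logical) and optional `exclusion_reason`. Relative paths are
#' resolved against the manifest's own directory. Paths of included records
#' must exist.
#'
#' @param path Path to `.yaml`/`.yml` or `.json` manifest.
#' @return A data.frame of dataset records with resolved paths.
#' @export
read_manifest <- function(path) {
  ext <- tolower(tools::file_ext(path))
  recs <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  } else {
    stop("manifest must be .yaml/.yml or .json, got '", ext, "'")
  }
  if (length(recs) == 0L) stop("empty manifest")
  base <- dirname(normalizePath(path))
  rows <- lapply(recs, function(r) {
    for (f in c("dataset_id", "expression_path", "clinical_path")) {
      if (is.null(r[[f]])) stop("manifest record lacks field '", f, "'")
    }
    data.frame(
      dataset_id = r$dataset_id,
      expression_path = r$expression_path,
      clinical_path = r$clinical_path,
      platform = if (is.null(r$platform)) "unknown" else r$platform,
      include = if (is.null(r$include)) TRUE else isTRUE(r$include),
      exclusion_reason = if (is.null(r$exclusion_reason)) NA_character_ else r$exclusion_reason,
      stringsAsFactors = FALSE
    )
  })
  mf <- do.call(rbind, rows)
  if (anyDuplicated(mf$dataset_id)) stop("duplicated dataset_id in manifest")
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  mf$expression_path <- resolve(mf$expression_path)
  mf$clinical_path <- resolve(mf$clinical_path)
  inc <- mf[mf$include, ]
  unreadable <- !file.exists(inc$expression_path) | !file.exists(inc$clinical_path)
  if (any(unreadable)) {
    stop(
      "manifest paths not readable for included dataset(s): ",
      paste(inc$dataset_id[unreadable], collapse = ", ")
    )
  }
  mf
}

RESULT_COLUMNS <- c(
  "gene", "n_responder", "n_nonresponder", "u_statistic", "auc",
  "direction", "p_raw", "fold_change", "significant"
)

#' Write a screen result table
#'
#' Tab-separated, sorted by raw p-value ascending, preceded by '#'-prefixed
#' metadata lines recording the cohort, the number of genes tested, alpha and
#' the Bonferroni threshold (exact and display form).
#'
#' @param screen A `screen_result` from [screen_cohort()] or [evaluate_panel()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(screen, path) {
  stopifnot(inherits(screen, "screen_result"))
  res <- screen$results
  if (is.null(res) || nrow(res) == 0L) stop("no results to write")
  res <- res[order(res$p_raw, res$gene), , drop = FALSE]
  con <- file(path, open = "wt")
  on.exit(close(con))
  meta <- c(
    paste0("# cohort: ", screen$spec$drug_class, " ", screen$spec$timing),
    paste0("# m_tested: ", screen$m_tested),
    paste0("# alpha: ", format(screen$alpha, digits = 10)),
    paste0("# threshold_exact: ", formatC(screen$threshold, format = "g", digits = 10)),
    paste0("# threshold_display: ", format_threshold(screen$threshold_display))
  )
  writeLines(meta, con)
  fmt <- res
  for (col in c("u_statistic", "auc", "p_raw", "fold_change")) {
    fmt[[col]] <- formatC(signif(res[[col]], 10), format = "g", digits = 10)
  }
  utils::write.table(
    fmt[, RESULT_COLUMNS], con,
    sep = "\t", quote = FALSE, row.names = FALSE, na = "NA"
  )
  invisible(path)
}

#' Read back a screen result table written by [write_results()]
#' @param path Path to the result TSV.
#' @return A list with `meta` (named character) and `results` (data.frame).
#' @export
read_results <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  kv <- sub("^# *", "", meta_lines)
  meta <- stats::setNames(
    trimws(sub("^[^:]+:", "", kv)),
    trimws(sub(":.*$", "", kv))
  )
  df <- utils::read.delim(
    textConnection(lines[!grepl("^#", lines)]),
    stringsAsFactors = FALSE
  )
  df$significant <- as.logical(df$significant)
  list(meta = meta, results = df)
}
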