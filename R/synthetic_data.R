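# Synthetic multi-dataset ICI cohort generator with known ground truth.
#
# Null genes share a log-normal baseline; response markers are planted on
# the log scale via the binormal model, whose class-mean shift
# delta = sqrt(2) * qnorm(target_auc) (unit log-scale noise) gives a
# closed-form AUC, so recovery tests have analytic targets. Per-dataset
# platform effects are monotone (power + scale) so that quantile
# normalization can remove them; panel-like datasets keep a gene subset and
# round values to integers to stress tie handling.

TUMOR_TYPES <- c(
  "melanoma", "urothelial", "gastric", "esophageal", "hnscc", "lung",
  "renal", "hepatocellular", "glioblastoma", "breast"
)

#' Per-dataset settings of the synthetic generator
#'
#' @param n_samples Samples in this dataset.
#' @param platform_kind "rnaseq_like" (all genes, continuous values) or
#'   "panel_like" (gene subset, integer-rounded values, tie-heavy).
#' @param gene_subset_fraction Fraction of the gene universe measured
#'   (panel-like platforms measure a subset; default 1).
#' @param scale_factor Multiplicative platform scale.
#' @param distortion_exponent Monotone power distortion `v -> s * v^e`.
#' @param outcome_mode Which clinical annotation the dataset reports:
#'   "recist_only", "pfs_only", "os_only" or "mixed".
#' @return A list of settings.
#' @export
dataset_config <- function(n_samples,
                           platform_kind = c("rnaseq_like", "panel_like"),
                           gene_subset_fraction = 1,
                           scale_factor = 1,
                           distortion_exponent = 1,
                           outcome_mode = c("mixed", "recist_only", "pfs_only", "os_only")) {
  platform_kind <- match.arg(platform_kind)
  outcome_mode <- match.arg(outcome_mode)
  stopifnot(
    n_samples >= 2, gene_subset_fraction > 0, gene_subset_fraction <= 1,
    scale_factor > 0, distortion_exponent > 0
  )
  list(
    n_samples = as.integer(n_samples), platform_kind = platform_kind,
    gene_subset_fraction = gene_subset_fraction, scale_factor = scale_factor,
    distortion_exponent = distortion_exponent, outcome_mode = outcome_mode
  )
}

default_datasets <- function() {
  list(
    dataset_config(120, "rnaseq_like", outcome_mode = "mixed"),
    dataset_config(90, "rnaseq_like", scale_factor = 30, distortion_exponent = 1.15, outcome_mode = "recist_only"),
    dataset_config(60, "rnaseq_like", scale_factor = 0.2, distortion_exponent = 0.9, outcome_mode = "pfs_only"),
    dataset_config(50, "panel_like", gene_subset_fraction = 0.4, scale_factor = 50, outcome_mode = "recist_only"),
    dataset_config(40, "rnaseq_like", distortion_exponent = 1.3, outcome_mode = "os_only"),
    dataset_config(40, "panel_like", gene_subset_fraction = 0.3, scale_factor = 20, outcome_mode = "mixed")
  )
}

default_markers <- function() {
  data.frame(
    gene = c("RESM01", "RESM02", "SENSM01"),
    target_auc = c(0.75, 0.68, 0.72),
    direction = c("higher_in_nonresponder", "higher_in_nonresponder", "higher_in_responder"),
    stringsAsFactors = FALSE
  )
}

#' Configuration of the synthetic ICI database
#'
#' Defaults emulate the structure of a multi-cohort ICI expression database
#' at desk scale: six datasets (four RNA-seq-like, two panel-like) totalling
#' 400 samples, mixed tumor types and outcome annotations, a ~35% responder
#' rate typical of checkpoint-inhibitor cohorts, drug-class proportions
#' dominated by anti-PD-1 with a small combination-therapy fraction, mostly
#' pre-treatment biopsies, and three planted markers.
#'
#' @param seed Integer RNG seed; the whole database is a deterministic
#'   function of the config.
#' @param n_genes Size of the gene universe (planted markers included).
#' @param datasets List of [dataset_config()]s.
#' @param responder_fraction Latent responder probability per sample.
#' @param drug_class_probs Named probabilities over `DRUG_CLASSES` for
#'   monotherapy assignment.
#' @param combination_fraction Probability a sample received anti-PD-1 +
#'   anti-CTLA-4 combination therapy.
#' @param on_treatment_fraction Probability a biopsy is on-treatment.
#' @param censoring_fraction Probability a survival-annotated sample is
#'   censored short of the 12-month cutoff (hence unevaluable).
#' @param planted_markers Data.frame with columns `gene`, `target_auc` in
#'   (0.5, 1), `direction`.
#' @param baseline_log_mean,baseline_log_sd Location/spread of per-gene
#'   log-scale baselines.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L,
                             n_genes = 2000L,
                             datasets = default_datasets(),
                             responder_fraction = 0.35,
                             drug_class_probs = c(
                               "anti-PD-1" = 0.60, "anti-PD-L1" = 0.28, "anti-CTLA-4" = 0.12
                             ),
                             combination_fraction = 0.04,
                             on_treatment_fraction = 0.10,
                             censoring_fraction = 0.10,
                             planted_markers = default_markers(),
                             baseline_log_mean = log(100),
                             baseline_log_sd = 1.2) {
  stopifnot(
    responder_fraction > 0, responder_fraction < 1,
    combination_fraction >= 0, combination_fraction < 1,
    on_treatment_fraction >= 0, on_treatment_fraction < 1,
    censoring_fraction >= 0, censoring_fraction < 1,
    all(names(drug_class_probs) %in% DRUG_CLASSES),
    abs(sum(drug_class_probs) - 1) < 1e-9,
    n_genes > nrow(planted_markers)
  )
  if (nrow(planted_markers) > 0L) {
    stopifnot(
      all(planted_markers$target_auc > 0.5), all(planted_markers$target_auc < 1),
      all(planted_markers$direction %in% c("higher_in_nonresponder", "higher_in_responder"))
    )
  }
  structure(
    list(
      seed = as.integer(seed), n_genes = as.integer(n_genes), datasets = datasets,
      responder_fraction = responder_fraction,
      drug_class_probs = drug_class_probs,
      combination_fraction = combination_fraction,
      on_treatment_fraction = on_treatment_fraction,
      censoring_fraction = censoring_fraction,
      planted_markers = planted_markers,
      baseline_log_mean = baseline_log_mean,
      baseline_log_sd = baseline_log_sd
    ),
    class = "synthetic_config"
  )
}

.gene_universe <- function(cfg) {
  n_null <- cfg$n_genes - nrow(cfg$planted_markers)
  c(cfg$planted_markers$gene, sprintf("GENE%05d", seq_len(n_null)))
}

# RECIST category given the latent response; responders split CR/PR,
# non-responders SD/PD.
.draw_recist <- function(responder) {
  ifelse(
    responder,
    sample(c("CR", "PR"), length(responder), replace = TRUE, prob = c(0.25, 0.75)),
    sample(c("SD", "PD"), length(responder), replace = TRUE, prob = c(0.4, 0.6))
  )
}

#' Simulate a multi-dataset ICI expression database with known truth
#'
#' Draws per-gene log-scale baselines once, then for each dataset draws
#' sample-level latent response, drug classes, biopsy timing and clinical
#' annotation per its outcome mode, and an expression matrix with planted
#' marker shifts applied to the latent classes before the dataset's
#' monotone platform distortion. Survival-annotated samples are censored
#' short of 12 months with probability `censoring_fraction`, making them
#' unevaluable by construction.
#'
#' @param cfg A [synthetic_config()].
#' @return List with `matrices` (list of [expression_matrix()]),
#'   `clinical` (validated data.frame), and `truth` (list: `samples`
#'   data.frame with latent response, expected label and arm memberships;
#'   `markers` = the planted-marker table).
#' @export
simulate_database <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  genes <- .gene_universe(cfg)
  baseline <- stats::rnorm(length(genes), cfg$baseline_log_mean, cfg$baseline_log_sd)
  names(baseline) <- genes
  markers <- cfg$planted_markers
  delta <- stats::setNames(sqrt(2) * stats::qnorm(markers$target_auc), markers$gene)

  matrices <- vector("list", length(cfg$datasets))
  clin_rows <- vector("list", length(cfg$datasets))
  truth_rows <- vector("list", length(cfg$datasets))
  panel_genes_seen <- character(0)

  for (d in seq_along(cfg$datasets)) {
    ds <- cfg$datasets[[d]]
    dsid <- sprintf("SYN%02d", d)
    n <- ds$n_samples
    sid <- sprintf("%s_S%03d", dsid, seq_len(n))

    responder <- stats::runif(n) < cfg$responder_fraction
    combo <- stats::runif(n) < cfg$combination_fraction
    mono <- sample(names(cfg$drug_class_probs), n, replace = TRUE, prob = cfg$drug_class_probs)
    drug <- ifelse(combo, "anti-PD-1;anti-CTLA-4", mono)
    timing <- ifelse(
      stats::runif(n) < cfg$on_treatment_fraction, "on-treatment", "pre-treatment"
    )
    tumor <- sample(TUMOR_TYPES, n, replace = TRUE)

    ds_genes <- if (ds$platform_kind == "panel_like") {
      sort(sample(genes, max(2L, round(ds$gene_subset_fraction * length(genes)))))
    } else {
      genes
    }
    panel_genes_seen <- union(panel_genes_seen, ds_genes)

    logv <- matrix(
      baseline[ds_genes] + stats::rnorm(length(ds_genes) * n),
      nrow = length(ds_genes), ncol = n, dimnames = list(ds_genes, sid)
    )
    for (k in seq_len(nrow(markers))) {
      g <- markers$gene[k]
      if (!g %in% ds_genes) next
      shifted <- if (markers$direction[k] == "higher_in_nonresponder") !responder else responder
      logv[g, shifted] <- logv[g, shifted] + delta[g]
    }
    vals <- ds$scale_factor * exp(logv)^ds$distortion_exponent
    if (ds$platform_kind == "panel_like") vals <- round(vals)

    # clinical annotation per outcome mode; censored survival samples are
    # unevaluable by construction
    mode <- if (ds$outcome_mode == "mixed") {
      sample(c("recist_only", "pfs_only"), n, replace = TRUE)
    } else {
      rep(ds$outcome_mode, n)
    }
    recist <- rep(NA_character_, n)
    pfs_m <- rep(NA_real_, n)
    pfs_e <- rep(NA_real_, n)
    os_m <- rep(NA_real_, n)
    os_e <- rep(NA_real_, n)
    expected <- ifelse(responder, "responder", "non_responder")

    is_rec <- mode == "recist_only"
    recist[is_rec] <- .draw_recist(responder[is_rec])

    for (mm in c("pfs_only", "os_only")) {
      idx <- which(mode == mm)
      if (length(idx) == 0L) next
      cens <- stats::runif(length(idx)) < cfg$censoring_fraction
      t_out <- numeric(length(idx))
      e_out <- numeric(length(idx))
      t_out[cens] <- stats::runif(sum(cens), 0.5, 11.5)
      e_out[cens] <- 0
      r_idx <- responder[idx] & !cens
      n_idx <- !responder[idx] & !cens
      t_out[r_idx] <- stats::runif(sum(r_idx), 12.5, 40)
      e_out[r_idx] <- stats::rbinom(sum(r_idx), 1, 0.5)
      t_out[n_idx] <- stats::runif(sum(n_idx), 0.5, 11.5)
      e_out[n_idx] <- 1
      if (mm == "pfs_only") {
        pfs_m[idx] <- t_out
        pfs_e[idx] <- e_out
      } else {
        os_m[idx] <- t_out
        os_e[idx] <- e_out
      }
      expected[idx[cens]] <- "unevaluable"
    }

    matrices[[d]] <- expression_matrix(vals, dataset_id = dsid, platform = ds$platform_kind)
    clin_rows[[d]] <- data.frame(
      sample_id = sid, dataset_id = dsid, patient_id = sub("_S", "_P", sid),
      tumor_type = tumor, drug_classes = drug, timing = timing,
      recist = recist, pfs_months = pfs_m, pfs_event = pfs_e,
      os_months = os_m, os_event = os_e,
      stringsAsFactors = FALSE
    )
    truth_rows[[d]] <- data.frame(
      sample_id = sid, dataset_id = dsid,
      latent_responder = responder, expected_label = expected,
      arms = drug, timing = timing, outcome_mode = mode,
      stringsAsFactors = FALSE
    )
  }

  orphans <- setdiff(markers$gene, panel_genes_seen)
  if (length(orphans) > 0L) {
    stop("planted gene(s) absent from every platform: ", paste(orphans, collapse = ", "))
  }

  clinical <- validate_clinical(do.call(rbind, clin_rows))
  list(
    matrices = matrices,
    clinical = clinical,
    truth = list(samples = do.call(rbind, truth_rows), markers = markers),
    config = cfg
  )
}

#' Write a simulated database to disk
#'
#' Emits one expression TSV per dataset, the clinical table, the truth
#' tables and a YAML manifest pointing at them — the exact on-disk dialect
#' [read_manifest()], [read_expression()] and [read_clinical()] consume.
#'
#' @param db A [simulate_database()] result.
#' @param dir Output directory (created if needed).
#' @return Path of the manifest, invisibly.
#' @export
write_database <- function(db, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  recs <- lapply(db$matrices, function(m) {
    expr_file <- paste0(m$dataset_id, "_expression.tsv")
    write_expression(m, file.path(dir, expr_file))
    list(
      dataset_id = m$dataset_id,
      expression_path = expr_file,
      clinical_path = "clinical.tsv",
      platform = m$platform,
      include = TRUE
    )
  })
  write_clinical(db$clinical, file.path(dir, "clinical.tsv"))
  utils::write.table(
    db$truth$samples, file.path(dir, "truth_samples.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  utils::write.table(
    db$truth$markers, file.path(dir, "truth_markers.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  manifest <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(recs, manifest)
  invisible(manifest)
}

#' Tiny deterministic worked example
#'
#' Two datasets, six genes, twelve samples with hand-checkable values:
#' `RES1` separates non-responders above responders completely in the
#' anti-PD-1 pre-treatment cohort, `SENS1` is elevated in responders,
#' `NULL1` is constant, and one sample received anti-PD-1 + anti-CTLA-4
#' combination therapy (so it belongs to two arms). Dataset `WRK1` is
#' RECIST-annotated; `WRK2` carries PFS with one short-censored
#' (unevaluable) sample.
#'
#' @return A list shaped like [simulate_database()] output.
#' @export
simulate_worked_example <- function() {
  a_samples <- paste0("A", 1:6)
  b_samples <- paste0("B", 1:6)
  # anti-PD-1 pre-treatment classes: responders A1 A2 A6 B1 B2 B6,
  # non-responders A3 A4 A5 B3 B4; B5 unevaluable (censored at 8 months)
  vals1 <- matrix(
    c(
      # A1    A2    A3    A4    A5    A6
      10,   12,   55,   60,   52,   11, # RES1: non-responders all higher
      40,   44,    9,    8,   10,   46, # SENS1: responders higher
      7,     7,    7,    7,    7,    7, # NULL1: constant
      20,   25,   22,   28,   21,   24, # GENEA
      100,  90,  110,  95,  105,   98, # GENEB
      5,     6,    4,    3,    5,    6  # GENEC
    ),
    nrow = 6, byrow = TRUE,
    dimnames = list(c("RES1", "SENS1", "NULL1", "GENEA", "GENEB", "GENEC"), a_samples)
  )
  vals2 <- matrix(
    c(
      14,   13,   58,   51,   30,    9,
      42,   38,   11,   10,   25,   50,
      7,     7,    7,    7,    7,    7,
      23,   27,   26,   19,   22,   25,
      97,  102,   93,  108,  101,   99,
      6,     5,    3,    4,    6,    5
    ),
    nrow = 6, byrow = TRUE,
    dimnames = list(c("RES1", "SENS1", "NULL1", "GENEA", "GENEB", "GENEC"), b_samples)
  )
  clinical <- data.frame(
    sample_id = c(a_samples, b_samples),
    dataset_id = rep(c("WRK1", "WRK2"), each = 6),
    patient_id = paste0("P", 1:12),
    tumor_type = rep(c("melanoma", "urothelial"), each = 6),
    drug_classes = c(rep("anti-PD-1", 11), "anti-PD-1;anti-CTLA-4"),
    timing = "pre-treatment",
    recist = c("CR", "PR", "SD", "PD", "PD", "PR", rep(NA, 6)),
    pfs_months = c(rep(NA, 6), 18, 24, 6, 10, 8, 30),
    pfs_event = c(rep(NA, 6), 0, 1, 1, 1, 0, 1),
    os_months = NA_real_, os_event = NA_real_,
    stringsAsFactors = FALSE
  )
  clinical <- validate_clinical(clinical)
  truth <- data.frame(
    sample_id = clinical$sample_id,
    dataset_id = clinical$dataset_id,
    latent_responder = c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE,
                         TRUE, TRUE, FALSE, FALSE, NA, TRUE),
    expected_label = c(
      "responder", "responder", "non_responder", "non_responder",
      "non_responder", "responder", "responder", "responder",
      "non_responder", "non_responder", "unevaluable", "responder"
    ),
    arms = clinical$drug_classes,
    timing = clinical$timing,
    stringsAsFactors = FALSE
  )
  list(
    matrices = list(
      expression_matrix(vals1, dataset_id = "WRK1", platform = "rnaseq_like"),
      expression_matrix(vals2, dataset_id = "WRK2", platform = "rnaseq_like")
    ),
    clinical = clinical,
    truth = list(samples = truth, markers = data.frame(
      gene = c("RES1", "SENS1"),
      target_auc = c(1, 1),
      direction = c("higher_in_nonresponder", "higher_in_responder"),
      stringsAsFactors = FALSE
    ))
  )
}
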