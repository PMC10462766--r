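# Independent oracles, deliberately naive: brute-force pair counting for the
# AUC, full label-permutation enumeration for the exact two-sided p, and
# small fixture builders shared across test files.

# AUC by enumerating all (nonresp, resp) pairs.
brute_auc <- function(nonresp, resp) {
  cmp <- outer(nonresp, resp, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Two-sided permutation p: fraction of label assignments whose U is at least
# as far from nx*ny/2 as the observed one.
enum_p <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  n <- length(pooled)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  center <- nx * (n - nx) / 2
  combos <- utils::combn(n, nx)
  u_all <- colSums(matrix(r[combos], nrow = nx)) - nx * (nx + 1) / 2
  mean(abs(u_all - center) >= abs(u_obs - center) - 1e-9)
}

# A ready-made cohort around an explicit value matrix and label vector,
# bypassing the I/O layers.
make_cohort <- function(values, labels,
                        drug_class = "anti-PD-1", timing = "pre-treatment",
                        min_class_size = 3L) {
  stopifnot(ncol(values) == length(labels))
  structure(
    list(
      spec = cohort_spec(drug_class, timing, min_class_size = min_class_size),
      values = values,
      labels = stats::setNames(labels, colnames(values)),
      sample_datasets = stats::setNames(rep("T1", ncol(values)), colnames(values)),
      n_responder = sum(labels == "responder"),
      n_nonresponder = sum(labels == "non_responder")
    ),
    class = "cohort"
  )
}

# Cohort of pure null genes: every value iid log-normal, labels balanced.
null_cohort <- function(n_genes, n_per_class) {
  n <- 2L * n_per_class
  v <- matrix(
    rlnorm(n_genes * n, meanlog = 4, sdlog = 1),
    nrow = n_genes,
    dimnames = list(sprintf("G%04d", seq_len(n_genes)), sprintf("S%04d", seq_len(n)))
  )
  make_cohort(v, rep(c("responder", "non_responder"), each = n_per_class))
}

# Null cohort with planted markers: rows `marker_rows` get a binormal
# log-scale shift delta = sqrt(2) * qnorm(target_auc) added to the
# non-responder class.
planted_cohort <- function(n_genes, n_per_class, marker_rows, target_auc) {
  co <- null_cohort(n_genes, n_per_class)
  delta <- sqrt(2) * qnorm(target_auc)
  nr <- co$labels == "non_responder"
  for (i in marker_rows) {
    co$values[i, nr] <- exp(log(co$values[i, nr]) + delta)
  }
  co
}

# One-dataset expression matrix from a plain matrix.
make_expr <- function(values, dataset_id = "D1", platform = "rnaseq_like") {
  expression_matrix(values, dataset_id = dataset_id, platform = platform)
}

# Minimal clinical row(s) with sensible defaults, overridable per field.
clinical_rows <- function(n = 1, sample_id = paste0("S", seq_len(n)),
                          dataset_id = "D1", patient_id = sample_id,
                          tumor_type = "melanoma", drug_classes = "anti-PD-1",
                          timing = "pre-treatment", recist = NA,
                          pfs_months = NA, pfs_event = NA,
                          os_months = NA, os_event = NA) {
  validate_clinical(data.frame(
    sample_id = sample_id, dataset_id = dataset_id, patient_id = patient_id,
    tumor_type = tumor_type, drug_classes = drug_classes, timing = timing,
    recist = recist, pfs_months = pfs_months, pfs_event = pfs_event,
    os_months = os_months, os_event = os_event,
    stringsAsFactors = FALSE
  ))
}
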