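# Figure rendering (per-gene ROC curve + responder/non-responder boxplot)
# and the end-to-end pipeline composition.

#' Empirical ROC coordinates for one gene in a cohort
#'
#' Step-function convention: each unique expression value is a threshold
#' (classifier "value >= t predicts non-responder"); tied values move both
#' rates simultaneously, so the trapezoid area under this path equals the
#' midrank AUC exactly.
#'
#' @param nonresp,resp Numeric value vectors of the two classes.
#' @return Data.frame with `fpr`, `tpr` from (0,0) to (1,1).
#' @export
roc_points <- function(nonresp, resp) {
  thr <- sort(unique(c(nonresp, resp)), decreasing = TRUE)
  fpr <- vapply(thr, function(t) mean(resp >= t), numeric(1))
  tpr <- vapply(thr, function(t) mean(nonresp >= t), numeric(1))
  data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
}

.gene_class_values <- function(cohort, gene) {
  if (!gene %in% rownames(cohort$values)) {
    stop("gene '", gene, "' not present in the cohort matrix")
  }
  vals <- cohort$values[gene, ]
  nonresp <- vals[cohort$labels == "non_responder" & !is.na(vals)]
  resp <- vals[cohort$labels == "responder" & !is.na(vals)]
  min_n <- cohort$spec$min_class_size
  if (length(nonresp) < min_n || length(resp) < min_n) {
    stop("gene '", gene, "' not testable in this cohort (class sizes ",
         length(nonresp), "/", length(resp), " below ", min_n, ")")
  }
  list(nonresp = nonresp, resp = resp)
}

#' ROC curve and class boxplot for one gene
#'
#' Renders the two standard candidate-gene panels: the empirical ROC curve
#' annotated with the oriented AUC, and a responder vs non-responder
#' expression boxplot annotated with the Mann-Whitney p-value and per-class
#' n. Every printed number is recomputed from the cohort object itself.
#'
#' @param cohort A [build_cohort()] result.
#' @param gene Gene symbol testable in the cohort.
#' @param file_roc,file_box Optional output paths (".png" or ".svg"); when
#'   given, the plots are written there.
#' @param width,height,dpi Device settings passed to [ggplot2::ggsave()].
#' @return List with ggplot objects `roc` and `box` and the annotation
#'   numbers (`auc`, `direction`, `p`, `n_responder`, `n_nonresponder`).
#' @export
plot_gene <- function(cohort, gene, file_roc = NULL, file_box = NULL,
                      width = 4, height = 4, dpi = 150) {
  cls <- .gene_class_values(cohort, gene)
  core <- .mw_core(cls$nonresp, cls$resp)
  auc <- max(core$auc, 1 - core$auc)
  direction <- if (core$auc > 0.5) {
    "higher_in_nonresponder"
  } else if (core$auc < 0.5) {
    "higher_in_responder"
  } else {
    "tie"
  }

  pts <- roc_points(cls$nonresp, cls$resp)
  roc_plot <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", color = "grey60") +
    ggplot2::geom_path(color = "#b2182b", linewidth = 0.8) +
    ggplot2::annotate(
      "text", x = 0.65, y = 0.1,
      label = sprintf("AUC = %.3f", auc), size = 4
    ) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = gene, x = "False positive rate", y = "True positive rate"
    ) +
    ggplot2::theme_bw()

  box_df <- data.frame(
    group = factor(
      rep(c("non-responder", "responder"), c(length(cls$nonresp), length(cls$resp))),
      levels = c("non-responder", "responder")
    ),
    value = c(cls$nonresp, cls$resp)
  )
  labels_n <- c(
    sprintf("non-responder\n(n = %d)", length(cls$nonresp)),
    sprintf("responder\n(n = %d)", length(cls$resp))
  )
  box_plot <- ggplot2::ggplot(box_df, ggplot2::aes(x = .data$group, y = .data$value, fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.shape = NA, alpha = 0.7) +
    ggplot2::geom_jitter(width = 0.15, size = 0.8, alpha = 0.6) +
    ggplot2::scale_x_discrete(labels = labels_n) +
    ggplot2::scale_fill_manual(values = c("#b2182b", "#2166ac"), guide = "none") +
    ggplot2::labs(
      title = gene,
      subtitle = sprintf("Mann-Whitney p = %.2g", core$p),
      x = NULL, y = "Normalized expression"
    ) +
    ggplot2::theme_bw()

  if (!is.null(file_roc)) {
    ggplot2::ggsave(file_roc, roc_plot, width = width, height = height, dpi = dpi)
  }
  if (!is.null(file_box)) {
    ggplot2::ggsave(file_box, box_plot, width = width, height = height, dpi = dpi)
  }
  list(
    roc = roc_plot, box = box_plot,
    auc = auc, direction = direction, p = core$p,
    n_responder = length(cls$resp), n_nonresponder = length(cls$nonresp)
  )
}

#' Run the whole pipeline from a dataset manifest
#'
#' harmonize -> label -> build cohort -> screen -> write results. The run
#' log records per-dataset sample and gene counts, cohort sizes, the number
#' of genes tested and the Bonferroni threshold (exact and display form).
#' Identical inputs produce byte-identical result tables.
#'
#' @param manifest Path to a YAML/JSON dataset manifest.
#' @param out_dir Output directory (created if needed).
#' @param drug_class,timing Cohort selection (defaults: anti-PD-1,
#'   pre-treatment).
#' @param label_cfg A [label_config()].
#' @param alpha Family-wise error level.
#' @param min_class_size Per-class minimum for a gene to be tested.
#' @param target Scaling target for the harmonized table.
#' @param gene_filter Optional whitelist passed to [screen_cohort()].
#' @param druggable Optional druggable-gene list for [annotate_druggable()].
#' @param plot_genes Optional gene symbols to render ROC/boxplot panels for.
#' @return Invisibly, a list with the combined matrix, labels, cohort,
#'   screen result and output paths.
#' @export
run_pipeline <- function(manifest, out_dir,
                         drug_class = "anti-PD-1", timing = "pre-treatment",
                         label_cfg = label_config(), alpha = 0.05,
                         min_class_size = 3L, target = 1000,
                         gene_filter = NULL, druggable = NULL,
                         plot_genes = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  say <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }
  say("iciscreen version: ", as.character(utils::packageVersion("iciscreen")))

  mf <- read_manifest(manifest)
  included <- mf[mf$include, ]
  say("datasets in manifest: ", nrow(mf), " (included: ", nrow(included), ")")
  matrices <- vector("list", nrow(included))
  clin_list <- list()
  for (i in seq_len(nrow(included))) {
    matrices[[i]] <- read_expression(
      included$expression_path[i],
      dataset_id = included$dataset_id[i],
      platform = included$platform[i]
    )
    say(
      "  ", included$dataset_id[i], ": ",
      nrow(matrices[[i]]$values), " genes x ", ncol(matrices[[i]]$values), " samples"
    )
    clin_list[[included$clinical_path[i]]] <- TRUE
  }
  clinical <- do.call(rbind, lapply(names(clin_list), read_clinical))
  clinical <- clinical[!duplicated(clinical$sample_id), ]

  cm <- harmonize(matrices, target = target)
  say("combined: ", nrow(cm$values), " genes x ", ncol(cm$values), " samples; state: ",
      cm$normalization_state)

  lab <- label_cohort(clinical, label_cfg)
  say(
    "labels: ",
    paste(names(lab$summary$by_label), lab$summary$by_label, sep = "=", collapse = ", ")
  )

  spec <- cohort_spec(drug_class, timing, min_class_size = min_class_size)
  cohort <- tryCatch(
    build_cohort(cm, clinical, lab$labels, spec),
    error = function(e) stop("cohort stage: ", conditionMessage(e), call. = FALSE)
  )
  say(
    "cohort ", drug_class, " ", timing, ": ",
    cohort$n_responder, " responders / ", cohort$n_nonresponder, " non-responders"
  )

  screen <- screen_cohort(cohort, alpha = alpha, gene_filter = gene_filter)
  if (!is.null(druggable)) screen <- annotate_druggable(screen, druggable)
  say(
    "screen: m_tested = ", screen$m_tested,
    ", threshold = ", formatC(screen$threshold, format = "g", digits = 4),
    " (display ", format_threshold(screen$threshold_display), "), ",
    sum(screen$results$significant), " significant"
  )

  results_path <- file.path(out_dir, "results.tsv")
  write_results(screen, results_path)

  plot_paths <- character(0)
  for (g in plot_genes) {
    roc_file <- file.path(out_dir, paste0(g, "_roc.png"))
    box_file <- file.path(out_dir, paste0(g, "_boxplot.png"))
    plot_gene(cohort, g, file_roc = roc_file, file_box = box_file)
    plot_paths <- c(plot_paths, roc_file, box_file)
  }

  log_path <- file.path(out_dir, "run_log.txt")
  writeLines(log_lines, log_path)
  invisible(list(
    combined = cm, labels = lab, cohort = cohort, screen = screen,
    results_path = results_path, log_path = log_path, plot_paths = plot_paths
  ))
}
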