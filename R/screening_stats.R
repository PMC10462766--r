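# Statistical core of the screen: Mann-Whitney U with midranks, its ROC AUC
# equivalence U = AUC * n1 * n2, oriented fold change, and genome-wide
# Bonferroni control.

# Rank machinery shared by roc_auc / mann_whitney / the per-gene screen.
# x plays the role of the positive class (non-responders): U counts pairs
# where x exceeds y, ties half-weighted.
.mw_core <- function(x, y, exact = NULL) {
  nx <- length(x)
  ny <- length(y)
  if (nx == 0L || ny == 0L) stop("both groups must be non-empty")
  n <- nx + ny
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2

  tie_lengths <- rle(sort(c(x, y)))$lengths
  has_ties <- any(tie_lengths > 1L)

  use_exact <- if (is.null(exact)) {
    !has_ties && nx <= 8L && ny <= 8L
  } else {
    if (isTRUE(exact) && has_ties) stop("exact p-value is undefined with ties")
    isTRUE(exact)
  }
  if (use_exact) {
    # exact null distribution (identical to permutation enumeration for
    # tie-free data); two-sided p doubles the smaller tail, capped at 1
    lo <- stats::pwilcox(u, nx, ny)
    hi <- stats::pwilcox(nx * ny - u, nx, ny) # P(U >= u) by symmetry
    p <- min(1, 2 * min(lo, hi))
    method <- "exact"
  } else {
    mu <- nx * ny / 2
    tie_term <- sum(tie_lengths^3 - tie_lengths)
    sigma2 <- nx * ny / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    if (sigma2 <= 0) {
      # constant pooled data: no ordering information
      p <- 1
    } else {
      d <- u - mu
      z <- (d - sign(d) * min(0.5, abs(d))) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal"
  }
  list(u = u, p = p, auc = u / (nx * ny), method = method)
}

#' Empirical ROC AUC of non-responder vs responder expression
#'
#' The probability that a randomly chosen non-responder has higher marker
#' value than a randomly chosen responder, ties counted half:
#' `AUC = (#(nr > r) + 0.5 * #(nr == r)) / (n_nr * n_r)`. This is the raw
#' (unoriented) AUC with non-responders as the positive class; it equals
#' `U / (n_nr * n_r)` for the Mann-Whitney U of the same comparison.
#'
#' @param nonresp Numeric vector of non-responder values.
#' @param resp Numeric vector of responder values.
#' @return Raw AUC in \[0, 1\].
#' @examples
#' roc_auc(c(2, 4, 6, 8), c(1, 3, 5, 7)) # 10/16
#' @export
roc_auc <- function(nonresp, resp) {
  .mw_core(nonresp, resp)$auc
}

#' Mann-Whitney unpaired U test
#'
#' U is the rank-sum statistic for `x` against `y` with midranks for ties;
#' it satisfies `U = roc_auc(x, y) * length(x) * length(y)`. The two-sided
#' p-value uses the exact null distribution when both groups have at most 8
#' observations and the pooled data are tie-free, and otherwise a normal
#' approximation with tie-corrected variance and continuity correction.
#' Constant pooled data give `U = n_x * n_y / 2` and `p = 1`.
#'
#' @param x,y Non-empty numeric vectors.
#' @param exact `NULL` (default) picks the method by sample size and ties;
#'   `TRUE` forces the exact distribution (error with ties), `FALSE` forces
#'   the normal approximation.
#' @return List with `u`, `p`, and `method` ("exact" or "normal").
#' @examples
#' mann_whitney(c(4, 5, 6), c(1, 2, 3)) # U = 9, exact p = 0.1
#' @export
mann_whitney <- function(x, y, exact = NULL) {
  out <- .mw_core(x, y, exact = exact)
  out[c("u", "p", "method")]
}

#' Oriented fold change between class means
#'
#' The ratio of the larger to the smaller class mean (always >= 1) together
#' with the direction saying which class is higher. Both class means must be
#' positive: a ratio is undefined at zero on the non-negative expression
#' scale.
#'
#' @param nonresp,resp Numeric vectors of class values (missing dropped).
#' @return List with `fc` (>= 1) and `direction`
#'   ("higher_in_nonresponder" / "higher_in_responder" / "tie").
#' @export
fold_change <- function(nonresp, resp) {
  m_nr <- mean(nonresp, na.rm = TRUE)
  m_r <- mean(resp, na.rm = TRUE)
  if (!is.finite(m_nr) || !is.finite(m_r) || m_nr <= 0 || m_r <= 0) {
    stop("fold change needs positive class means (got ", m_nr, " and ", m_r, ")")
  }
  direction <- if (m_nr > m_r) {
    "higher_in_nonresponder"
  } else if (m_r > m_nr) {
    "higher_in_responder"
  } else {
    "tie"
  }
  list(fc = max(m_nr, m_r) / min(m_nr, m_r), direction = direction)
}

#' Bonferroni threshold for a screen of m genes
#'
#' The exact family-wise threshold `alpha / m`, plus the display form
#' truncated (floored) to two significant digits — the form a screen report
#' prints. Filtering always uses the exact threshold.
#'
#' @param m Number of simultaneous tests (>= 1).
#' @param alpha Family-wise error level in (0, 1), default 0.05.
#' @return List with `exact` and `display`.
#' @examples
#' bonferroni_threshold(29755) # display 1.6e-06
#' @export
bonferroni_threshold <- function(m, alpha = 0.05) {
  stopifnot(length(m) == 1L, m >= 1, is.numeric(alpha), alpha > 0, alpha < 1)
  exact <- alpha / m
  e <- floor(log10(exact))
  display <- floor(exact / 10^(e - 1)) * 10^(e - 1)
  list(exact = exact, display = display)
}

format_threshold <- function(x) {
  formatC(x, format = "E", digits = 1)
}

# One gene's screen row; x = non-responder values, y = responder values,
# both already non-missing.
.screen_gene <- function(x, y) {
  core <- .mw_core(x, y)
  raw <- core$auc
  auc <- max(raw, 1 - raw)
  direction <- if (raw > 0.5) {
    "higher_in_nonresponder"
  } else if (raw < 0.5) {
    "higher_in_responder"
  } else {
    "tie"
  }
  fc <- tryCatch(fold_change(x, y)$fc, error = function(e) NA_real_)
  list(
    u = core$u, p = core$p, auc = auc, direction = direction, fc = fc
  )
}

#' Screen every gene of a cohort for association with response
#'
#' For each gene with at least `min_class_size` non-missing values in both
#' classes (after the optional gene filter), computes the Mann-Whitney U and
#' two-sided p for non-responders vs responders, the oriented ROC AUC
#' `max(AUC, 1 - AUC)` with its direction, and the oriented fold change.
#' Significance is controlled family-wise by Bonferroni at `alpha` over the
#' number of genes actually tested in this cohort, so the threshold is
#' cohort-specific.
#'
#' @param cohort A [build_cohort()] result.
#' @param alpha Family-wise error level (default 0.05).
#' @param min_class_size Override of the spec's per-class minimum.
#' @param gene_filter Optional whitelist: a character vector of gene symbols
#'   or a predicate `function(genes) -> logical` (e.g. a protein-coding
#'   whitelist).
#' @return A `screen_result`: list with `spec`, `m_tested`, `alpha`,
#'   `threshold`, `threshold_display` and `results` (data.frame with one row
#'   per tested gene, ordered by raw p).
#' @export
screen_cohort <- function(cohort, alpha = 0.05, min_class_size = NULL,
                          gene_filter = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  if (is.null(min_class_size)) min_class_size <- cohort$spec$min_class_size
  v <- cohort$values
  genes <- rownames(v)
  if (!is.null(gene_filter)) {
    keep <- if (is.function(gene_filter)) gene_filter(genes) else genes %in% gene_filter
    v <- v[keep, , drop = FALSE]
    genes <- rownames(v)
  }
  if (length(genes) == 0L) stop("no genes left to test after filtering")

  nr_idx <- cohort$labels == "non_responder"
  r_idx <- cohort$labels == "responder"
  ng <- length(genes)
  tested <- logical(ng)
  n_r <- integer(ng)
  n_nr <- integer(ng)
  u_stat <- numeric(ng)
  auc <- numeric(ng)
  direction <- character(ng)
  p_raw <- numeric(ng)
  fc <- numeric(ng)
  for (i in seq_len(ng)) {
    x <- v[i, nr_idx]
    y <- v[i, r_idx]
    x <- x[!is.na(x)]
    y <- y[!is.na(y)]
    if (length(x) < min_class_size || length(y) < min_class_size) next
    g <- .screen_gene(x, y)
    tested[i] <- TRUE
    n_r[i] <- length(y)
    n_nr[i] <- length(x)
    u_stat[i] <- g$u
    auc[i] <- g$auc
    direction[i] <- g$direction
    p_raw[i] <- g$p
    fc[i] <- g$fc
  }
  if (!any(tested)) stop("zero genes testable at min_class_size = ", min_class_size)
  res <- data.frame(
    gene = genes[tested],
    n_responder = n_r[tested], n_nonresponder = n_nr[tested],
    u_statistic = u_stat[tested], auc = auc[tested],
    direction = direction[tested], p_raw = p_raw[tested],
    fold_change = fc[tested],
    stringsAsFactors = FALSE
  )
  m_tested <- nrow(res)
  thr <- bonferroni_threshold(m_tested, alpha)
  res$significant <- res$p_raw <= thr$exact
  res <- res[order(res$p_raw, res$gene), , drop = FALSE]
  rownames(res) <- NULL
  structure(
    list(
      spec = cohort$spec, m_tested = m_tested, alpha = alpha,
      threshold = thr$exact, threshold_display = thr$display,
      results = res
    ),
    class = "screen_result"
  )
}

#' @export
print.screen_result <- function(x, ...) {
  cat(
    "<screen_result>", x$spec$drug_class, x$spec$timing, "-",
    x$m_tested, "genes tested, alpha", x$alpha,
    "(threshold", format_threshold(x$threshold_display), "),",
    sum(x$results$significant), "significant\n"
  )
  invisible(x)
}

#' Evaluate a fixed gene panel in a cohort
#'
#' Restricts the screen to a user-supplied panel (e.g. established cancer
#' biomarkers or mismatch-repair genes) and controls the family-wise error
#' over the panel size instead of the genome: the threshold is
#' `alpha / (number of testable panel genes)`. Panel genes absent from the
#' matrix or failing the per-class minimum are reported as untested.
#'
#' @param cohort A [build_cohort()] result.
#' @param genes Character vector of panel gene symbols.
#' @param alpha Family-wise error level (default 0.05).
#' @param min_class_size Override of the spec's per-class minimum.
#' @return A `screen_result` with an extra `untested` character vector.
#' @export
evaluate_panel <- function(cohort, genes, alpha = 0.05, min_class_size = NULL) {
  stopifnot(inherits(cohort, "cohort"), length(genes) > 0L)
  genes <- unique(genes)
  present <- intersect(genes, rownames(cohort$values))
  if (length(present) == 0L) stop("no panel gene present in the cohort matrix")
  screen <- screen_cohort(
    cohort,
    alpha = alpha, min_class_size = min_class_size,
    gene_filter = present
  )
  screen$untested <- setdiff(genes, screen$results$gene)
  screen
}

#' How many genes beat a given gene's oriented AUC
#'
#' @param screen A `screen_result`.
#' @param gene Gene symbol tested in the screen.
#' @return Number of other genes with strictly higher oriented AUC.
#' @export
rank_against <- function(screen, gene) {
  stopifnot(inherits(screen, "screen_result"))
  res <- screen$results
  i <- match(gene, res$gene)
  if (is.na(i)) stop("gene '", gene, "' was not tested in this screen")
  sum(res$auc > res$auc[i])
}

#' Flag druggable genes in a screen result
#'
#' Joins a user-supplied druggable-gene list onto the results and extracts
#' the headline category: significant, druggable genes with higher
#' expression in non-responders (candidate resistance targets), ordered by
#' raw p.
#'
#' @param screen A `screen_result`.
#' @param druggable Character vector of druggable gene symbols.
#' @return The screen with a logical `druggable` result column and a
#'   `druggable_resistance` data.frame of the headline candidates.
#' @export
annotate_druggable <- function(screen, druggable) {
  stopifnot(inherits(screen, "screen_result"))
  res <- screen$results
  res$druggable <- res$gene %in% druggable
  screen$results <- res
  hits <- res[res$significant & res$druggable & res$direction == "higher_in_nonresponder", ]
  screen$druggable_resistance <- hits[order(hits$p_raw, hits$gene), , drop = FALSE]
  screen
}
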