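# Cross-platform harmonization: merge per-dataset matrices over the union
# gene space, quantile normalize the combined table, scale to a target mean.

#' Merge per-dataset expression matrices into one combined table
#'
#' The combined gene set is the union over input matrices; entries absent
#' from a sample's platform are missing (`NA`), never zero. Sample
#' identifiers must be globally unique across datasets.
#'
#' @param matrices Non-empty list of [expression_matrix()] objects.
#' @return A `combined_matrix`: list with `values` (union-genes x all-samples
#'   matrix), `sample_datasets` (named character: sample -> dataset),
#'   `platforms` (named character: dataset -> platform) and
#'   `normalization_state` (one of "raw", "quantile_normalized", "scaled").
#' @export
merge_datasets <- function(matrices) {
  if (length(matrices) == 0L) stop("need at least one expression matrix")
  lapply(matrices, validate_expression_matrix)
  all_samples <- unlist(lapply(matrices, function(m) colnames(m$values)))
  if (anyDuplicated(all_samples)) {
    stop(
      "sample_id collision across datasets: ",
      paste(unique(all_samples[duplicated(all_samples)]), collapse = ", ")
    )
  }
  genes <- Reduce(union, lapply(matrices, function(m) rownames(m$values)))
  v <- matrix(
    NA_real_, nrow = length(genes), ncol = length(all_samples),
    dimnames = list(genes, all_samples)
  )
  sample_datasets <- character(0)
  platforms <- character(0)
  for (m in matrices) {
    v[rownames(m$values), colnames(m$values)] <- m$values
    sample_datasets[colnames(m$values)] <- m$dataset_id
    platforms[m$dataset_id] <- m$platform
  }
  structure(
    list(
      values = v,
      sample_datasets = sample_datasets,
      platforms = platforms,
      normalization_state = "raw"
    ),
    class = "combined_matrix"
  )
}

#' @export
print.combined_matrix <- function(x, ...) {
  cat(
    "<combined_matrix>", nrow(x$values), "genes x", ncol(x$values), "samples from",
    length(unique(x$sample_datasets)), "dataset(s); state:", x$normalization_state, "\n"
  )
  invisible(x)
}

# Empirical quantile curve of one sample's sorted non-missing values,
# linearly interpolated onto a probability grid of length `g`.
.quantile_curve <- function(sorted_vals, g) {
  k <- length(sorted_vals)
  if (k == g) return(sorted_vals)
  if (k == 1L) return(rep(sorted_vals, g))
  stats::approx(
    x = seq(0, 1, length.out = k), y = sorted_vals,
    xout = seq(0, 1, length.out = g)
  )$y
}

#' Quantile normalize a combined expression table
#'
#' Classical quantile normalization across all samples of the combined
#' table. The reference distribution is the across-sample mean of
#' within-sample order statistics; each sample's value of rank r is replaced
#' by the reference value of rank r. Tied values within a sample receive the
#' mean of the reference values their tied ranks span. Samples missing genes
#' (platform gene-set differences) contribute to, and are normalized
#' against, the reference quantile function evaluated at their own empirical
#' quantiles by linear interpolation.
#'
#' @param cm A `combined_matrix` in state "raw".
#' @return The matrix with `normalization_state = "quantile_normalized"`.
#' @examples
#' m <- expression_matrix(
#'   matrix(c(2, 5, 3, 1, 4, 6), 3, 2,
#'     dimnames = list(c("g1", "g2", "g3"), c("A", "B"))
#'   ),
#'   dataset_id = "demo"
#' )
#' qn <- quantile_normalize(merge_datasets(list(m)))
#' qn$values # reference = sorted-mean distribution [1.5, 3.5, 5.5]
#' @export
quantile_normalize <- function(cm) {
  stopifnot(inherits(cm, "combined_matrix"))
  if (cm$normalization_state != "raw") {
    stop("quantile_normalize expects a raw combined matrix, got state '",
         cm$normalization_state, "'")
  }
  v <- cm$values
  g <- nrow(v)
  grid_probs <- if (g > 1L) seq(0, 1, length.out = g) else 0.5

  curves <- vapply(
    seq_len(ncol(v)),
    function(j) .quantile_curve(sort(v[, j], na.last = NA), g),
    numeric(g)
  )
  reference <- rowMeans(curves)

  out <- v
  for (j in seq_len(ncol(v))) {
    idx <- which(!is.na(v[, j]))
    x <- v[idx, j]
    k <- length(x)
    refk <- if (k == g) {
      reference
    } else if (k == 1L) {
      mean(reference)
    } else {
      stats::approx(grid_probs, reference, xout = seq(0, 1, length.out = k))$y
    }
    ord <- order(x)
    # rank r gets refk[r]; ties averaged over the reference values they span
    assigned <- stats::ave(refk, x[ord], FUN = mean)
    res <- numeric(k)
    res[ord] <- assigned
    out[idx, j] <- res
  }
  cm$values <- out
  cm$normalization_state <- "quantile_normalized"
  cm
}

#' Scale a normalized table to a target overall mean
#'
#' Multiplies every value by one global constant
#' `c = target / mean(all non-missing values)`, fixing the overall mean of
#' the combined table at `target` (default 1000). A single global constant
#' leaves every rank statistic — U, AUC, p — and every fold change
#' unchanged.
#'
#' @param cm A `combined_matrix` in state "quantile_normalized".
#' @param target Positive target for the overall mean (default 1000).
#' @return The matrix with `normalization_state = "scaled"`.
#' @export
scale_to_target <- function(cm, target = 1000) {
  stopifnot(inherits(cm, "combined_matrix"))
  if (cm$normalization_state != "quantile_normalized") {
    stop("scale_to_target expects a quantile-normalized matrix, got state '",
         cm$normalization_state, "'")
  }
  stopifnot(is.numeric(target), length(target) == 1L, target > 0)
  overall <- mean(cm$values, na.rm = TRUE)
  if (!is.finite(overall) || overall <= 0) {
    stop("cannot scale: overall mean of the table is not positive")
  }
  cm$values <- cm$values * (target / overall)
  cm$normalization_state <- "scaled"
  cm$scale_target <- target
  cm
}

#' Harmonize a set of datasets end to end
#'
#' Convenience composition: [merge_datasets()], [quantile_normalize()],
#' optionally [scale_to_target()].
#'
#' @param matrices List of `expr_matrix` objects.
#' @param target Target overall mean for scaling (default 1000).
#' @param scale If `FALSE`, stop after quantile normalization.
#' @return A `combined_matrix`.
#' @export
harmonize <- function(matrices, target = 1000, scale = TRUE) {
  cm <- quantile_normalize(merge_datasets(matrices))
  if (scale) cm <- scale_to_target(cm, target)
  cm
}
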