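test_that("merge takes the union gene space and keeps platform gaps missing", {
  m1 <- make_expr(matrix(
    c(1, 2, 3, 4), 2, 2,
    dimnames = list(c("A", "B"), c("s1", "s2"))
  ), "D1")
  m2 <- make_expr(matrix(
    c(5, 6, 7, 8), 2, 2,
    dimnames = list(c("B", "C"), c("s3", "s4"))
  ), "D2")
  cm <- merge_datasets(list(m1, m2))
  expect_setequal(rownames(cm$values), c("A", "B", "C"))
  expect_true(all(is.na(cm$values["A", c("s3", "s4")])))
  expect_true(all(is.na(cm$values["C", c("s1", "s2")])))
  expect_equal(unname(cm$values["B", ]), c(2, 4, 5, 7))
  expect_identical(unname(cm$sample_datasets), rep(c("D1", "D2"), each = 2))
  expect_identical(cm$normalization_state, "raw")

  # single input: identity up to container
  single <- merge_datasets(list(m1))
  expect_equal(single$values, m1$values)

  # sample collisions are named
  m_dup <- make_expr(matrix(1, 1, 1, dimnames = list("A", "s1")), "D3")
  expect_error(merge_datasets(list(m1, m_dup)), "s1")

  # sizes concatenate
  mk <- function(n, id) make_expr(matrix(
    seq_len(2 * n), 2, n,
    dimnames = list(c("A", "B"), paste0(id, seq_len(n)))
  ), id)
  big <- merge_datasets(list(mk(5, "x"), mk(7, "y"), mk(9, "z")))
  expect_identical(ncol(big$values), 21L)
})

test_that("quantile normalization matches the hand-computed reference rule", {
  # samples A=[2,5,3], B=[1,4,6]: reference = mean of order stats [1.5,3.5,5.5]
  m <- make_expr(matrix(
    c(2, 5, 3, 1, 4, 6), 3, 2,
    dimnames = list(c("g1", "g2", "g3"), c("A", "B"))
  ))
  qn <- quantile_normalize(merge_datasets(list(m)))
  expect_equal(unname(qn$values[, "A"]), c(1.5, 5.5, 3.5))
  expect_equal(unname(qn$values[, "B"]), c(1.5, 3.5, 5.5))
  expect_identical(qn$normalization_state, "quantile_normalized")
  expect_error(quantile_normalize(qn), "state")
})

test_that("ties receive the mean of the reference values their ranks span", {
  # [4,4,10] vs [1,2,3]: reference [2.5,3,6.5]; tied pair -> 2.75 each
  m <- make_expr(matrix(
    c(4, 4, 10, 1, 2, 3), 3, 2,
    dimnames = list(c("g1", "g2", "g3"), c("A", "B"))
  ))
  qn <- quantile_normalize(merge_datasets(list(m)))
  expect_equal(unname(qn$values[, "A"]), c(2.75, 2.75, 6.5))
  expect_equal(unname(qn$values[, "B"]), c(2.5, 3, 6.5))
})

test_that("identical samples are a fixed point and normalization is idempotent", {
  v <- matrix(
    rep(c(3, 1, 8, 5), 3), 4, 3,
    dimnames = list(paste0("g", 1:4), paste0("s", 1:3))
  )
  qn <- quantile_normalize(merge_datasets(list(make_expr(v))))
  expect_equal(qn$values, v)

  set.seed(21)
  v2 <- matrix(
    rlnorm(50 * 6), 50, 6,
    dimnames = list(paste0("g", 1:50), paste0("s", 1:6))
  )
  once <- quantile_normalize(merge_datasets(list(make_expr(v2))))
  again <- once
  again$normalization_state <- "raw"
  twice <- quantile_normalize(again)
  expect_equal(twice$values, once$values, tolerance = 1e-9)
})

test_that("complete-case samples share one sorted value multiset; ranks are preserved", {
  set.seed(22)
  v <- matrix(
    rlnorm(200 * 5, 3, 1.5), 200, 5,
    dimnames = list(paste0("g", 1:200), paste0("s", 1:5))
  )
  qn <- quantile_normalize(merge_datasets(list(make_expr(v))))
  ref <- unname(sort(qn$values[, 1]))
  for (j in 2:5) expect_equal(unname(sort(qn$values[, j])), ref)
  for (j in 1:5) expect_identical(order(qn$values[, j]), order(v[, j]))
})

test_that("quantile normalization agrees with limma on complete tie-free data", {
  set.seed(23)
  v <- matrix(
    rlnorm(120 * 8, 4, 1), 120, 8,
    dimnames = list(paste0("g", 1:120), paste0("s", 1:8))
  )
  qn <- quantile_normalize(merge_datasets(list(make_expr(v))))
  ref <- limma::normalizeQuantiles(v)
  expect_equal(qn$values, ref, tolerance = 1e-9)
})

test_that("scaling applies one global constant fixing the overall mean", {
  m <- make_expr(matrix(
    c(1, 2, 3, 4), 2, 2,
    dimnames = list(c("g1", "g2"), c("s1", "s2"))
  ))
  qn <- quantile_normalize(merge_datasets(list(m)))
  qn$values <- matrix(
    c(1, 2, 3, 4), 2, 2,
    dimnames = dimnames(qn$values)
  ) # mean 2.5
  sc <- scale_to_target(qn, target = 1000)
  expect_equal(unname(sc$values), matrix(c(400, 800, 1200, 1600), 2, 2))
  expect_equal(mean(sc$values), 1000, tolerance = 1e-9)

  qn2 <- quantile_normalize(merge_datasets(list(m)))
  qn2$values[] <- qn2$values * (1000 / mean(qn2$values))
  sc2 <- scale_to_target(qn2, target = 1000)
  expect_equal(sc2$values, qn2$values, tolerance = 1e-12)

  expect_error(scale_to_target(merge_datasets(list(m))), "state")
  zero <- quantile_normalize(merge_datasets(list(m)))
  zero$values[] <- 0
  expect_error(scale_to_target(zero), "not positive")
})

test_that("global scaling leaves every screen statistic unchanged", {
  set.seed(24)
  co <- planted_cohort(60, 15, marker_rows = 1:2, target_auc = 0.8)
  co_scaled <- co
  co_scaled$values <- co$values * (1000 / mean(co$values))
  s1 <- screen_cohort(co)
  s2 <- screen_cohort(co_scaled)
  expect_identical(s1$results$gene, s2$results$gene)
  expect_equal(s1$results$u_statistic, s2$results$u_statistic)
  expect_equal(s1$results$auc, s2$results$auc)
  expect_equal(s1$results$p_raw, s2$results$p_raw)
  expect_equal(s1$results$fold_change, s2$results$fold_change)
  expect_identical(s1$results$significant, s2$results$significant)
})

test_that("platform-missing samples are normalized by interpolated reference quantiles", {
  set.seed(25)
  full <- matrix(
    rlnorm(100 * 4, 3, 1), 100, 4,
    dimnames = list(paste0("g", 1:100), paste0("f", 1:4))
  )
  panel_genes <- sort(sample(rownames(full), 40))
  panel <- matrix(
    rlnorm(40 * 3, 6, 0.5), 40, 3,
    dimnames = list(panel_genes, paste0("p", 1:3))
  )
  cm <- merge_datasets(list(make_expr(full, "D1"), make_expr(panel, "D2", "panel")))
  qn <- quantile_normalize(cm)
  # panel samples keep their within-sample ordering
  for (j in paste0("p", 1:3)) {
    obs <- qn$values[panel_genes, j]
    expect_identical(order(obs), order(panel[, j]))
    # and land inside the reference range
    expect_true(all(obs >= min(qn$values[, "f1"]) - 1e-9))
    expect_true(all(obs <= max(qn$values[, "f1"]) + 1e-9))
  }
})
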