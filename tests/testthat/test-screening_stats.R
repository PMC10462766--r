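test_that("roc_auc matches hand-checkable cases and brute-force pair counting", {
  expect_equal(roc_auc(c(3, 4, 5), c(1, 2)), 1)
  expect_equal(roc_auc(c(5, 5), c(5, 5)), 0.5)
  expect_equal(roc_auc(c(2, 4, 6, 8), c(1, 3, 5, 7)), 10 / 16)

  set.seed(101)
  for (i in 1:50) {
    x <- sample(0:6, sample(2:12, 1), replace = TRUE) # heavy ties
    y <- sample(0:6, sample(2:12, 1), replace = TRUE)
    expect_equal(roc_auc(x, y), brute_auc(x, y))
  }
  expect_error(roc_auc(numeric(0), 1), "non-empty")
})

test_that("U = AUC * n1 * n2 on random tie-containing vectors", {
  set.seed(102)
  for (i in 1:1000) {
    nx <- sample(2:25, 1)
    ny <- sample(2:25, 1)
    x <- round(rlnorm(nx, 2, 1), sample(0:2, 1)) # rounding induces ties
    y <- round(rlnorm(ny, 2, 1), sample(0:2, 1))
    mw <- mann_whitney(x, y)
    expect_equal(mw$u, roc_auc(x, y) * nx * ny, tolerance = 1e-12)
  }
})

test_that("antisymmetry: roc_auc(a, b) + roc_auc(b, a) = 1", {
  set.seed(103)
  for (i in 1:100) {
    a <- sample(1:10, sample(3:10, 1), replace = TRUE)
    b <- sample(1:10, sample(3:10, 1), replace = TRUE)
    expect_equal(roc_auc(a, b) + roc_auc(b, a), 1)
  }
})

test_that("U, p and AUC are invariant under strictly increasing transforms", {
  set.seed(104)
  transforms <- list(
    function(v) exp(v),
    function(v) v^3 + 5,
    function(v) log(v + 20),
    function(v) rank(v, ties.method = "average") # monotone on pooled values
  )
  for (i in 1:25) {
    x <- round(rlnorm(15, 3, 1), 1)
    y <- round(rlnorm(12, 3, 1), 1)
    base <- mann_whitney(x, y)
    base_auc <- roc_auc(x, y)
    for (f in transforms) {
      pooled <- f(c(x, y))
      fx <- pooled[seq_along(x)]
      fy <- pooled[-seq_along(x)]
      tr <- mann_whitney(fx, fy)
      expect_equal(tr$u, base$u)
      expect_equal(tr$p, base$p)
      expect_equal(roc_auc(fx, fy), base_auc)
    }
  }
})

test_that("exact p matches full permutation enumeration for tie-free small samples", {
  expect_equal(mann_whitney(c(4, 5, 6), c(1, 2, 3)), list(u = 9, p = 0.1, method = "exact"))

  set.seed(105)
  for (i in 1:40) {
    nx <- sample(1:8, 1)
    ny <- sample(2:8, 1)
    x <- rnorm(nx)
    y <- rnorm(ny)
    mw <- mann_whitney(x, y)
    expect_identical(mw$method, "exact")
    expect_equal(mw$p, enum_p(x, y), tolerance = 1e-12)
  }
})

test_that("total ties give U = n1*n2/2 and p = 1", {
  mw <- mann_whitney(c(5, 5), c(5, 5))
  expect_equal(mw$u, 2)
  expect_equal(mw$p, 1)
  big <- mann_whitney(rep(3, 30), rep(3, 40))
  expect_equal(big$u, 600)
  expect_equal(big$p, 1)
})

test_that("normal-approximation p stays within 0.03 of permutation enumeration near the exact regime", {
  set.seed(106)
  # just past the exact-path cutoff: one group of 9 forces the asymptotic
  # path, while full enumeration is still feasible as the oracle
  for (i in 1:25) {
    nx <- 9
    ny <- sample(5:8, 1)
    x <- rnorm(nx, sample(0:1, 1))
    y <- rnorm(ny)
    mw <- mann_whitney(x, y)
    expect_identical(mw$method, "normal")
    expect_lt(abs(mw$p - enum_p(x, y)), 0.03)
  }
  # forcing the approximation on tie-free samples with n <= 8 per group:
  # within 0.03 absolute of the exact enumeration
  for (i in 1:60) {
    nx <- sample(4:8, 1)
    ny <- sample(4:8, 1)
    x <- rnorm(nx, sample(0:1, 1))
    y <- rnorm(ny)
    exact_p <- mann_whitney(x, y, exact = TRUE)$p
    expect_equal(exact_p, enum_p(x, y), tolerance = 1e-12)
    approx_p <- mann_whitney(x, y, exact = FALSE)$p
    expect_identical(mann_whitney(x, y, exact = FALSE)$method, "normal")
    expect_lt(abs(approx_p - exact_p), 0.03)
  }
  expect_error(mann_whitney(c(1, 1, 2), c(3, 4), exact = TRUE), "ties")
})

test_that("fold change is an oriented ratio >= 1 with the correct direction", {
  fc1 <- fold_change(rep(22, 4), rep(10, 4))
  expect_equal(fc1$fc, 2.2)
  expect_identical(fc1$direction, "higher_in_nonresponder")

  fc2 <- fold_change(c(1, 3), c(1, 3))
  expect_equal(fc2$fc, 1)
  expect_identical(fc2$direction, "tie")

  fc3 <- fold_change(rep(10, 3), rep(15, 3))
  expect_equal(fc3$fc, 1.5)
  expect_identical(fc3$direction, "higher_in_responder")

  expect_error(fold_change(c(0, 0), c(1, 2)), "positive")
})

test_that("Bonferroni display threshold floors to two significant digits", {
  t1 <- bonferroni_threshold(29755)
  expect_equal(t1$exact, 0.05 / 29755)
  expect_equal(t1$display, 1.6e-06)
  expect_equal(bonferroni_threshold(26819)$display, 1.8e-06)
  expect_equal(bonferroni_threshold(22561)$display, 2.2e-06)
  expect_equal(bonferroni_threshold(1)$exact, 0.05)
  expect_equal(bonferroni_threshold(1)$display, 0.05)
  expect_error(bonferroni_threshold(0), "m >= 1")
})

test_that("screen recovers a strongly planted marker among nulls", {
  set.seed(107)
  co <- planted_cohort(500, 60, marker_rows = 1, target_auc = 0.95)
  screen <- screen_cohort(co)
  expect_identical(screen$m_tested, 500L)
  marker <- screen$results[screen$results$gene == "G0001", ]
  expect_true(marker$significant)
  expect_identical(marker$direction, "higher_in_nonresponder")
  expect_lt(abs(marker$auc - 0.95), 0.06)
  # oriented AUC >= 0.5 everywhere; direction tie iff auc exactly 0.5
  expect_true(all(screen$results$auc >= 0.5))
  expect_identical(screen$results$direction == "tie", screen$results$auc == 0.5)
  # significance flag consistent with the exact threshold
  expect_identical(
    screen$results$significant,
    screen$results$p_raw <= screen$threshold
  )
  # U bounded by the pair count
  expect_true(all(
    screen$results$u_statistic <=
      screen$results$n_responder * screen$results$n_nonresponder
  ))
})

test_that("gene filters shrink m_tested and the Bonferroni family accordingly", {
  set.seed(108)
  co <- null_cohort(500, 20)
  keep <- rownames(co$values)[1:400]
  s_whitelist <- screen_cohort(co, gene_filter = keep)
  expect_identical(s_whitelist$m_tested, 400L)
  expect_equal(s_whitelist$threshold, 0.05 / 400)
  s_pred <- screen_cohort(co, gene_filter = function(g) g %in% keep)
  expect_identical(s_pred$m_tested, 400L)
})

test_that("min_class_size excludes genes measured in too few samples per class", {
  set.seed(109)
  co <- null_cohort(50, 10)
  co$values[1, co$labels == "responder"][1:8] <- NA # 2 responder values left
  screen <- screen_cohort(co, min_class_size = 3)
  expect_identical(screen$m_tested, 49L)
  expect_false("G0001" %in% screen$results$gene)
  expect_error(screen_cohort(co, min_class_size = 50), "zero genes")
})

test_that("panel evaluation controls error over the panel and reports absent genes", {
  set.seed(110)
  co <- planted_cohort(200, 30, marker_rows = 1:2, target_auc = 0.9)
  panel <- c("G0001", "G0002", "NOT_ON_ARRAY")
  pe <- evaluate_panel(co, panel)
  expect_identical(pe$m_tested, 2L)
  expect_equal(pe$threshold, 0.05 / 2)
  expect_identical(pe$untested, "NOT_ON_ARRAY")
  expect_true(all(pe$results$significant))

  # a planted sensitivity marker orients toward responders
  co2 <- null_cohort(50, 40)
  delta <- sqrt(2) * qnorm(0.85)
  r <- co2$labels == "responder"
  co2$values[3, r] <- exp(log(co2$values[3, r]) + delta)
  pe2 <- evaluate_panel(co2, c("G0003", "G0010"))
  row3 <- pe2$results[pe2$results$gene == "G0003", ]
  expect_identical(row3$direction, "higher_in_responder")
  expect_gt(row3$auc, 0.5)

  expect_error(evaluate_panel(co, c("NOPE1", "NOPE2")), "no panel gene")

  # panel = all genes reduces to the full screen
  full <- screen_cohort(co)
  as_panel <- evaluate_panel(co, rownames(co$values))
  expect_equal(as_panel$results, full$results)
})

test_that("rank_against counts strictly higher oriented AUCs", {
  set.seed(111)
  co <- planted_cohort(100, 25, marker_rows = 1:3, target_auc = 0.9)
  screen <- screen_cohort(co)
  top_gene <- screen$results$gene[which.max(screen$results$auc)]
  expect_identical(rank_against(screen, top_gene), 0L)
  for (g in sample(screen$results$gene, 10)) {
    expect_identical(
      rank_against(screen, g),
      sum(sort(screen$results$auc, decreasing = TRUE) >
            screen$results$auc[screen$results$gene == g])
    )
  }
  expect_error(rank_against(screen, "ABSENT"), "not tested")
})

test_that("druggable annotation extracts significant resistance candidates in p order", {
  set.seed(112)
  co <- planted_cohort(300, 50, marker_rows = 1:7, target_auc = 0.92)
  screen <- screen_cohort(co)
  druggable <- c("G0002", "G0005", "G0007", "G0250")
  ann <- annotate_druggable(screen, druggable)
  expect_true(all(c("G0002", "G0005", "G0007") %in% ann$druggable_resistance$gene))
  expect_false("G0250" %in% ann$druggable_resistance$gene) # null gene: not significant
  expect_false(is.unsorted(ann$druggable_resistance$p_raw))

  none <- annotate_druggable(screen, character(0))
  expect_false(any(none$results$druggable))
  expect_identical(nrow(none$druggable_resistance), 0L)
})
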