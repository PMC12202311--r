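two_group <- function(a, b) {
  list(values = c(a, b),
       y = factor(rep(c("castrated_male", "intact_gilt"),
                      c(length(a), length(b))),
                  levels = c("castrated_male", "intact_gilt")))
}

test_that("folded AUC matches pair-counting on the printed examples", {
  g <- two_group(c(1, 2, 3), c(4, 5, 6))
  expect_identical(metabolite_auc(g$values, g$y), 1)
  expect_identical(metabolite_auc(g$values, g$y, fold = FALSE), 0)
  g2 <- two_group(c(1, 3), c(2, 4)) # P(A > B) = 1/4 over the 4 pairs
  expect_identical(metabolite_auc(g2$values, g2$y, fold = FALSE), 0.25)
  expect_identical(metabolite_auc(g2$values, g2$y), 0.75)
  tied <- two_group(rep(1, 5), rep(1, 5))
  expect_identical(metabolite_auc(tied$values, tied$y), 0.5)
})

test_that("folded AUC agrees with pROC on random data", {
  set.seed(6)
  for (i in 1:5) {
    g <- two_group(rnorm(20, 0.5), rnorm(30))
    ours <- metabolite_auc(g$values, g$y)
    ref <- as.numeric(pROC::auc(pROC::roc(g$y, g$values, quiet = TRUE,
                                          direction = "auto")))
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("Mann-Whitney matches the exhaustive-enumeration oracle", {
  # printed case: {1,2,3} vs {4,5,6} -> U = 0, exact two-sided p = 2/20
  g <- two_group(c(1, 2, 3), c(4, 5, 6))
  mw <- mann_whitney_test(g$values, g$y)
  expect_identical(mw$U, 0)
  expect_equal(mw$p, 0.1, tolerance = 1e-12)
  expect_equal(mw_enum_p(c(1, 2, 3), c(4, 5, 6)), 0.1, tolerance = 1e-12)

  set.seed(8)
  for (n1 in 2:8) {
    for (rep in 1:2) {
      n2 <- sample(2:8, 1L)
      a <- rnorm(n1)
      b <- rnorm(n2, 0.8)
      g <- two_group(a, b)
      p <- mann_whitney_test(g$values, g$y)$p
      expect_lte(abs(p - mw_enum_p(a, b)), 0.02)
    }
  }
})

test_that("near-identical groups give p ~ 1 and significance respects Bonferroni", {
  # interleaved groups put U exactly at its null mean -> p = 1
  g <- two_group(c(1, 4, 5, 8), c(2, 3, 6, 7))
  mw <- mann_whitney_test(g$values, g$y)
  expect_identical(mw$p, 1)
  strong <- two_group(1:10, 21:30)
  expect_true(mann_whitney_test(strong$values, strong$y, n_tests = 1L)$significant)
  expect_false(mann_whitney_test(strong$values, strong$y,
                                 n_tests = 10000L)$significant)
})

test_that("delta_percent reproduces the exact arithmetic cases", {
  expect_identical(delta_percent(2, 1), 50)
  expect_identical(delta_percent(3, 3), 0)
  expect_identical(delta_percent(1, 2), -100)
  expect_error(delta_percent(0, 1), "mean_a = 0")
})

test_that("normalized MDG sums to one and respects exchangeability", {
  set.seed(10)
  n <- 100L
  y <- factor(rep(c("a", "b"), each = n / 2))
  single <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "only"))
  expect_identical(unname(gini_importance(single, y, n_trees = 50L)), 1)

  x <- matrix(rnorm(n * 40), n, 40, dimnames = list(NULL, paste0("f", 1:40)))
  mdg <- gini_importance(x, y, n_trees = 200L, seed = 1L)
  expect_equal(sum(mdg), 1, tolerance = 1e-12)
  expect_true(all(abs(mdg - 1 / 40) < 0.02)) # exchangeable noise features

  wins <- vapply(1:10, function(s) {
    xs <- cbind(sig = as.numeric(y == "a") + rnorm(n, sd = 0.2),
                matrix(rnorm(n * 9), n, 9,
                       dimnames = list(NULL, paste0("f", 1:9))))
    imp <- gini_importance(xs, y, n_trees = 100L, seed = s)
    names(which.max(imp)) == "sig"
  }, logical(1))
  expect_true(all(wins))
})

test_that("OOB score and error are complementary and calibrated", {
  set.seed(12)
  n <- 200L
  y <- factor(rep(c("a", "b"), each = n / 2))
  x <- cbind(label = as.numeric(y == "a"),
             matrix(rnorm(n * 5), n, 5,
                    dimnames = list(NULL, paste0("f", 1:5))))
  s <- oob_evaluate(x, y, n_trees = 200L, seed = 1L)
  expect_identical(s$oob_score + s$oob_error, 1)
  expect_lte(s$oob_error, 0.05)

  null_err <- vapply(1:5, function(k) {
    set.seed(k)
    yp <- factor(sample(as.character(y)))
    oob_evaluate(matrix(rnorm(n * 5), n, 5,
                        dimnames = list(NULL, paste0("f", 1:5))),
                 yp, n_trees = 100L, seed = k)$oob_error
  }, numeric(1))
  expect_true(all(null_err > 0.35 & null_err < 0.65))
})

test_that("PCA summary on rank-1 data and variance bookkeeping", {
  set.seed(14)
  u <- rnorm(50)
  rank1 <- outer(u, c(1, 2, 3))
  colnames(rank1) <- paste0("f", 1:3)
  p <- pca_summary(rank1)
  expect_equal(p$explained[1L], 1, tolerance = 1e-12)

  x <- matrix(rnorm(500 * 50), 500, 50,
              dimnames = list(NULL, paste0("f", 1:50)))
  p2 <- pca_summary(x)
  expect_equal(sum(p2$explained), 1, tolerance = 1e-12)
  expect_gte(p2$explained[1L], 1.5 / 50)
  expect_lte(p2$explained[1L], 4 / 50)
  expect_lt(max(abs(crossprod(p2$scores[, 1L], p2$scores[, 2L]))), 1e-8)
  expect_error(pca_summary(x[, 1, drop = FALSE]), "2 features")
})

test_that("folded AUC increases with the Mann-Whitney U deviation", {
  set.seed(16)
  n1 <- 15L; n2 <- 25L
  y <- factor(rep(c("a", "b"), c(n1, n2)))
  stats <- t(vapply(1:30, function(i) {
    v <- c(rnorm(n1, runif(1, 0, 2)), rnorm(n2))
    u <- sum(rank(v)[1:n1]) - n1 * (n1 + 1) / 2
    c(dev = abs(u - n1 * n2 / 2), auc = metabolite_auc(v, y))
  }, numeric(2)))
  expect_identical(order(stats[, "dev"]), order(stats[, "auc"]))
})

test_that("scorecards aggregate across imputed datasets with OOB attribute", {
  fix <- tiny_complete(seed = 44)
  coll <- as_collection(list(seed1_imp1 = fix$matrix,
                             seed1_imp2 = fix$matrix))
  ids <- colnames(fix$matrix)[1:6]
  card <- score_metabolites(coll, fix$metadata, ids,
                            core_ids = ids[1:2], n_trees = 100L, seed = 3L)
  expect_setequal(card$metabolite_id, ids)
  expect_equal(sum(card$mdg), 1, tolerance = 1e-6)
  expect_true(all(card$auc >= 0.5 & card$auc <= 1))
  expect_identical(sum(card$core), 2L)
  expect_identical(card$rank, seq_len(nrow(card)))
  # direction consistent with the sign of delta_pct
  expect_identical(card$direction == "castrated_male", card$delta_pct >= 0)
  oob <- attr(card, "oob")
  expect_identical(nrow(oob), 2L)
  expect_equal(oob$oob_score + oob$oob_error, rep(1, 2L))
})
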