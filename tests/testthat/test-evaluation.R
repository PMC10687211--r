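# Brute-force oracles, kept deliberately naive and independent of the
# implementation under test.

aurocOracle <- function(scores, labels) {
  ps <- scores[labels == 1]; ns <- scores[labels == 0]
  tot <- 0
  for (p in ps) for (q in ns)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(ps) * length(ns))
}

auprcOracle <- function(scores, labels) {
  ord <- order(-scores)          # stable walk down the ranked list
  y <- labels[ord]
  tp <- 0; s <- 0
  for (i in seq_along(y)) {
    if (y[i] == 1) { tp <- tp + 1; s <- s + tp / i }
  }
  s / sum(labels == 1)
}

ppvOracle <- function(scores, labels, k) {
  m <- ceiling(k * length(scores))
  sel <- order(-scores)[seq_len(m)]
  c(ppv = sum(labels[sel]) / m, sens = sum(labels[sel]) / sum(labels))
}

test_that("auroc/auprc/ppv match their brute-force oracles on randomized instances", {
  set.seed(20)
  for (r in 1:60) {
    n <- sample(10:200, 1)
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # induce ties sometimes
    labels <- rbinom(n, 1, runif(1, 0.1, 0.9))
    if (length(unique(labels)) < 2) next
    expect_equal(auroc(scores, labels), aurocOracle(scores, labels))
    expect_equal(auprc(scores, labels), auprcOracle(scores, labels))
    k <- runif(1, 0.05, 1)
    got <- ppvAtTopFraction(scores, labels, k)
    want <- ppvOracle(scores, labels, k)
    expect_equal(got$ppv, unname(want["ppv"]))
    expect_equal(got$sensitivity, unname(want["sens"]))
  }
})

test_that("auroc agrees with an independent rank-based implementation", {
  skip_if_not_installed("pROC")
  set.seed(3)
  scores <- runif(300)
  labels <- rbinom(300, 1, 0.3)
  expect_equal(auroc(scores, labels),
               as.numeric(pROC::auc(pROC::roc(labels, scores,
                                              quiet = TRUE,
                                              direction = "<"))))
})

test_that("metric edge cases behave as defined", {
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)   # separation
  expect_equal(auprc(c(0.9, 0.8, 0.2), c(1, 1, 0)), 1)           # perfect rank
  expect_error(auroc(c(0.1, 0.2), c(1, 1)), "both classes")
  expect_error(auprc(c(0.1, 0.2), c(0, 0)), "positive")
  # null behaviour
  set.seed(4)
  s <- runif(500); y <- rbinom(500, 1, 0.3)
  expect_lt(abs(auroc(s, y) - 0.5), 0.1)
  expect_lt(abs(auprc(s, y) - mean(y)), 0.1)
  # full-cohort threshold: ppv = prevalence, sensitivity = 1
  r <- ppvAtTopFraction(s, y, 1)
  expect_equal(r$ppv, mean(y))
  expect_equal(r$sensitivity, 1)
  # 10 individuals, top-10% = 1 individual, that one positive -> PPV 1
  r2 <- ppvAtTopFraction(c(0.99, runif(9, 0, 0.5)), c(1, rep(0, 9)), 0.1)
  expect_equal(r2$ppv, 1)
  expect_equal(r2$nSelected, 1L)
})

test_that("ranking metrics are invariant under strictly monotone score transforms", {
  set.seed(11)
  trans <- list(function(x) 3 * x + 1, function(x) x^3,
                function(x) exp(2 * x), function(x) atan(x) + 5)
  for (r in 1:10) {
    n <- sample(30:150, 1)
    s <- runif(n); y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    f <- trans[[sample(length(trans), 1)]]
    expect_equal(auroc(f(s), y), auroc(s, y))
    expect_equal(auprc(f(s), y), auprc(s, y))
    expect_equal(ppvAtTopFraction(f(s), y, 0.2)$ppv,
                 ppvAtTopFraction(s, y, 0.2)$ppv)
  }
})

test_that("thresholdSweep reproduces pointwise ppvAtTopFraction", {
  set.seed(6)
  s <- runif(200); y <- rbinom(200, 1, 0.2)
  tab <- thresholdSweep(s, y)
  expect_equal(tab$k, seq(0.1, 0.6, by = 0.1))
  for (i in seq_len(nrow(tab)))
    expect_equal(tab$ppv[i], ppvAtTopFraction(s, y, tab$k[i])$ppv)
})

test_that("bootstrap metric reports are seeded, ordered and cover the estimate", {
  set.seed(8)
  s <- c(runif(150, 0.3, 1), runif(150, 0, 0.7))
  y <- rep(c(1, 0), each = 150)
  a <- metricReport(s, y, "auroc", nBoot = 200L, seed = 33L)
  b <- metricReport(s, y, "auroc", nBoot = 200L, seed = 33L)
  expect_identical(a, b)
  expect_lte(a$lower, a$estimate)
  expect_gte(a$upper, a$estimate)
})

test_that("new-vs-recurrent stratification follows the context-history definition", {
  ctx <- list(c("A", "B"), c("B"), c("A"), c("C"), c("A", "C"), c("B", "C"))
  scores <- c(0.9, 0.2, 0.8, 0.3, 0.1, 0.6)
  labels <- c(1, 0, 1, 0, 0, 1)
  out <- stratifyNewRecurrent(ctx, scores, labels, "A")
  expect_equal(out$n[out$stratum == "R"], 3L)   # contexts 1, 3, 5
  expect_equal(out$n[out$stratum == "0"], 3L)
  expect_true(all(out$evaluable))
  # empty stratum is not-evaluable, not an error
  out2 <- stratifyNewRecurrent(list("A", c("A", "B")), c(0.5, 0.6), c(1, 0),
                               "A")
  expect_false(out2$evaluable[out2$stratum == "0"])
  expect_true(is.na(out2$auroc[out2$stratum == "0"]))
})

test_that("subgroup reports are invariant to relabeling and deterministic", {
  set.seed(10)
  s <- runif(120); y <- rbinom(120, 1, 0.4)
  g <- rep(c("g1", "g2"), each = 60)
  # identical score/label multisets in both groups -> identical estimates
  s2 <- c(s[1:60], s[1:60]); y2 <- c(y[1:60], y[1:60])
  r <- subgroupReport(s2, y2, g, nBoot = 100L, seed = 2L)
  expect_equal(r$table$auroc[1], r$table$auroc[2])
  expect_equal(r$table$auprc[1], r$table$auprc[2])
  r2 <- subgroupReport(s2, y2, g, nBoot = 100L, seed = 2L)
  expect_identical(r, r2)
  # exchangeable labels across groups: group estimate within full-cohort CI
  full <- metricReport(s, y, "auroc", nBoot = 300L, seed = 5L)
  r3 <- subgroupReport(s, y, g, nBoot = 100L, seed = 3L)
  for (i in which(r3$table$evaluable))
    expect_true(r3$table$auroc[i] >= full$lower - 0.1 &&
                r3$table$auroc[i] <= full$upper + 0.1)
  # tiny single-class group marked not-evaluable
  r4 <- subgroupReport(c(s, 0.5, 0.6), c(y, 1, 1),
                       c(g, "tiny", "tiny"), nBoot = 50L, seed = 1L)
  expect_false(r4$table$evaluable[r4$table$group == "tiny"])
})

test_that("one-sided t-test handles closed-form and degenerate cases", {
  # hand-checkable: {0.8,0.8,0.8} vs {0.6,0.6,0.6} favors arm 1 decisively
  r <- oneSidedT(c(0.8, 0.8, 0.8), c(0.6, 0.6, 0.6))
  expect_lt(r$p, 0.01)
  # identical arms: symmetric null
  expect_equal(oneSidedT(c(0.7, 0.7), c(0.7, 0.7))$p, 0.5)
  # against stats::t.test on non-degenerate data
  set.seed(12)
  x <- rnorm(8, 0.75, 0.05); y <- rnorm(8, 0.7, 0.05)
  want <- t.test(x, y, alternative = "greater")
  got <- oneSidedT(x, y)
  expect_equal(got$p, want$p.value)
  expect_equal(got$t, unname(want$statistic))
})
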