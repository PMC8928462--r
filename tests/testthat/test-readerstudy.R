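test_that("confusion metrics reproduce a published operating point", {
  # 123 positives with TP=102, 347 negatives with TN=292
  truth <- rep(c(TRUE, FALSE), c(123, 347))
  call <- c(rep(TRUE, 102), rep(FALSE, 21), rep(TRUE, 55), rep(FALSE, 292))
  s <- confusionMetrics(decisionSet(call, truth))
  expect_equal(roundHalfUp(s@sensitivity, 2), 82.93)
  expect_equal(roundHalfUp(s@specificity, 2), 84.15)
  expect_equal(roundHalfUp(s@accuracy, 2), 83.83)
  expect_equal(roundHalfUp(s@auc, 3), 0.835)
  expect_equal(s@tp + s@fn, s@nPos)
  expect_equal(s@tn + s@fp, s@nNeg)
})

test_that("confusion metrics handle perfect and all-positive callers", {
  truth <- rep(c(TRUE, FALSE), c(5, 7))
  perfect <- confusionMetrics(decisionSet(truth, truth))
  expect_equal(c(perfect@sensitivity, perfect@specificity,
                 perfect@accuracy), c(100, 100, 100))
  allpos <- confusionMetrics(decisionSet(rep(TRUE, 12), truth))
  expect_equal(c(allpos@sensitivity, allpos@specificity), c(100, 0))
  expect_error(confusionMetrics(decisionSet(truth, rep(TRUE, 12))),
               class = "undefinedMetricError")
})

test_that("single-point AUC is the two-segment trapezoid", {
  expect_equal(roundHalfUp(aucSinglePoint(77.24, 79.54), 3), 0.784)
  expect_equal(aucSinglePoint(100, 100), 1.0)
  expect_equal(aucSinglePoint(50, 50), 0.5)
  expect_error(aucSinglePoint(101, 50), "0, 100")
})

test_that("score AUC equals the all-pairs concordance count", {
  expect_equal(aucFromScores(c(0.9, 0.4, 0.6, 0.1),
                             c(TRUE, TRUE, FALSE, FALSE))$auc, 0.75)
  expect_equal(aucFromScores(c(3, 2, 1, 0),
                             c(TRUE, TRUE, FALSE, FALSE))$auc, 1.0)
  set.seed(21)
  for (rep in 1:30) {
    n <- sample(6:30, 1)
    pos <- sample(c(TRUE, FALSE), n, TRUE)
    if (!any(pos) || all(pos)) next
    s <- sample(seq_len(8), n, TRUE) / 2  # ties on purpose
    expect_equal(aucFromScores(s, pos)$auc, bruteAUC(s, pos),
                 tolerance = 1e-12)
  }
  expect_error(aucFromScores(1:4, rep(TRUE, 4)),
               class = "undefinedMetricError")
})

test_that("DeLong interval brackets the point estimate and covers truth", {
  set.seed(9)
  a <- aucFromScores(rnorm(40, rep(c(1, 0), each = 20)),
                     rep(c(TRUE, FALSE), each = 20))
  expect_true(a$ci[1] <= a$auc && a$auc <= a$ci[2])
  # binormal model with true AUC = pnorm(1/sqrt(2))
  trueAUC <- pnorm(1 / sqrt(2))
  hits <- replicate(500, {
    sc <- c(rnorm(50, 1), rnorm(50, 0))
    ci <- aucFromScores(sc, rep(c(TRUE, FALSE), each = 50))$ci
    ci[1] <= trueAUC && trueAUC <= ci[2]
  })
  expect_gt(mean(hits), 0.90)
  expect_lt(mean(hits), 0.99)
})

test_that("OR-fusion follows the rule table and dominance bounds", {
  truth <- c(TRUE, TRUE, FALSE, FALSE)
  reader <- decisionSet(c(FALSE, TRUE, FALSE, TRUE), truth)
  cad <- decisionSet(c(TRUE, FALSE, FALSE, FALSE), truth)
  fused <- fuseOr(reader, cad)
  expect_equal(fused$positive, c(TRUE, TRUE, FALSE, TRUE))
  # all-negative CAD is the identity element
  none <- decisionSet(rep(FALSE, 4), truth)
  expect_equal(fuseOr(reader, none)$positive, reader$positive)
  # dominance on random pairs
  set.seed(4)
  for (rep in 1:50) {
    tr <- sample(c(TRUE, FALSE), 30, TRUE, prob = c(0.3, 0.7))
    if (!any(tr) || all(tr)) next
    a <- decisionSet(sample(c(TRUE, FALSE), 30, TRUE), tr)
    b <- decisionSet(sample(c(TRUE, FALSE), 30, TRUE), tr)
    f <- confusionMetrics(fuseOr(a, b))
    ma <- confusionMetrics(a); mb <- confusionMetrics(b)
    expect_gte(f@sensitivity, max(ma@sensitivity, mb@sensitivity))
    expect_lte(f@specificity, min(ma@specificity, mb@specificity))
  }
  mismatch <- decisionSet(c(TRUE, FALSE), c(TRUE, FALSE))
  expect_error(fuseOr(reader, mismatch), class = "caseSetMismatchError")
})

test_that("proportion comparison matches the closed-form chi-square", {
  truth <- rep(TRUE, 100)  # sensitivity table on 100 positive cases
  a <- decisionSet(rep(c(TRUE, FALSE), c(90, 10)), truth)
  b <- decisionSet(rep(c(TRUE, FALSE), c(50, 50)), truth)
  # truth has no negatives, so compare via accuracy on an all-positive set
  h <- compareProportions(a, b, "sensitivity")
  O <- matrix(c(90, 10, 50, 50), 2, byrow = TRUE)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  expect_equal(h$statistic, sum((O - E)^2 / E), tolerance = 1e-6)
  expect_lt(h$p.value, 0.05)
  same <- compareProportions(a, a, "sensitivity")
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  mc <- compareProportions(a, b, "sensitivity", method = "mcnemar")
  expect_true(is.finite(mc$statistic))
  perfect <- decisionSet(truth, truth)
  expect_error(compareProportions(perfect, perfect, "sensitivity"),
               class = "zeroMarginError")
})

test_that("subtype summaries partition the cohort and flag degenerates", {
  set.seed(14)
  n <- 120
  subtype <- sample(c("LuminalA", "LuminalB", "HER2+", "TN"), n, TRUE)
  truth <- sample(c(TRUE, FALSE), n, TRUE, prob = c(0.3, 0.7))
  truth[subtype == "HER2+"] <- FALSE  # degenerate subgroup
  d <- decisionSet(sample(c(TRUE, FALSE), n, TRUE), truth,
                   subtype = subtype)
  out <- subgroupSummary(d)
  expect_true("HER2+" %in% attr(out, "flagged"))
  expect_false("HER2+" %in% names(out))
  expect_false("other" %in% names(out))
  tpSum <- sum(vapply(out, function(s) s@tp, 0L))
  keep <- d$subtype %in% names(out)
  expect_equal(tpSum, sum(d$positive[keep] & d$truthPositive[keep]))
})

test_that("count reconstruction reproduces rates it was given", {
  r <- reconstructCounts(87.80, 88.18, 123, 347)
  expect_equal(r$tp, 108L); expect_equal(r$tn, 306L)
  expect_equal(roundHalfUp(r$accuracy, 2), 88.09)
  r2 <- reconstructCounts(88.62, 89.04, 123, 347)
  expect_equal(roundHalfUp(r2$accuracy, 2), 88.94)
  expect_equal(reconstructCounts(100, 100, 9, 11)$accuracy, 100)
  expect_equal(reconstructCounts(100, 100, 9, 11)$auc, 1.0)
  # round trip: rates printed from integer counts reconstruct those counts
  set.seed(6)
  for (rep in 1:25) {
    nPos <- sample(20:200, 1); nNeg <- sample(20:400, 1)
    tp <- sample.int(nPos, 1); tn <- sample.int(nNeg, 1)
    se <- roundHalfUp(100 * tp / nPos, 2)
    sp <- roundHalfUp(100 * tn / nNeg, 2)
    r <- reconstructCounts(se, sp, nPos, nNeg)
    expect_equal(r$tp, tp)
    expect_equal(r$tn, tn)
    expect_equal(roundHalfUp(r$accuracy, 2),
                 roundHalfUp(100 * (tp + tn) / (nPos + nNeg), 2))
  }
})

test_that("simulated readers hit their operating point at large n", {
  truth <- rep(c(TRUE, FALSE), c(2000, 6000))
  d <- simulateReader(truth, 80, 90, seed = 3L)
  m <- confusionMetrics(d)
  expect_lt(abs(m@sensitivity - 80), 3)
  expect_lt(abs(m@specificity - 90), 2)
  expect_identical(simulateReader(truth, 80, 90, seed = 3L)$positive,
                   d$positive)
})
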