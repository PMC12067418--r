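test_that("ROC AUC equals concordant-pair counting on canonical cases", {
  expect_equal(rocAuc(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(rocAuc(rep(0.5, 6), c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE)),
               0.5)
  expect_equal(rocAuc(c(0.8, 0.3, 0.6, 0.2, 0.1),
                      c(TRUE, TRUE, FALSE, FALSE, FALSE)), 5 / 6)
  expect_error(rocAuc(1:3, c(TRUE, TRUE, TRUE)), "at least one")
})

test_that("ROC AUC matches the brute-force oracle on random small cases", {
  set.seed(31)
  for (i in 1:300) {
    n <- sample(4:12, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE) # forces ties
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (all(labels) || !any(labels)) next
    expect_equal(rocAuc(scores, labels), bruteAuc(scores, labels))
  }
})

test_that("ROC AUC agrees with an independent ROC implementation", {
  set.seed(36)
  for (i in 1:10) {
    scores <- runif(30)
    labels <- sample(c(TRUE, FALSE), 30, replace = TRUE, prob = c(0.3, 0.7))
    if (all(labels) || !any(labels)) next
    ref <- suppressMessages(pROC::auc(pROC::roc(labels, scores,
                                                direction = "<",
                                                quiet = TRUE)))
    expect_equal(rocAuc(scores, labels), as.numeric(ref), tolerance = 1e-12)
  }
})

test_that("AUC complements under score reflection for tie-free scores", {
  set.seed(32)
  for (i in 1:20) {
    scores <- runif(15)
    labels <- c(rep(TRUE, 5), rep(FALSE, 10))
    expect_equal(rocAuc(scores, labels) + rocAuc(1 - scores, labels), 1)
  }
})

test_that("seizure AUC pools channel medians across windows", {
  vals <- rbind(c(0.9, 0.1, 0.2), c(0.8, 0.3, 0.1), c(0.7, 0.2, 0.4))
  fl <- new("FlowSeries", method = "pdc", measure = "inflow",
            period = "preictal", values = vals,
            channelLabels = c("a", "b", "c"),
            sozMask = c(TRUE, FALSE, FALSE))
  expect_equal(seizureAuc(fl), rocAuc(apply(vals, 2, median),
                                      c(TRUE, FALSE, FALSE)))
  one <- new("FlowSeries", method = "pdc", measure = "inflow",
             period = "preictal", values = vals[1, , drop = FALSE],
             channelLabels = c("a", "b", "c"),
             sozMask = c(TRUE, FALSE, FALSE))
  expect_equal(seizureAuc(one), rocAuc(vals[1, ], c(TRUE, FALSE, FALSE)))
})

test_that("rank-sum exact branch reproduces enumeration and known values", {
  expect_equal(wilcoxonRanksum(c(1, 2, 3), c(4, 5, 6))$p, 0.1)
  expect_equal(wilcoxonRanksum(c(1, 2, 3), c(1, 2, 3))$p, 1)

  set.seed(33)
  for (i in 1:25) {
    nx <- sample(3:6, 1); ny <- sample(3:6, 1)
    x <- round(runif(nx), 2); y <- round(runif(ny), 2)
    mine <- wilcoxonRanksum(x, y)
    expect_equal(mine$p, enumRanksumP(x, y), tolerance = 1e-12)
    if (!any(duplicated(c(x, y)))) {
      ref <- wilcox.test(x, y, exact = TRUE)
      expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
      expect_equal(mine$statistic, unname(ref$statistic))
    }
  }
})

test_that("rank-sum normal approximation tracks the exact distribution", {
  set.seed(34)
  diffs <- vapply(1:20, function(i) {
    x <- rnorm(10); y <- rnorm(10) # pooled n = 20 -> approximation branch
    pApprox <- wilcoxonRanksum(x, y)$p
    pExact <- wilcox.test(x, y, exact = TRUE)$p.value
    abs(pApprox - pExact)
  }, 0)
  expect_lt(max(diffs), 0.02)
})

test_that("KS normality check behaves on normal and uniform samples", {
  pn <- vapply(1:20, function(s) { set.seed(1100 + s)
    ksNormality(rnorm(500))$p }, 0)
  expect_gte(mean(pn > 0.05), 18 / 20)
  pu <- vapply(1:20, function(s) { set.seed(1200 + s)
    ksNormality(runif(500))$p }, 0)
  expect_gte(mean(pu < 0.05), 18 / 20)
  st <- ksNormality(rnorm(50))$statistic
  expect_true(st >= 0 && st <= 1)
  expect_error(ksNormality(1:4), "at least 5")
})

test_that("effect size follows the pooled-SD definition", {
  set.seed(35)
  x <- rnorm(5000); y <- rnorm(5000)
  expect_equal(cohensD(x, y), 0, tolerance = 0.1)
  expect_equal(cohensD(y + 1, y), 1, tolerance = 0.05)
  expect_equal(cohensD(x, y), -cohensD(y, x))
  expect_error(cohensD(c(1, 1, 1), c(1, 1)), "pooled")
})

test_that("Bonferroni adjustment multiplies and clips", {
  expect_equal(bonferroni(c(0.01, 0.04), m = 2), c(0.02, 0.08))
  expect_equal(bonferroni(0.9, m = 5), 1)
  expect_equal(bonferroni(c(0.2, 0.7), m = 1), c(0.2, 0.7))
  expect_equal(bonferroni(c(0.01, 0.02, 0.03)),
               p.adjust(c(0.01, 0.02, 0.03), "bonferroni"))
  expect_error(bonferroni(1.2), "0, 1")
})

mkFlow <- function(vals, soz, method, measure) {
  new("FlowSeries", method = method, measure = measure, period = "preictal",
      values = vals, channelLabels = sprintf("c%d", seq_len(ncol(vals))),
      sozMask = soz)
}

test_that("classification requires exclusive, both-method significance", {
  soz <- c(TRUE, TRUE, rep(FALSE, 8))
  hi <- cbind(matrix(0.9, 7, 2), matrix(seq(0, 0.6, length.out = 56), 7, 8))
  lo <- cbind(matrix(0.05, 7, 2), matrix(seq(0.2, 0.9, length.out = 56), 7, 8))
  flowsIn <- list(mkFlow(hi, soz, "pdc", "inflow"),
                  mkFlow(hi, soz, "dtf", "inflow"),
                  mkFlow(lo, soz, "pdc", "outflow"),
                  mkFlow(lo, soz, "dtf", "outflow"))
  expect_equal(classifyRecording(flowsIn)$label, "inflow_dominant")

  flowsOut <- list(mkFlow(lo, soz, "pdc", "inflow"),
                   mkFlow(lo, soz, "dtf", "inflow"),
                   mkFlow(hi, soz, "pdc", "outflow"),
                   mkFlow(hi, soz, "dtf", "outflow"))
  expect_equal(classifyRecording(flowsOut)$label, "outflow_dominant")

  # SOZ significantly higher in BOTH measures -> the exclusion clause fires
  flowsBoth <- list(mkFlow(hi, soz, "pdc", "inflow"),
                    mkFlow(hi, soz, "dtf", "inflow"),
                    mkFlow(hi, soz, "pdc", "outflow"),
                    mkFlow(hi, soz, "dtf", "outflow"))
  expect_equal(classifyRecording(flowsBoth)$label, "unclassified")

  expect_error(classifyRecording(flowsIn[1:3]), "missing")
})

test_that("classification is conservative on exchangeable null flows", {
  hits <- 0L
  for (s in 1:40) {
    set.seed(1300 + s)
    soz <- sample(c(TRUE, TRUE, rep(FALSE, 8)))
    flows <- list(
      mkFlow(matrix(runif(70), 7, 10), soz, "pdc", "inflow"),
      mkFlow(matrix(runif(70), 7, 10), soz, "dtf", "inflow"),
      mkFlow(matrix(runif(70), 7, 10), soz, "pdc", "outflow"),
      mkFlow(matrix(runif(70), 7, 10), soz, "dtf", "outflow"))
    if (classifyRecording(flows)$label != "unclassified") hits <- hits + 1L
  }
  expect_lte(hits / 40, 2 * 0.05)
})

test_that("cohort summaries aggregate and stratify correctly", {
  mkRes <- function(auc, group, implant) {
    new("EvaluationResult",
        aucTable = data.frame(patient = "p", seizure = "s", method = "pdc",
                              measure = "inflow", period = "preictal",
                              auc = auc),
        groupLabel = group, tests = data.frame(),
        meta = list(implant_type = implant))
  }
  one <- summarizeCohort(list(mkRes(0.7, "inflow_dominant", "seeg")))
  expect_equal(one$summary$median, 0.7)
  expect_equal(one$summary$q3 - one$summary$q1, 0)

  res <- c(lapply(c(0.6, 0.7, 0.65), mkRes, group = "inflow_dominant",
                  implant = "seeg"),
           lapply(c(0.55, 0.5, 0.62), mkRes, group = "inflow_dominant",
                  implant = "ecog"))
  strat <- summarizeCohort(res, stratifyBy = "implant_type")
  expect_equal(nrow(strat$summary), 2)
  expect_true(all(c("stratum_a", "stratum_b", "p_adjusted") %in%
                    names(strat$tests)))
  expect_error(summarizeCohort(res, stratifyBy = "no_such_key"),
               "missing")
})
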