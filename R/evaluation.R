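#' Area under the ROC curve
#'
#' Trapezoidal area under the TPR-vs-FPR curve over the full threshold range,
#' computed in closed form as the Mann-Whitney U statistic with half-credit
#' for ties, divided by n_pos * n_neg: the probability that a randomly chosen
#' positive-class score outranks a randomly chosen negative-class score.
#'
#' @param scores numeric vector of channel scores (any scale; only ranks
#'   matter).
#' @param labels logical vector, TRUE for the positive (SOZ) class.
#' @return AUC in [0, 1].
#' @examples
#' rocAuc(c(0.8, 0.3, 0.6, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE, FALSE))
#' @export
rocAuc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length")
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L)
    stop("labels must contain at least one positive and one negative")
  r <- rank(scores) # midranks give ties half credit
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' SOZ-discrimination AUC for one seizure
#'
#' Each channel is scored by the median of its normalized per-window flow
#' values (a robust segment-to-channel pooling), then scored channels are
#' ranked against the SOZ annotation.
#'
#' @param flow a [FlowSeries-class].
#' @return AUC in [0, 1].
#' @export
seizureAuc <- function(flow) {
  stopifnot(is(flow, "FlowSeries"))
  scores <- apply(flow@values, 2, stats::median)
  rocAuc(scores, flow@sozMask)
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact permutation enumeration when the pooled sample size is at most 12
#' (ties included); otherwise the tie-corrected normal approximation with
#' continuity correction. The statistic reported is the Mann-Whitney U of the
#' first sample.
#'
#' @param x,y numeric samples to compare.
#' @param alternative `"two.sided"` (default) or `"greater"` (x tends larger
#'   than y).
#' @return list with `statistic` (U) and `p`.
#' @examples
#' wilcoxonRanksum(c(1, 2, 3), c(4, 5, 6))$p # exact: 0.1
#' @export
wilcoxonRanksum <- function(x, y, alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  if (!length(x) || !length(y)) stop("both samples must be nonempty")
  n1 <- length(x)
  n2 <- length(y)
  N <- n1 + n2
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  U <- W - n1 * (n1 + 1) / 2
  if (N <= 12) {
    # full enumeration of the C(N, n1) equally likely rank assignments
    sums <- combn(N, n1, FUN = function(idx) sum(r[idx]))
    pGE <- mean(sums >= W - 1e-9)
    pLE <- mean(sums <= W + 1e-9)
    p <- switch(alternative,
                two.sided = min(1, 2 * min(pGE, pLE)),
                greater = pGE)
  } else {
    mu <- n1 * n2 / 2
    tie <- table(r)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(tie^3 - tie) / (N * (N - 1)))
    if (sigma2 <= 0) return(list(statistic = U, p = 1))
    # continuity-corrected z, as in the standard large-sample treatment
    z <- switch(alternative,
                two.sided = (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2),
                greater = (U - mu - 0.5) / sqrt(sigma2))
    p <- switch(alternative,
                two.sided = 2 * stats::pnorm(-abs(z)),
                greater = stats::pnorm(z, lower.tail = FALSE))
  }
  list(statistic = unname(U), p = min(1, p))
}

#' Kolmogorov-Smirnov normality check
#'
#' One-sample KS statistic of `x` against a normal with the sample mean and
#' standard deviation, with the asymptotic KS p-value. Used as a gate before
#' choosing non-parametric comparisons.
#'
#' @param x numeric sample, n >= 5.
#' @return list with `statistic` and `p`.
#' @export
ksNormality <- function(x) {
  if (length(x) < 5) stop("need at least 5 observations")
  res <- suppressWarnings(
    stats::ks.test(x, "pnorm", mean = mean(x), sd = stats::sd(x)))
  list(statistic = unname(res$statistic), p = res$p.value)
}

#' Cohen's d effect size
#'
#' `(mean(x) - mean(y)) / s_pooled` with the pooled standard deviation
#' `sqrt(((n_x - 1) s_x^2 + (n_y - 1) s_y^2) / (n_x + n_y - 2))`.
#'
#' @param x,y numeric samples (each n >= 2).
#' @return Cohen's d (signed).
#' @export
cohensD <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) stop("need at least 2 observations per sample")
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  if (sp2 <= 0) stop("zero pooled standard deviation")
  (mean(x) - mean(y)) / sqrt(sp2)
}

#' Bonferroni correction
#'
#' @param pValues numeric vector of raw p-values in [0, 1].
#' @param m family size (defaults to `length(pValues)`).
#' @return adjusted p-values, `pmin(1, p * m)`.
#' @export
bonferroni <- function(pValues, m = length(pValues)) {
  if (any(pValues < 0 | pValues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  pmin(1, pValues * m)
}

#' Classify a recording as inflow- or outflow-dominant
#'
#' Pools the normalized per-window flow values of SOZ vs non-SOZ channels
#' across the preictal windows and tests SOZ > non-SOZ by one-sided Wilcoxon
#' rank-sum, separately for each method (PDC, DTF) and measure (inflow,
#' outflow); the four p-values form one Bonferroni family. A recording is
#' `inflow_dominant` when SOZ inflow is significantly higher under BOTH
#' methods while the same is not true of outflow; `outflow_dominant` is
#' symmetric; anything else (including both or neither measure significant)
#' is `unclassified`.
#'
#' @param flows list of four preictal [FlowSeries-class] objects covering
#'   methods pdc/dtf x measures inflow/outflow (any order; matched by slots).
#' @param alpha significance level applied to the adjusted p-values
#'   (default 0.05).
#' @return list with `label` and `tests` (data.frame: name, statistic, p_raw,
#'   p_adjusted, effect_size_d).
#' @export
classifyRecording <- function(flows, alpha = 0.05) {
  stopifnot(all(vapply(flows, is, TRUE, "FlowSeries")))
  key <- vapply(flows, function(f) paste(f@method, f@measure, sep = "_"), "")
  names(flows) <- key
  wanted <- c("pdc_inflow", "dtf_inflow", "pdc_outflow", "dtf_outflow")
  if (!all(wanted %in% key))
    stop("need preictal flow series for both methods x both measures; missing: ",
         paste(setdiff(wanted, key), collapse = ", "))
  soz <- flows[[wanted[1]]]@sozMask
  if (!any(soz) || all(soz))
    stop("sozMask must contain at least one SOZ and one non-SOZ channel")
  rows <- lapply(wanted, function(k) {
    v <- flows[[k]]@values
    xs <- as.vector(v[, soz, drop = FALSE])
    ys <- as.vector(v[, !soz, drop = FALSE])
    wt <- wilcoxonRanksum(xs, ys, alternative = "greater")
    data.frame(name = k, statistic = wt$statistic, p_raw = wt$p,
               effect_size_d = cohensD(xs, ys), stringsAsFactors = FALSE)
  })
  tests <- do.call(rbind, rows)
  tests$p_adjusted <- bonferroni(tests$p_raw, m = nrow(tests))
  tests <- tests[, c("name", "statistic", "p_raw", "p_adjusted",
                     "effect_size_d")]
  sig <- stats::setNames(tests$p_adjusted < alpha, tests$name)
  inflowSig <- sig[["pdc_inflow"]] && sig[["dtf_inflow"]]
  outflowSig <- sig[["pdc_outflow"]] && sig[["dtf_outflow"]]
  label <- if (inflowSig && !outflowSig) "inflow_dominant"
           else if (outflowSig && !inflowSig) "outflow_dominant"
           else "unclassified"
  list(label = label, tests = tests)
}

#' Summarize SOZ-discrimination performance over a cohort
#'
#' Median and IQR of the per-seizure AUCs for every (method, measure, period,
#' group) cell, optionally split by a metadata stratum (e.g., implant type),
#' with Bonferroni-adjusted pairwise Wilcoxon rank-sum comparisons between
#' strata.
#'
#' @param results list of [EvaluationResult-class] objects.
#' @param stratifyBy optional name of a metadata key present in every
#'   result's `meta`.
#' @return list with `summary` (data.frame of median/IQR per cell) and
#'   `tests` (pairwise stratum comparisons; NULL without stratification).
#' @export
summarizeCohort <- function(results, stratifyBy = NULL) {
  stopifnot(length(results) >= 1,
            all(vapply(results, is, TRUE, "EvaluationResult")))
  tabs <- lapply(results, function(r) {
    tb <- r@aucTable
    tb$group <- r@groupLabel
    if (!is.null(stratifyBy)) {
      if (is.null(r@meta[[stratifyBy]]))
        stop(sprintf("metadata key '%s' missing from a result", stratifyBy))
      tb$stratum <- as.character(r@meta[[stratifyBy]])
    }
    tb
  })
  auc <- do.call(rbind, tabs)
  byCols <- c("method", "measure", "period", "group",
              if (!is.null(stratifyBy)) "stratum")
  agg <- stats::aggregate(
    auc$auc, by = auc[byCols],
    FUN = function(v) c(median = stats::median(v),
                        q1 = unname(stats::quantile(v, 0.25)),
                        q3 = unname(stats::quantile(v, 0.75)),
                        n = length(v)))
  summary <- cbind(agg[byCols], as.data.frame(agg$x))
  tests <- NULL
  if (!is.null(stratifyBy)) {
    strata <- unique(auc$stratum)
    if (length(strata) >= 2) {
      cells <- unique(auc[c("method", "measure", "period")])
      rows <- list()
      for (ci in seq_len(nrow(cells))) {
        sub <- merge(auc, cells[ci, , drop = FALSE])
        pairs <- utils::combn(sort(strata), 2, simplify = FALSE)
        for (pr in pairs) {
          a <- sub$auc[sub$stratum == pr[1]]
          b <- sub$auc[sub$stratum == pr[2]]
          if (length(a) && length(b)) {
            wt <- wilcoxonRanksum(a, b)
            rows[[length(rows) + 1L]] <- data.frame(
              cells[ci, , drop = FALSE],
              stratum_a = pr[1], stratum_b = pr[2],
              statistic = wt$statistic, p_raw = wt$p,
              stringsAsFactors = FALSE)
          }
        }
      }
      if (length(rows)) {
        tests <- do.call(rbind, rows)
        tests$p_adjusted <- bonferroni(tests$p_raw)
      }
    }
  }
  list(summary = summary, tests = tests, aucLong = auc)
}
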