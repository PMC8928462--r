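#' Construct a decision set
#'
#' A decision set holds one diagnostic method's per-case binary pCR calls,
#' the truth labels, and optionally a continuous score (CAD) and molecular
#' subtype per case.
#'
#' @param call character/logical, the method's calls ("pCR"/"non-pCR" or
#'   TRUE for positive).
#' @param truth character/logical truth labels, same convention.
#' @param score optional numeric score (higher = more pCR-like).
#' @param subtype optional character molecular subtype per case.
#' @param caseId optional case identifiers (defaults to row numbers).
#' @return data.frame of class \code{decisionSet} with logical columns
#'   \code{positive}, \code{truthPositive}.
#' @export
decisionSet <- function(call, truth, score = NULL, subtype = NULL,
                        caseId = NULL) {
  toLogical <- function(v) if (is.logical(v)) v else v == "pCR"
  pos <- toLogical(call)
  tr <- toLogical(truth)
  stopifnot(length(pos) == length(tr), !anyNA(pos), !anyNA(tr))
  d <- data.frame(
    case_id = if (is.null(caseId)) as.character(seq_along(pos))
              else as.character(caseId),
    positive = pos, truthPositive = tr, stringsAsFactors = FALSE)
  if (!is.null(score)) d$score <- score
  if (!is.null(subtype)) d$subtype <- as.character(subtype)
  class(d) <- c("decisionSet", "data.frame")
  d
}

#' Confusion-matrix diagnostic metrics of a decision set
#'
#' Sensitivity, specificity and accuracy as percentages, plus AUC: the
#' Mann-Whitney AUC with a DeLong 95\% CI when the set carries scores, or
#' the single-operating-point trapezoid \eqn{(Se + Sp) / 2} for call-only
#' sets (the two-segment ROC through the method's one operating point).
#'
#' @param d a \code{\link{decisionSet}}; both classes must be present.
#' @return a \linkS4class{DiagnosticSummary}.
#' @export
#' @examples
#' d <- decisionSet(c(TRUE, FALSE, TRUE), c(TRUE, FALSE, FALSE))
#' confusionMetrics(d)
confusionMetrics <- function(d) {
  nPos <- sum(d$truthPositive); nNeg <- sum(!d$truthPositive)
  if (nPos == 0)
    stopWithClass("undefinedMetricError",
                  "no positive cases: sensitivity undefined")
  if (nNeg == 0)
    stopWithClass("undefinedMetricError",
                  "no negative cases: specificity undefined")
  tp <- sum(d$positive & d$truthPositive)
  fp <- sum(d$positive & !d$truthPositive)
  tn <- sum(!d$positive & !d$truthPositive)
  fn <- sum(!d$positive & d$truthPositive)
  if (!is.null(d$score)) {
    a <- aucFromScores(d$score, d$truthPositive)
    auc <- a$auc; ci <- a$ci
  } else {
    auc <- aucSinglePoint(100 * tp / nPos, 100 * tn / nNeg)
    ci <- c(NA_real_, NA_real_)
  }
  new("DiagnosticSummary",
      tp = as.integer(tp), fp = as.integer(fp), tn = as.integer(tn),
      fn = as.integer(fn),
      sensitivity = 100 * tp / nPos, specificity = 100 * tn / nNeg,
      accuracy = 100 * (tp + tn) / (nPos + nNeg),
      auc = auc, aucCI = as.numeric(ci),
      nPos = as.integer(nPos), nNeg = as.integer(nNeg))
}

#' Single-operating-point AUC of a call-only method
#'
#' A binary decision maker has one point on the ROC plane; the area of the
#' two-segment ROC through (1 - Sp, Se) is \eqn{(Se + Sp)/2} (inputs as
#' percentages, result a fraction). This is how published reader AUCs in
#' diagnostic tables are reproduced from their printed Se/Sp.
#'
#' @param sensitivity,specificity percentages in [0, 100].
#' @return AUC fraction in [0, 1].
#' @export
#' @examples
#' aucSinglePoint(77.24, 79.54)  # 0.784 at 3 decimals
aucSinglePoint <- function(sensitivity, specificity) {
  if (any(c(sensitivity, specificity) < 0) ||
      any(c(sensitivity, specificity) > 100))
    stop("sensitivity and specificity must lie in [0, 100]")
  (sensitivity / 100 + specificity / 100) / 2
}

#' Mann-Whitney AUC with DeLong 95% confidence interval
#'
#' @param scores numeric scores, higher = more positive-like.
#' @param truth logical (or "pCR"/"non-pCR") truth labels.
#' @return list with \code{auc} (ties counted 1/2) and \code{ci}
#'   (DeLong 95\%, clamped to [0, 1]).
#' @export
#' @examples
#' aucFromScores(c(0.9, 0.4, 0.6, 0.1), c(TRUE, TRUE, FALSE, FALSE))$auc
aucFromScores <- function(scores, truth) {
  pos <- if (is.logical(truth)) truth else truth == "pCR"
  stopifnot(all(is.finite(scores)))
  if (!any(pos) || all(pos))
    stopWithClass("undefinedMetricError",
                  "both classes are required to compute an AUC")
  r <- pROC::roc(response = pos, predictor = scores,
                 levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  ci <- suppressWarnings(as.numeric(pROC::ci.auc(r, method = "delong")))
  list(auc = as.numeric(pROC::auc(r)),
       ci = pmin(pmax(ci[c(1, 3)], 0), 1))
}

#' OR-fusion of a reader with the CAD
#'
#' CAD-assisted reading: a case is called positive when the reader or the
#' CAD calls it positive. Fused sensitivity is therefore never below either
#' component's, and fused specificity never above either component's.
#'
#' @param reader,cad \code{\link{decisionSet}}s over the same cases (same
#'   case_ids and truth).
#' @return a call-only \code{\link{decisionSet}}.
#' @export
fuseOr <- function(reader, cad) {
  if (!identical(reader$case_id, cad$case_id) ||
      !identical(reader$truthPositive, cad$truthPositive))
    stopWithClass("caseSetMismatchError",
                  "reader and CAD decision sets cover different cases")
  decisionSet(reader$positive | cad$positive, reader$truthPositive,
              subtype = reader$subtype, caseId = reader$case_id)
}

#' Compare a diagnostic proportion between two methods
#'
#' Builds the 2x2 correct/incorrect-by-method table for the chosen metric
#' (sensitivity: positive cases only; specificity: negative cases only;
#' accuracy: all cases) and tests it. The default is the unpaired Pearson
#' chi-square statistic \eqn{\sum (O - E)^2 / E} (no continuity
#' correction); since both methods read the same cases, the paired McNemar
#' test (without continuity correction) is available via
#' \code{method = "mcnemar"}.
#'
#' @param a,b \code{\link{decisionSet}}s over the same cases.
#' @param metric one of "sensitivity", "specificity", "accuracy".
#' @param method "chisq" (default) or "mcnemar".
#' @return list with \code{statistic}, \code{p.value}, \code{method},
#'   \code{table}.
#' @export
compareProportions <- function(a, b,
                               metric = c("sensitivity", "specificity",
                                          "accuracy"),
                               method = c("chisq", "mcnemar")) {
  metric <- match.arg(metric)
  method <- match.arg(method)
  if (!identical(a$truthPositive, b$truthPositive))
    stopWithClass("caseSetMismatchError",
                  "decision sets must share the same truth")
  sel <- switch(metric,
                sensitivity = a$truthPositive,
                specificity = !a$truthPositive,
                accuracy = rep(TRUE, nrow(a)))
  okA <- (a$positive == a$truthPositive)[sel]
  okB <- (b$positive == b$truthPositive)[sel]
  if (method == "chisq") {
    tab <- rbind(A = c(sum(okA), sum(!okA)), B = c(sum(okB), sum(!okB)))
    colnames(tab) <- c("correct", "incorrect")
    if (any(colSums(tab) == 0) || any(rowSums(tab) == 0))
      stopWithClass("zeroMarginError",
                    "degenerate 2x2 table (zero margin) for %s", metric)
    ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  } else {
    tab <- table(factor(okA, c(FALSE, TRUE)), factor(okB, c(FALSE, TRUE)),
                 dnn = c("A correct", "B correct"))
    if (tab[1, 2] + tab[2, 1] == 0)
      return(list(statistic = 0, p.value = 1, method = method, table = tab))
    ht <- stats::mcnemar.test(tab, correct = FALSE)
  }
  list(statistic = unname(ht$statistic), p.value = unname(ht$p.value),
       method = method, table = tab)
}

#' Per-subtype diagnostic summaries
#'
#' Splits a decision set by molecular subtype and summarizes each group.
#' Subtypes where only one truth class is present cannot be summarized;
#' they are reported in the \code{flagged} attribute and omitted from the
#' result.
#'
#' @param d a \code{\link{decisionSet}} carrying a \code{subtype} column.
#' @return named list of \linkS4class{DiagnosticSummary}, one per summarizable
#'   subtype present, with attribute \code{flagged} naming skipped
#'   subtypes.
#' @export
subgroupSummary <- function(d) {
  stopifnot(!is.null(d$subtype))
  out <- list(); flagged <- character(0)
  for (st in unique(d$subtype)) {
    g <- d[d$subtype == st, , drop = FALSE]
    class(g) <- class(d)
    res <- tryCatch(confusionMetrics(g), undefinedMetricError = function(e) NULL)
    if (is.null(res)) flagged <- c(flagged, st) else out[[st]] <- res
  }
  attr(out, "flagged") <- flagged
  out
}

#' Reconstruct confusion counts from printed rates
#'
#' Given a published sensitivity/specificity pair and the class sizes,
#' recovers the integer confusion counts (rounding half away from zero, as
#' printed tables do) and the accuracy and single-operating-point AUC they
#' imply. This is the consistency check that makes published diagnostic
#' tables verifiable without the underlying images.
#'
#' @param sensitivity,specificity percentages in [0, 100].
#' @param nPos,nNeg class sizes (>= 1).
#' @return list: \code{tp}, \code{tn}, \code{accuracy} (percent),
#'   \code{auc} (fraction), all unrounded except the integer counts.
#' @export
#' @examples
#' reconstructCounts(87.80, 88.18, 123, 347)$accuracy  # 88.09 at 2 decimals
reconstructCounts <- function(sensitivity, specificity, nPos, nNeg) {
  if (any(c(sensitivity, specificity) < 0) ||
      any(c(sensitivity, specificity) > 100))
    stop("rates must lie in [0, 100]")
  stopifnot(nPos >= 1, nNeg >= 1)
  tp <- roundHalfUp(sensitivity / 100 * nPos)
  tn <- roundHalfUp(specificity / 100 * nNeg)
  list(tp = as.integer(tp), tn = as.integer(tn),
       accuracy = 100 * (tp + tn) / (nPos + nNeg),
       auc = (sensitivity + specificity) / 200)
}

#' Simulate a human reader at a fixed operating point
#'
#' Draws per-case calls that are correct with probability equal to the
#' reader's sensitivity (positive cases) or specificity (negative cases);
#' used to emulate junior/senior radiologists in synthetic end-to-end runs.
#'
#' @param truth logical or "pCR"/"non-pCR" truth labels.
#' @param sensitivity,specificity operating point, percentages.
#' @param seed integer seed.
#' @param subtype optional subtype vector carried into the decision set.
#' @param caseId optional case ids.
#' @return a call-only \code{\link{decisionSet}}.
#' @export
simulateReader <- function(truth, sensitivity, specificity, seed = 1L,
                           subtype = NULL, caseId = NULL) {
  pos <- if (is.logical(truth)) truth else truth == "pCR"
  withLocalSeed(seed, {
    hit <- runif(length(pos)) < ifelse(pos, sensitivity, specificity) / 100
    decisionSet(ifelse(pos, hit, !hit), pos, subtype = subtype,
                caseId = caseId)
  })
}

#' Published example reader/CAD operating points
#'
#' Loads the packaged table of example published operating points of a
#' breast-MRI pCR reader study (junior/senior radiologist, CAD, and
#' CAD-assisted readers, plus CAD subtype rows), used in documentation and
#' for rate-to-count reconstruction demonstrations.
#'
#' @return data.frame: method, sensitivity, specificity, n_pos, n_neg.
#' @export
publishedOperatingPoints <- function() {
  utils::read.csv(system.file("extdata", "published_reader_metrics.csv",
                              package = "pcrCAD"),
                  stringsAsFactors = FALSE)
}
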