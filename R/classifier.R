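#' Build the 61-column feature matrix for a cohort
#'
#' Computes the 13 shape and 48 texture features per case. By default the
#' ground-truth masks are used (segmentation bypass); a named list of
#' predicted masks can be supplied instead, e.g. from
#' \code{\link{segmentLesion}}.
#'
#' @param cohort a \linkS4class{LesionCohort}.
#' @param masks optional named list of binary masks keyed by case_id;
#'   defaults to each case's ground-truth mask.
#' @param config a \code{\link{glcmConfig}}.
#' @return data.frame: case_id, label, subtype, then 13 + 48 named feature
#'   columns in canonical order, no missing values.
#' @export
extractFeatures <- function(cohort, masks = NULL, config = glcmConfig()) {
  tb <- cohortTable(cohort)
  cases <- cohortCases(cohort)
  rows <- vector("list", nrow(tb))
  for (i in seq_len(nrow(tb))) {
    id <- tb$case_id[i]
    msk <- if (is.null(masks)) lesionMask(cases[[id]]) else masks[[id]]
    if (is.null(msk))
      stopWithClass("missingMaskError", "no mask for case '%s'", id)
    sf <- shapeFeatures(msk)
    tf <- textureFeatures(lesionPixels(cases[[id]]), msk, config)
    rows[[i]] <- c(sf, tf)
  }
  feat <- do.call(rbind, rows)
  stopifnot(!anyNA(feat), all(is.finite(feat)))
  cbind(tb[, c("case_id", "label", "subtype")],
        as.data.frame(feat, row.names = NULL))
}

#' Canonical feature column order (13 shape + 48 texture)
#' @param config a \code{\link{glcmConfig}}.
#' @return character vector of length 61 for the faithful configuration.
#' @export
featureColumnNames <- function(config = glcmConfig()) {
  c(shapeFeatureNames(), textureFeatureNames(config))
}

#' Stratified 5-part split with rotation roles
#'
#' Shuffles each class independently (seeded) and deals cases into
#' \code{nParts} parts round-robin, so per-class part sizes differ by at
#' most one case. Rotation r tests on part r, validates on part
#' (r mod nParts) + 1, and trains on the remaining parts; over all
#' rotations every case is tested exactly once.
#'
#' @param cohort a \linkS4class{LesionCohort} or a cohort table
#'   (data.frame with case_id and label).
#' @param seed integer seed for the stratified shuffle.
#' @param nParts number of parts (default 5).
#' @return a \linkS4class{SplitScheme}.
#' @export
makeSplits <- function(cohort, seed = 1L, nParts = 5L) {
  tb <- if (is(cohort, "LesionCohort")) cohortTable(cohort) else cohort
  classes <- unique(tb$label)
  cnt <- table(tb$label)
  small <- names(cnt)[cnt < nParts]
  if (length(small))
    stopWithClass("splitError",
                  "class '%s' has %d cases; need at least %d per class",
                  small[1], cnt[[small[1]]], nParts)
  part <- integer(nrow(tb))
  withLocalSeed(seed, {
    for (cl in classes) {
      idx <- sample(which(tb$label == cl))
      part[idx] <- rep_len(seq_len(nParts), length(idx))
    }
  })
  new("SplitScheme", part = part, caseId = as.character(tb$case_id),
      nParts = as.integer(nParts), seed = as.integer(seed))
}

# fast Mann-Whitney AUC (ties counted 1/2); used for model selection
rankAUC <- function(scores, positive) {
  nP <- sum(positive); nN <- sum(!positive)
  if (nP == 0 || nN == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - nP * (nP + 1) / 2) / (nP * nN)
}

#' Train a maximum-margin SVM on feature rows
#'
#' Per-feature z-standardization is fitted on the training rows only, then
#' a support vector machine (libsvm via \pkg{e1071}) is trained to separate
#' pCR from non-pCR. The decision score is oriented so that positive means
#' pCR. For the linear kernel the hyperplane normal \code{w} and offset
#' \code{b} (in standardized feature space) are exposed, so in the
#' separable hard-margin case support vectors satisfy
#' \eqn{|w x + b| = 1}.
#'
#' @param x numeric matrix of feature rows (training cases).
#' @param y character/factor labels, "pCR" / "non-pCR"; both classes must
#'   be present.
#' @param cost soft-margin cost parameter C.
#' @param kernel "linear" (default) or "radial".
#' @param classWeights logical; weight classes by inverse prevalence.
#' @return object of class \code{trainedSVM} with elements \code{model},
#'   \code{center}, \code{scale}, \code{w}, \code{b} (linear kernel only),
#'   \code{featureNames}.
#' @export
trainSVM <- function(x, y, cost = 1, kernel = "linear",
                     classWeights = TRUE) {
  x <- as.matrix(x)
  y <- factor(as.character(y), levels = c("non-pCR", "pCR"))
  if (anyNA(y)) stop("labels must be 'pCR' or 'non-pCR'")
  if (nlevels(droplevels(y)) < 2)
    stopWithClass("singleClassError",
                  "training set contains a single class ('%s')",
                  as.character(unique(y)))
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1
  xs <- scale(x, ctr, scl)
  cw <- if (classWeights) {
    tab <- table(y)
    stats::setNames(as.numeric(length(y) / (2 * tab)), names(tab))
  } else NULL
  fit <- e1071::svm(xs, y, kernel = kernel, cost = cost, scale = FALSE,
                    class.weights = cw)
  # libsvm's decision value is positive for the first label it encountered;
  # orient so positive score always means pCR
  sgn <- if (fit$labels[1] == which(levels(y) == "pCR")) 1 else -1
  out <- list(model = fit, center = ctr, scale = scl, sign = sgn,
              kernel = kernel, featureNames = colnames(x))
  if (kernel == "linear") {
    out$w <- sgn * drop(t(fit$coefs) %*% fit$SV)
    out$b <- -sgn * fit$rho
  }
  class(out) <- "trainedSVM"
  out
}

#' Decision scores and calls from a trained SVM
#'
#' @param fit a \code{trainedSVM}.
#' @param x feature matrix with the training columns.
#' @return data.frame with \code{score} (signed margin distance, positive
#'   = pCR) and \code{call} ("pCR" when score > 0).
#' @export
svmDecision <- function(fit, x) {
  x <- as.matrix(x)[, fit$featureNames, drop = FALSE]
  xs <- scale(x, fit$center, fit$scale)
  dv <- attr(stats::predict(fit$model, xs, decision.values = TRUE),
             "decision.values")
  score <- fit$sign * drop(dv)
  data.frame(score = score,
             call = ifelse(score > 0, "pCR", "non-pCR"),
             stringsAsFactors = FALSE)
}

#' Run the 5-rotation split protocol
#'
#' For each rotation: the cost parameter is selected from \code{costGrid}
#' by validation-part AUC, a model with the selected cost is trained on the
#' training parts only (standardization included), the operating threshold
#' is fixed on the validation part by the Youden index, and the frozen
#' model + threshold score the test part. Pooling the test parts gives
#' exactly one score and call per case.
#'
#' @param features feature data.frame from \code{\link{extractFeatures}}.
#' @param scheme a \linkS4class{SplitScheme} built on the same cohort.
#' @param costGrid candidate cost values.
#' @param kernel SVM kernel.
#' @param classWeights weight classes by inverse prevalence.
#' @return data.frame: case_id, label, subtype, score, call, rotation — one
#'   row per case, ordered as the cohort table.
#' @export
runRotations <- function(features, scheme,
                         costGrid = c(0.01, 0.1, 1, 10),
                         kernel = "linear", classWeights = TRUE) {
  stopifnot(identical(as.character(features$case_id), scheme@caseId))
  featCols <- setdiff(names(features), c("case_id", "label", "subtype"))
  X <- as.matrix(features[, featCols])
  y <- as.character(features$label)
  score <- rep(NA_real_, nrow(features))
  call <- rep(NA_character_, nrow(features))
  rot <- rep(NA_integer_, nrow(features))
  for (r in seq_len(scheme@nParts)) {
    roles <- rotationRoles(scheme, r)
    best <- NULL; bestAUC <- -Inf
    for (C in costGrid) {
      fit <- trainSVM(X[roles$train, , drop = FALSE], y[roles$train],
                      cost = C, kernel = kernel,
                      classWeights = classWeights)
      vs <- svmDecision(fit, X[roles$validation, , drop = FALSE])$score
      a <- rankAUC(vs, y[roles$validation] == "pCR")
      if (!is.na(a) && a > bestAUC) {
        bestAUC <- a; best <- fit
      }
    }
    vs <- svmDecision(best, X[roles$validation, , drop = FALSE])$score
    thr <- youdenThreshold(vs, y[roles$validation] == "pCR")
    ts <- svmDecision(best, X[roles$test, , drop = FALSE])$score
    score[roles$test] <- ts
    call[roles$test] <- ifelse(ts > thr, "pCR", "non-pCR")
    rot[roles$test] <- r
  }
  data.frame(case_id = features$case_id, label = y,
             subtype = features$subtype, score = score, call = call,
             rotation = rot, stringsAsFactors = FALSE)
}

# threshold maximizing Youden's J = Se + Sp - 1 on a validation part;
# midpoint between consecutive distinct scores, default 0 when degenerate
youdenThreshold <- function(scores, positive) {
  u <- sort(unique(scores))
  if (length(u) < 2 || !any(positive) || all(positive)) return(0)
  cand <- c(u[1] - 1, (u[-1] + u[-length(u)]) / 2)
  j <- vapply(cand, function(t) {
    se <- mean(scores[positive] > t)
    sp <- mean(scores[!positive] <= t)
    se + sp - 1
  }, 0)
  cand[which.max(j)]
}
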