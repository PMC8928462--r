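#' @import methods
NULL

#' PhantomSpec: parameters of one synthetic lesion
#'
#' Describes a single simulated breast mass: a radial-harmonic contour
#' (lobulation), optional triangular spicules, and either a homogeneous or a
#' heterogeneous (necrosis-like) internal texture, rendered on an 8-bit
#' grayscale canvas with Gaussian background noise. All randomness (harmonic
#' phase, spicule angles, noise, texture field) derives from \code{seed}, so
#' an identical spec yields a bit-identical image and mask.
#'
#' @slot imageSize integer, pixels per side of the square canvas.
#' @slot baseRadius numeric, mean lesion radius in pixels (>= 3 and the
#'   lesion must fit inside the canvas).
#' @slot lobulationOrder integer, harmonic order k of the contour
#'   modulation; a k-th order harmonic produces k lobes.
#' @slot lobulationAmp numeric in [0, 1), amplitude of the harmonic as a
#'   fraction of \code{baseRadius}.
#' @slot spiculeCount integer >= 0, number of triangular spicules placed at
#'   seeded random angles.
#' @slot spiculeLen numeric, spicule length as a fraction of
#'   \code{baseRadius}.
#' @slot textureClass character, \code{"homogeneous"} or
#'   \code{"heterogeneous"}.
#' @slot noiseSD numeric, Gaussian noise standard deviation in 8-bit gray
#'   levels.
#' @slot seed integer RNG seed.
#' @export
setClass("PhantomSpec", representation(
  imageSize = "integer", baseRadius = "numeric",
  lobulationOrder = "integer", lobulationAmp = "numeric",
  spiculeCount = "integer", spiculeLen = "numeric",
  textureClass = "character", noiseSD = "numeric", seed = "integer"
))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (object@baseRadius < 3) msg <- c(msg, "baseRadius must be >= 3 px")
  maxR <- object@baseRadius * (1 + object@lobulationAmp + object@spiculeLen)
  if (maxR >= object@imageSize / 2)
    msg <- c(msg, sprintf(
      "lesion (max radius %.1f px) exceeds the %d px canvas",
      maxR, object@imageSize))
  if (object@lobulationAmp < 0 || object@lobulationAmp >= 1)
    msg <- c(msg, "lobulationAmp must lie in [0, 1)")
  if (object@spiculeCount < 0) msg <- c(msg, "spiculeCount must be >= 0")
  if (!object@textureClass %in% c("homogeneous", "heterogeneous"))
    msg <- c(msg, "textureClass must be 'homogeneous' or 'heterogeneous'")
  if (object@noiseSD < 0) msg <- c(msg, "noiseSD must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a PhantomSpec
#'
#' @param imageSize canvas side length in pixels.
#' @param baseRadius mean lesion radius in pixels.
#' @param lobulationOrder harmonic order of the contour modulation.
#' @param lobulationAmp harmonic amplitude as a fraction of the radius.
#' @param spiculeCount number of triangular spicules.
#' @param spiculeLen spicule length as a fraction of the radius.
#' @param textureClass "homogeneous" or "heterogeneous".
#' @param noiseSD background noise SD in gray levels.
#' @param seed integer seed driving all randomness of the phantom.
#' @return a \linkS4class{PhantomSpec}.
#' @export
#' @examples
#' phantomSpec(baseRadius = 12, seed = 1L)
phantomSpec <- function(imageSize = 64L, baseRadius = 12, lobulationOrder = 3L,
                        lobulationAmp = 0, spiculeCount = 0L, spiculeLen = 0.4,
                        textureClass = "homogeneous", noiseSD = 8, seed = 1L) {
  new("PhantomSpec", imageSize = as.integer(imageSize),
      baseRadius = as.numeric(baseRadius),
      lobulationOrder = as.integer(lobulationOrder),
      lobulationAmp = as.numeric(lobulationAmp),
      spiculeCount = as.integer(spiculeCount),
      spiculeLen = as.numeric(spiculeLen),
      textureClass = textureClass, noiseSD = as.numeric(noiseSD),
      seed = as.integer(seed))
}

#' LesionImage: a 2D grayscale lesion with optional ground-truth mask
#'
#' The central data container: an 8-bit grayscale image stored as a numeric
#' matrix (rows = image rows), an optional binary ground-truth mask of the
#' same dimensions, and case metadata (case id, pCR label, molecular
#' subtype, generating spec when synthetic).
#'
#' @slot image numeric matrix, gray levels in [0, 255].
#' @slot mask matrix (0/1) of identical dimensions, or a 0x0 matrix when no
#'   ground truth is available.
#' @slot meta list of case metadata.
#' @export
setClass("LesionImage", representation(
  image = "matrix", mask = "matrix", meta = "list"
))

setValidity("LesionImage", function(object) {
  msg <- character()
  if (length(object@mask) &&
      !identical(dim(object@image), dim(object@mask)))
    msg <- c(msg, "image and mask dimensions differ")
  if (length(object@mask) && !all(object@mask %in% c(0, 1)))
    msg <- c(msg, "mask must be binary (0/1)")
  if (any(!is.finite(object@image))) msg <- c(msg, "image has non-finite values")
  if (length(msg)) msg else TRUE
})

#' @describeIn LesionImage-class constructor.
#' @param image numeric matrix of gray levels.
#' @param mask optional 0/1 matrix of the same dimensions.
#' @param meta list of case metadata (caseId, label, subtype, ...).
#' @export
lesionImage <- function(image, mask = NULL, meta = list()) {
  if (is.null(mask)) mask <- matrix(numeric(0), 0, 0)
  new("LesionImage", image = image,
      mask = matrix(as.numeric(mask > 0), nrow(mask), ncol(mask)),
      meta = meta)
}

#' @describeIn LesionImage-class pixel data accessor.
#' @param x a LesionImage.
#' @export
lesionPixels <- function(x) x@image

#' @describeIn LesionImage-class ground-truth mask accessor (NULL if absent).
#' @export
lesionMask <- function(x) if (length(x@mask)) x@mask else NULL

#' @describeIn LesionImage-class metadata accessor.
#' @export
lesionMeta <- function(x) x@meta

setMethod("show", "LesionImage", function(object) {
  d <- dim(object@image)
  cat(sprintf("LesionImage %dx%d, %s mask", d[1], d[2],
              if (length(object@mask)) "with ground-truth" else "no"))
  if (!is.null(object@meta$caseId))
    cat(sprintf(" [%s, %s/%s]", object@meta$caseId,
                object@meta$label %||% "?", object@meta$subtype %||% "?"))
  cat("\n")
})

`%||%` <- function(a, b) if (is.null(a)) b else a

#' LesionCohort: a set of cases with a cohort table
#'
#' Bundles a cohort table (case_id, label, subtype, image_path, mask_path)
#' with the corresponding \linkS4class{LesionImage} objects, keyed by
#' case_id.
#'
#' @slot table data.frame with the cohort margins.
#' @slot cases named list of LesionImage objects.
#' @export
setClass("LesionCohort", representation(table = "data.frame", cases = "list"))

setValidity("LesionCohort", function(object) {
  msg <- character()
  need <- c("case_id", "label", "subtype", "image_path", "mask_path")
  if (!all(need %in% names(object@table)))
    msg <- c(msg, paste("cohort table must have columns:",
                        paste(need, collapse = ", ")))
  if (anyDuplicated(object@table$case_id))
    msg <- c(msg, "case_ids must be unique")
  if (length(object@cases) &&
      !identical(names(object@cases), as.character(object@table$case_id)))
    msg <- c(msg, "cases must be named by case_id in table order")
  if (length(msg)) msg else TRUE
})

#' @describeIn LesionCohort-class cohort table accessor.
#' @param x a LesionCohort.
#' @export
cohortTable <- function(x) x@table

#' @describeIn LesionCohort-class case list accessor.
#' @export
cohortCases <- function(x) x@cases

setMethod("show", "LesionCohort", function(object) {
  tb <- table(object@table$label)
  cat(sprintf("LesionCohort with %d cases (%s)\n", nrow(object@table),
              paste(sprintf("%s: %d", names(tb), tb), collapse = ", ")))
  st <- table(object@table$subtype)
  cat("  subtypes:", paste(sprintf("%s %d", names(st), st), collapse = ", "),
      "\n")
})

#' SegmenterModel: a trained encoder-decoder segmentation network
#'
#' Holds the learned parameters of the convolutional encoder-decoder, the
#' training configuration used, and the per-epoch loss trace.
#'
#' @slot params list of layer weight matrices and biases.
#' @slot config list, the resolved \code{\link{segTrainConfig}}.
#' @slot lossTrace numeric, mean cross-entropy per epoch.
#' @export
setClass("SegmenterModel", representation(
  params = "list", config = "list", lossTrace = "numeric"
))

setMethod("show", "SegmenterModel", function(object) {
  cat(sprintf(
    "SegmenterModel: depth %d, base channels %d, %d epochs (final loss %.4g)\n",
    object@config$encoderDepth, object@config$baseChannels,
    length(object@lossTrace), tail(object@lossTrace, 1)))
})

#' @describeIn SegmenterModel-class per-epoch training loss accessor.
#' @param x a SegmenterModel.
#' @export
lossTrace <- function(x) x@lossTrace

#' SplitScheme: stratified 5-part split with rotation roles
#'
#' Each class is divided into 5 near-equal parts; rotation r uses part r as
#' the test set, part (r mod 5) + 1 as the validation set, and the remaining
#' three parts as the training set, so that across the 5 rotations every
#' case serves in the test role exactly once.
#'
#' @slot part integer vector, part assignment (1..nParts) per case.
#' @slot caseId character vector of case ids, parallel to \code{part}.
#' @slot nParts integer, number of parts (5).
#' @slot seed integer seed used for the stratified shuffle.
#' @export
setClass("SplitScheme", representation(
  part = "integer", caseId = "character", nParts = "integer", seed = "integer"
))

setMethod("show", "SplitScheme", function(object) {
  cat(sprintf("SplitScheme: %d cases in %d parts (sizes %s)\n",
              length(object@part), object@nParts,
              paste(tabulate(object@part, object@nParts), collapse = "/")))
})

#' @describeIn SplitScheme-class roles (train/validation/test index vectors)
#'   for one rotation.
#' @param x a SplitScheme.
#' @param rotation rotation number in 1..nParts.
#' @export
rotationRoles <- function(x, rotation) {
  stopifnot(rotation >= 1, rotation <= x@nParts)
  testPart <- rotation
  valPart <- rotation %% x@nParts + 1L
  list(test = which(x@part == testPart),
       validation = which(x@part == valPart),
       train = which(!x@part %in% c(testPart, valPart)))
}

#' DiagnosticSummary: confusion counts and diagnostic accuracy metrics
#'
#' Sensitivity, specificity and accuracy are stored as percentages; AUC as a
#' fraction in [0, 1] with an optional 95\% confidence interval (DeLong for
#' score-based sets, single-operating-point trapezoid for call-only sets).
#'
#' @slot tp,fp,tn,fn integer confusion counts.
#' @slot sensitivity,specificity,accuracy numeric percentages.
#' @slot auc numeric in [0, 1].
#' @slot aucCI numeric length-2 95\% CI (NA when unavailable).
#' @slot nPos,nNeg integer class sizes.
#' @export
setClass("DiagnosticSummary", representation(
  tp = "integer", fp = "integer", tn = "integer", fn = "integer",
  sensitivity = "numeric", specificity = "numeric", accuracy = "numeric",
  auc = "numeric", aucCI = "numeric", nPos = "integer", nNeg = "integer"
))

setValidity("DiagnosticSummary", function(object) {
  msg <- character()
  if (object@tp + object@fn != object@nPos) msg <- c(msg, "TP + FN must equal nPos")
  if (object@tn + object@fp != object@nNeg) msg <- c(msg, "TN + FP must equal nNeg")
  if (!is.na(object@auc) && (object@auc < 0 || object@auc > 1))
    msg <- c(msg, "auc must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "DiagnosticSummary", function(object) {
  cat(sprintf(
    "DiagnosticSummary (n=%d: %d pos / %d neg)\n  TP %d  FP %d  TN %d  FN %d\n",
    object@nPos + object@nNeg, object@nPos, object@nNeg,
    object@tp, object@fp, object@tn, object@fn))
  cat(sprintf("  Se %.2f%%  Sp %.2f%%  Acc %.2f%%  AUC %.3f",
              object@sensitivity, object@specificity, object@accuracy,
              object@auc))
  if (!anyNA(object@aucCI))
    cat(sprintf(" (95%% CI %.3f-%.3f)", object@aucCI[1], object@aucCI[2]))
  cat("\n")
})

#' @describeIn DiagnosticSummary-class one-row data.frame with percentages
#'   rounded to 2 decimals and AUC to 3 (half away from zero), matching the
#'   conventional table formatting of reader studies.
#' @param x a DiagnosticSummary.
#' @export
summaryRow <- function(x) {
  data.frame(
    auc = roundHalfUp(x@auc, 3),
    auc_ci_low = if (anyNA(x@aucCI)) NA_real_ else roundHalfUp(x@aucCI[1], 3),
    auc_ci_high = if (anyNA(x@aucCI)) NA_real_ else roundHalfUp(x@aucCI[2], 3),
    sensitivity = roundHalfUp(x@sensitivity, 2),
    specificity = roundHalfUp(x@specificity, 2),
    accuracy = roundHalfUp(x@accuracy, 2),
    tp = x@tp, fp = x@fp, tn = x@tn, fn = x@fn
  )
}
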