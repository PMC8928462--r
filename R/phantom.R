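#' Render a synthetic lesion phantom
#'
#' Rasterizes a star-convex lesion whose contour follows
#' \eqn{r(\theta) = R (1 + a \cos(k\theta + \phi))} with optional triangular
#' spicules at seeded random angles, on an 8-bit grayscale canvas.
#' Homogeneous lesions have constant foreground intensity plus Gaussian
#' noise; heterogeneous lesions are additionally modulated by a seeded
#' smoothed random field, imitating necrosis-like internal patches.
#' The ground-truth mask is reduced to its largest 8-connected component
#' (rasterization of extreme spicules can detach single pixels).
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return a \linkS4class{LesionImage} with ground-truth mask; the
#'   generating spec is kept in \code{lesionMeta(x)$spec}.
#' @export
#' @examples
#' ph <- makePhantom(phantomSpec(baseRadius = 10, seed = 7L))
#' sum(lesionMask(ph))
makePhantom <- function(spec) {
  validObject(spec)
  S <- spec@imageSize
  R <- spec@baseRadius
  withLocalSeed(spec@seed, {
    phase <- runif(1, 0, 2 * pi)
    spicAngle <- if (spec@spiculeCount > 0)
      runif(spec@spiculeCount, 0, 2 * pi) else numeric(0)

    ctr <- (S + 1) / 2
    xs <- matrix(rep(seq_len(S) - ctr, each = S), S, S)   # col offsets
    ys <- matrix(rep(seq_len(S) - ctr, times = S), S, S)  # row offsets
    theta <- atan2(ys, xs)
    rad <- R * (1 + spec@lobulationAmp *
                  cos(spec@lobulationOrder * theta + phase))
    halfwidth <- 0.10  # angular half-width of a spicule, radians
    for (psi in spicAngle) {
      d <- abs((theta - psi + pi) %% (2 * pi) - pi)
      rad <- rad + spec@spiculeLen * R * pmax(0, 1 - d / halfwidth)
    }
    mask <- largestComponent(sqrt(xs^2 + ys^2) <= rad)

    fg <- 180
    img <- matrix(0, S, S)
    if (spec@textureClass == "heterogeneous") {
      field <- matrix(rnorm(S * S), S, S)
      brush <- EBImage::makeBrush(2 * ceiling(3 * 2.5) + 1, "gaussian",
                                  sigma = 2.5)
      sm <- as.matrix(EBImage::filter2(EBImage::Image(field), brush))
      sm <- (sm - mean(sm)) / stats::sd(sm)
      img[mask == 1] <- fg * (1 + 0.35 * sm[mask == 1])
    } else {
      img[mask == 1] <- fg
    }
    img <- img + matrix(rnorm(S * S, sd = spec@noiseSD), S, S)
    img <- round(pmin(pmax(img, 0), 255))
    lesionImage(img, mask, meta = list(spec = spec))
  })
}

#' Generate a synthetic cohort with fixed class and subtype margins
#'
#' Draws one phantom per case. The pCR class is sampled from a smoother,
#' rounder spec distribution than the non-pCR class; \code{classEffect}
#' in [0, 1] scales the distributional gap (at 0 the two class
#' distributions are identical, so a downstream classifier has no signal).
#' Molecular subtypes are assigned by a seeded shuffle honouring
#' \code{subtypeCounts} exactly and are independent of lesion morphology.
#'
#' @param nPCR,nNonPCR class sizes.
#' @param subtypeCounts named integer vector over
#'   \code{c("LuminalA","LuminalB","HER2+","TN")} (any subset); must sum to
#'   \code{nPCR + nNonPCR}.
#' @param classEffect separation parameter in [0, 1].
#' @param seed integer seed; drives subtype shuffling, per-case spec draws
#'   and per-case phantom seeds.
#' @param imageSize canvas side in pixels for every phantom.
#' @param dir optional directory; when given, images and masks are written
#'   as 8-bit PNGs and the table carries their paths.
#' @return a \linkS4class{LesionCohort}.
#' @export
#' @examples
#' co <- makeCohort(5, 12, c(LuminalA = 8, TN = 9), classEffect = 1, seed = 3L,
#'                  imageSize = 48L)
#' table(cohortTable(co)$label)
makeCohort <- function(nPCR, nNonPCR, subtypeCounts, classEffect = 1,
                       seed = 1L, imageSize = 64L, dir = NULL) {
  stopifnot(nPCR >= 0, nNonPCR >= 0, classEffect >= 0, classEffect <= 1)
  n <- nPCR + nNonPCR
  bad <- names(subtypeCounts)[subtypeCounts < 0]
  if (length(bad))
    stopWithClass("cohortMarginError",
                  "negative count for subtype '%s'", bad[1])
  if (sum(subtypeCounts) != n)
    stopWithClass(
      "cohortMarginError",
      "subtype counts (%s) sum to %d, but nPCR + nNonPCR = %d",
      paste(sprintf("%s=%d", names(subtypeCounts), subtypeCounts),
            collapse = ", "),
      sum(subtypeCounts), n)
  if (nPCR == 0 || nNonPCR == 0)
    warning("single-class cohort: downstream sensitivity/specificity ",
            "will be undefined", call. = FALSE)

  withLocalSeed(seed, {
    label <- c(rep("pCR", nPCR), rep("non-pCR", nNonPCR))
    subtype <- sample(rep(names(subtypeCounts), times = subtypeCounts))
    caseSeed <- sample.int(.Machine$integer.max - 1L, n)

    cases <- vector("list", n)
    for (i in seq_len(n)) {
      isNon <- label[i] == "non-pCR"
      R <- runif(1, 0.125, 0.22) * imageSize
      amp <- runif(1, 0.02, 0.10) + isNon * classEffect * runif(1, 0.12, 0.22)
      nspic <- rbinom(1, 2, 0.15) + rbinom(1, 6, 0.65 * classEffect * isNon)
      hetero <- runif(1) < 0.15 + 0.70 * classEffect * isNon
      spec <- phantomSpec(
        imageSize = imageSize, baseRadius = R,
        lobulationOrder = sample(2:5, 1), lobulationAmp = amp,
        spiculeCount = nspic, spiculeLen = runif(1, 0.25, 0.45),
        textureClass = if (hetero) "heterogeneous" else "homogeneous",
        noiseSD = 8, seed = caseSeed[i])
      ph <- makePhantom(spec)
      ph@meta <- c(ph@meta, list(
        caseId = sprintf("case_%04d", i), label = label[i],
        subtype = subtype[i]))
      cases[[i]] <- ph
    }
    names(cases) <- vapply(cases, function(x) x@meta$caseId, "")

    imgPath <- maskPath <- rep(NA_character_, n)
    if (!is.null(dir)) {
      dir.create(file.path(dir, "images"), recursive = TRUE,
                 showWarnings = FALSE)
      for (i in seq_len(n)) {
        id <- names(cases)[i]
        imgPath[i] <- file.path(dir, "images", paste0(id, ".png"))
        maskPath[i] <- file.path(dir, "images", paste0(id, "_mask.png"))
        writeGrayPNG(lesionPixels(cases[[i]]), imgPath[i])
        writeGrayPNG(lesionMask(cases[[i]]) * 255, maskPath[i])
      }
    }
    tb <- data.frame(case_id = names(cases), label = label,
                     subtype = subtype, image_path = imgPath,
                     mask_path = maskPath, stringsAsFactors = FALSE)
    new("LesionCohort", table = tb, cases = cases)
  })
}
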