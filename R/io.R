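#' Write an 8-bit grayscale PNG
#'
#' @param mat numeric matrix with values in [0, 255].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeGrayPNG <- function(mat, path) {
  png::writePNG(pmin(pmax(mat, 0), 255) / 255, path)
  invisible(path)
}

#' Read a grayscale image (PNG or NIfTI)
#'
#' PNG values are rescaled to 8-bit gray levels; multi-channel PNGs are
#' reduced to their first channel. NIfTI images are read as-is.
#'
#' @param path file path ending in .png, .nii or .nii.gz.
#' @return numeric matrix of gray levels.
#' @export
readGrayImage <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    x <- png::readPNG(path)
    if (length(dim(x)) == 3) x <- x[, , 1]
    round(x * 255)
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    x <- RNifti::readNifti(path)
    matrix(as.numeric(x), dim(x)[1], dim(x)[2])
  } else {
    stop("unsupported image format: ", path)
  }
}

#' Read a binary mask (PNG or NIfTI), binarized at > 0
#'
#' @param path file path ending in .png, .nii or .nii.gz.
#' @return 0/1 numeric matrix.
#' @export
readMask <- function(path) {
  m <- readGrayImage(path)
  matrix(as.numeric(m > 0), nrow(m), ncol(m))
}

#' Write a binary mask as PNG or NIfTI
#'
#' @param mask 0/1 matrix.
#' @param path output path; format chosen by extension.
#' @return the path, invisibly.
#' @export
writeMask <- function(mask, path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    writeGrayPNG((mask > 0) * 255, path)
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    RNifti::writeNifti(RNifti::asNifti(matrix(as.numeric(mask > 0),
                                              nrow(mask), ncol(mask))),
                       path)
  } else {
    stop("unsupported mask format: ", path)
  }
  invisible(path)
}

#' Write / read the 61-column feature table
#'
#' The on-disk schema is case_id, label, subtype followed by the canonical
#' feature columns of \code{\link{featureColumnNames}}; reading validates
#' the schema and fails naming the first missing column.
#'
#' @param features feature data.frame from \code{\link{extractFeatures}}.
#' @param path CSV path.
#' @return the path, invisibly.
#' @export
writeFeatureCSV <- function(features, path) {
  out <- features
  for (j in seq_along(out)) {
    # 17 significant digits round-trip IEEE doubles exactly
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeFeatureCSV
#' @param config \code{\link{glcmConfig}} defining the expected texture
#'   columns.
#' @export
readFeatureCSV <- function(path, config = glcmConfig()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("case_id", "label", "subtype", featureColumnNames(config))
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopWithClass("schemaError",
                  "feature CSV is missing column '%s'", miss[1])
  df <- df[, need]
  for (j in featureColumnNames(config)) df[[j]] <- as.double(df[[j]])
  df
}

# defaults for every run-config block; user values override by name
defaultRunConfig <- function() {
  list(
    seed = 1L,
    outdir = "pcrcad_run",
    phantom = list(nPCR = 16L, nNonPCR = 44L,
                   subtypeCounts = list(LuminalA = 13L, LuminalB = 23L,
                                        `HER2+` = 13L, TN = 11L),
                   classEffect = 1, imageSize = 64L),
    segmentation = list(useGroundTruth = TRUE, threshold = 0.5,
                        learningRate = 3e-3, epochs = 120L,
                        weightDecay = 5e-4, encoderDepth = 2L,
                        baseChannels = 8L),
    glcm = list(levels = 32L, distances = c(1L, 2L, 3L),
                angles = c(0L, 45L, 90L, 135L)),
    svm = list(kernel = "linear", costGrid = c(0.01, 0.1, 1, 10),
               classWeights = TRUE),
    eval = list(alpha = 0.05, fusion = TRUE,
                readers = list(junior = c(77.24, 79.54),
                               senior = c(82.93, 84.15)))
  )
}

#' Read and validate a pipeline run configuration
#'
#' YAML blocks (phantom, segmentation, glcm, svm, eval) are merged over the
#' documented defaults; unknown keys fail with the offending key named.
#'
#' @param path YAML file path, or NULL for pure defaults.
#' @return validated config list.
#' @export
readRunConfig <- function(path = NULL) {
  cfg <- defaultRunConfig()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    for (k in names(user)) {
      if (!k %in% names(cfg))
        stopWithClass("configError", "unknown config key '%s'", k)
      if (is.list(cfg[[k]]) && is.list(user[[k]])) {
        for (kk in names(user[[k]])) {
          if (!kk %in% names(cfg[[k]]))
            stopWithClass("configError", "unknown config key '%s.%s'", k, kk)
          cfg[[k]][[kk]] <- user[[k]][[kk]]
        }
      } else {
        cfg[[k]] <- user[[k]]
      }
    }
  }
  if (cfg$phantom$nPCR + cfg$phantom$nNonPCR !=
      sum(unlist(cfg$phantom$subtypeCounts)))
    stopWithClass("configError",
                  "phantom.subtypeCounts must sum to nPCR + nNonPCR")
  cfg
}
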