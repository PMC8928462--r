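#' GLCM configuration
#'
#' The faithful configuration uses 4 statistics (energy, correlation,
#' contrast, entropy) at 3 offset distances and 4 directions, yielding the
#' 48-feature texture panel. Gray levels inside the mask are quantized to
#' \code{levels} equal-width bins before co-occurrence counting; the GLCM is
#' symmetrized (transpose added) and normalized to sum 1.
#'
#' @param levels gray-level count after quantization (>= 2).
#' @param distances integer pixel offsets (3 in the faithful panel).
#' @param angles directions in degrees, subset of \{0, 45, 90, 135\}.
#' @return list of class \code{glcmConfig}.
#' @export
glcmConfig <- function(levels = 32L, distances = c(1L, 2L, 3L),
                       angles = c(0L, 45L, 90L, 135L)) {
  stopifnot(levels >= 2, all(distances >= 1),
            all(angles %in% c(0L, 45L, 90L, 135L)))
  structure(list(levels = as.integer(levels),
                 distances = as.integer(distances),
                 angles = as.integer(angles)),
            class = "glcmConfig")
}

#' Quantize the in-mask region of an image
#'
#' Equal-width binning of the in-mask min-max intensity range into
#' \code{levels} levels \code{0 .. levels-1}. A constant region maps to
#' level 0.
#'
#' @param image numeric matrix of gray levels.
#' @param mask binary matrix; must be nonempty.
#' @param levels number of quantization levels.
#' @return integer matrix; in-mask pixels hold the quantized level,
#'   out-of-mask pixels are \code{NA}.
#' @export
#' @examples
#' img <- matrix(c(10, 20, 30, 0), 2, 2)
#' quantizeROI(img, matrix(c(1, 1, 1, 0), 2, 2), 3)
quantizeROI <- function(image, mask, levels) {
  m <- mask > 0
  if (!any(m)) stopWithClass("emptyMaskError", "empty mask: cannot quantize")
  vals <- image[m]
  lo <- min(vals); hi <- max(vals)
  q <- matrix(NA_integer_, nrow(image), ncol(image))
  if (hi == lo) {
    q[m] <- 0L
  } else {
    q[m] <- pmin(as.integer(floor((vals - lo) / (hi - lo) * levels)),
                 levels - 1L)
  }
  q
}

# row/col offset of one pixel step at each supported direction; distance d
# scales the step. 0 deg = along a row towards larger columns.
glcmOffset <- function(angle, d) {
  switch(as.character(angle),
         "0"   = c(0L, d),
         "45"  = c(-d, d),
         "90"  = c(-d, 0L),
         "135" = c(-d, -d),
         stop("unsupported GLCM angle: ", angle))
}

#' Gray-level co-occurrence matrix for one offset
#'
#' Counts ordered level pairs over all pixel pairs at displacement
#' (distance, angle) whose two pixels both lie inside the mask, adds the
#' transpose (symmetrization), and normalizes to sum 1. When no valid pair
#' exists at the offset the all-zero matrix is returned with attribute
#' \code{degenerate = TRUE}.
#'
#' @param q quantized ROI from \code{\link{quantizeROI}} (NA outside mask).
#' @param levels number of gray levels in \code{q}.
#' @param distance pixel offset distance (>= 1).
#' @param angle direction in degrees: 0, 45, 90 or 135.
#' @return \code{levels x levels} matrix of co-occurrence probabilities.
#' @export
glcmMatrix <- function(q, levels, distance, angle) {
  off <- glcmOffset(angle, as.integer(distance))
  nr <- nrow(q); nc <- ncol(q)
  rLo <- max(1, 1 - off[1]); rHi <- min(nr, nr - off[1])
  cLo <- max(1, 1 - off[2]); cHi <- min(nc, nc - off[2])
  g <- matrix(0, levels, levels)
  if (rLo <= rHi && cLo <= cHi) {
    a <- q[rLo:rHi, cLo:cHi, drop = FALSE]
    b <- q[rLo:rHi + off[1], cLo:cHi + off[2], drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (any(ok)) {
      idx <- a[ok] * levels + b[ok] + 1L
      cnt <- tabulate(idx, levels * levels)
      g <- matrix(cnt, levels, levels, byrow = TRUE)  # rows = first pixel
      g <- g + t(g)
      g <- g / sum(g)
      return(g)
    }
  }
  attr(g, "degenerate") <- TRUE
  g
}

#' Haralick statistics of a normalized GLCM
#'
#' \code{energy} \eqn{= \sum p^2}; \code{contrast}
#' \eqn{= \sum (i-j)^2 p}; \code{entropy} \eqn{= -\sum p \log_2 p} (with
#' \eqn{0 \log 0 = 0}); \code{correlation}
#' \eqn{= \sum (i-\mu_x)(j-\mu_y) p / (\sigma_x \sigma_y)}. When
#' \eqn{\sigma_x \sigma_y = 0} (all mass on one level) the correlation is
#' defined as 1: a perfectly concentrated diagonal. A degenerate (all-zero)
#' GLCM takes the same values as a constant ROI: energy 1, contrast 0,
#' entropy 0, correlation 1.
#'
#' @param g matrix from \code{\link{glcmMatrix}}.
#' @return named numeric vector (energy, correlation, contrast, entropy).
#' @export
haralickStats <- function(g) {
  if (isTRUE(attr(g, "degenerate")) || sum(g) == 0)
    return(c(energy = 1, correlation = 1, contrast = 0, entropy = 0))
  L <- nrow(g)
  i <- matrix(rep(seq_len(L) - 1, times = L), L)
  j <- matrix(rep(seq_len(L) - 1, each = L), L)
  px <- rowSums(g); py <- colSums(g)
  mx <- sum((seq_len(L) - 1) * px); my <- sum((seq_len(L) - 1) * py)
  sx <- sqrt(sum(((seq_len(L) - 1) - mx)^2 * px))
  sy <- sqrt(sum(((seq_len(L) - 1) - my)^2 * py))
  corr <- if (sx * sy == 0) 1 else sum((i - mx) * (j - my) * g) / (sx * sy)
  pos <- g > 0
  c(energy = sum(g^2),
    correlation = corr,
    contrast = sum((i - j)^2 * g),
    entropy = -sum(g[pos] * log2(g[pos])))
}

#' The 48 GLCM texture features of a lesion
#'
#' Quantizes the in-mask region and computes the four Haralick statistics
#' for every (distance, angle) offset of the configuration. Feature order
#' is statistic-major, then distance, then angle, with names
#' \code{<stat>_d<distance>_a<angle>}; the faithful configuration yields
#' exactly 48 features.
#'
#' @param image numeric gray-level matrix.
#' @param mask binary matrix (the segmented tumor region).
#' @param config a \code{\link{glcmConfig}}.
#' @return named numeric vector of length
#'   \code{4 * length(distances) * length(angles)}.
#' @export
#' @examples
#' ph <- makePhantom(phantomSpec(baseRadius = 10, seed = 2L))
#' length(textureFeatures(lesionPixels(ph), lesionMask(ph)))
textureFeatures <- function(image, mask, config = glcmConfig()) {
  q <- quantizeROI(image, mask, config$levels)
  stats <- c("energy", "correlation", "contrast", "entropy")
  raw <- lapply(config$distances, function(d)
    lapply(config$angles, function(a)
      haralickStats(glcmMatrix(q, config$levels, d, a))))
  out <- numeric(0)
  for (s in stats)
    for (di in seq_along(config$distances))
      for (ai in seq_along(config$angles)) {
        v <- raw[[di]][[ai]][[s]]
        names(v) <- sprintf("%s_d%d_a%d", s, config$distances[di],
                            config$angles[ai])
        out <- c(out, v)
      }
  out
}

#' Names of the texture feature columns for a configuration
#' @param config a \code{\link{glcmConfig}}.
#' @return character vector (length 48 for the faithful configuration).
#' @export
textureFeatureNames <- function(config = glcmConfig()) {
  as.vector(t(outer(
    c("energy", "correlation", "contrast", "entropy"),
    as.vector(t(outer(config$distances, config$angles,
                      function(d, a) sprintf("d%d_a%d", d, a)))),
    paste, sep = "_")))
}
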