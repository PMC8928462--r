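#' Radial profile of a segmented lesion
#'
#' Extracts the 8-connected boundary of a single-component binary mask,
#' orders the boundary pixels counterclockwise by polar angle about the
#' pixel-center centroid (ties broken by increasing radius), and computes
#' the radial lengths \eqn{d_i} and normalized radial lengths
#' \eqn{nd_i = d_i / \max_j d_j}. The normalized radial length (NRL)
#' profile underlies most of the shape descriptors of
#' \code{\link{shapeFeatures}}.
#'
#' @param mask binary matrix; must be nonempty and a single 8-connected
#'   component with at least 8 boundary pixels.
#' @return list with \code{centroid} (row, col), \code{boundary} (n x 2
#'   matrix of row, col), \code{d}, \code{nd}.
#' @export
radialProfile <- function(mask) {
  m <- matrix(as.integer(mask > 0), nrow(mask), ncol(mask))
  if (!any(m == 1))
    stopWithClass("featureUndefinedError", "empty mask: shape features undefined")
  lab <- EBImage::bwlabel(m)
  if (max(lab) > 1)
    stopWithClass("featureUndefinedError",
                  "mask has %d connected components; expected 1", max(lab))
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(0L, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  core <- pad[2:(nr + 1), 2:(nc + 1)]
  inner <- pad[1:nr, 2:(nc + 1)] & pad[3:(nr + 2), 2:(nc + 1)] &
    pad[2:(nr + 1), 1:nc] & pad[2:(nr + 1), 3:(nc + 2)]
  boundary <- which(core == 1L & !inner, arr.ind = TRUE)
  if (nrow(boundary) < 8)
    stopWithClass("featureUndefinedError",
                  "only %d boundary pixels (need >= 8)", nrow(boundary))
  px <- which(m == 1L, arr.ind = TRUE)
  ctr <- colMeans(px)  # (row, col), pixel-center coordinates
  dy <- boundary[, 1] - ctr[1]
  dx <- boundary[, 2] - ctr[2]
  d <- sqrt(dx^2 + dy^2)
  ang <- atan2(-dy, dx)  # counterclockwise with row axis pointing down
  o <- order(ang, d)
  boundary <- boundary[o, , drop = FALSE]
  d <- d[o]
  list(centroid = ctr, boundary = unname(boundary), d = d, nd = d / max(d))
}

# circular moving average; window forced odd and < n
circularSmooth <- function(x, w) {
  n <- length(x)
  if (w %% 2 == 0) w <- w + 1
  w <- min(w, n - (1 - n %% 2))
  h <- (w - 1) %/% 2
  if (h == 0) return(x)
  xp <- c(tail(x, h), x, head(x, h))
  as.numeric(stats::filter(xp, rep(1 / w, w), sides = 2))[(h + 1):(h + n)]
}

# peaks of a circular series with topographic prominence >= minProm;
# plateaus count once (sign of the circular difference carried forward)
circularPeaks <- function(s, minProm) {
  n <- length(s)
  if (n < 3 || diff(range(s)) == 0) return(integer(0))
  sg <- sign(s[c(2:n, 1)] - s)  # sg[i]: slope leaving point i
  if (!any(sg != 0)) return(integer(0))
  filled <- sg
  last <- filled[max(which(sg != 0))]
  for (pass in 1:2) for (i in seq_len(n)) {
    if (filled[i] == 0) filled[i] <- last else last <- filled[i]
  }
  prevSlope <- filled[c(n, 1:(n - 1))]
  peaks <- which(prevSlope > 0 & filled < 0)
  keep <- logical(length(peaks))
  for (k in seq_along(peaks)) {
    p <- peaks[k]; v <- s[p]
    valley <- c(NA_real_, NA_real_)
    for (side in 1:2) {
      dir <- if (side == 1) -1L else 1L
      mn <- v; i <- p
      for (step in seq_len(n - 1)) {
        i <- ((i - 1 + dir) %% n) + 1
        if (s[i] > v) break
        mn <- min(mn, s[i])
      }
      valley[side] <- mn
    }
    prom <- v - max(valley)
    if (p == which.max(s)[1]) prom <- v - min(s)  # global max: full drop
    keep[k] <- prom >= minProm
  }
  peaks[keep]
}

# minimum-area rotated bounding rectangle side lengths (rotating calipers
# over the convex hull of the boundary points)
minAreaRectSides <- function(xy) {
  h <- grDevices::chull(xy)
  hull <- xy[h, , drop = FALSE]
  nh <- nrow(hull)
  best <- c(Inf, NA, NA)
  for (i in seq_len(nh)) {
    j <- i %% nh + 1
    e <- hull[j, ] - hull[i, ]
    len <- sqrt(sum(e^2))
    if (len == 0) next
    u <- e / len
    v <- c(-u[2], u[1])
    pu <- hull %*% u
    pv <- hull %*% v
    w <- diff(range(pu)); hgt <- diff(range(pv))
    if (w * hgt < best[1]) best <- c(w * hgt, w, hgt)
  }
  sort(best[2:3], decreasing = TRUE)
}

ramanujanPerimeter <- function(a, b) {
  pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
}

#' The 13 shape features of a lesion mask
#'
#' Computes the classic normalized-radial-length (NRL) morphometry panel on
#' a single-component binary mask. The features, in fixed column order:
#' \describe{
#'   \item{roundness}{\eqn{4\pi A / P^2}, pixel area over squared contour
#'     perimeter (polygon length of the angle-ordered boundary).}
#'   \item{bbox_aspect_ratio}{long/short side of the minimum-area rotated
#'     bounding rectangle.}
#'   \item{nrl_mean, nrl_sd}{mean and population SD of the NRL profile.}
#'   \item{nrl_entropy}{Shannon entropy (bits) of a 10-bin NRL histogram
#'     on [0, 1].}
#'   \item{area_ratio}{\eqn{\sum_i \max(nd_i - \bar{nd}, 0) / (\bar{nd} N)},
#'     the excess-radius fraction above the mean radius.}
#'   \item{elongation}{major/minor axis ratio of the inertia-equivalent
#'     ellipse (from second central moments).}
#'   \item{leaflet_count}{number of NRL local maxima after circular
#'     moving-average smoothing (window N/16, min 3) with topographic
#'     prominence >= 0.05.}
#'   \item{spiculation}{density of sign changes of the first circular NRL
#'     difference; differences smaller than one pixel of radial change are
#'     treated as flat, so the count reflects structure rather than
#'     contour quantization jitter.}
#'   \item{boundary_roughness}{mean absolute first circular NRL
#'     difference.}
#'   \item{direction_angle}{orientation of the principal inertia axis in
#'     [0, pi), measured from the column axis in pixel coordinates.}
#'   \item{norm_ellipse_circumference}{contour perimeter divided by the
#'     Ramanujan perimeter of the inertia-equivalent ellipse.}
#'   \item{norm_ellipse_contour}{Jaccard overlap between the mask and its
#'     inertia-equivalent ellipse rendered at the same centroid and
#'     orientation.}
#' }
#' All features are dimensionless or angular, so the panel is
#' scale-invariant up to pixelization.
#'
#' @param mask binary matrix (single 8-connected component).
#' @return named numeric vector of length 13.
#' @export
#' @examples
#' sq <- matrix(0, 32, 32); sq[9:24, 9:24] <- 1
#' shapeFeatures(sq)[["bbox_aspect_ratio"]]
shapeFeatures <- function(mask) {
  rp <- radialProfile(mask)
  m <- matrix(as.integer(mask > 0), nrow(mask), ncol(mask))
  nd <- rp$nd
  N <- length(nd)
  A <- sum(m)
  b <- rp$boundary
  # light (1/4, 1/2, 1/4) circular average of the boundary polygon before
  # measuring its length: removes the half-pixel zigzag of the digitized
  # contour, which otherwise inflates the perimeter by a few percent even
  # for a perfect disk
  bs <- b / 2 + b[c(2:N, 1), , drop = FALSE] / 4 + b[c(N, 1:(N - 1)), , drop = FALSE] / 4
  P <- sum(sqrt(rowSums((bs - bs[c(2:N, 1), , drop = FALSE])^2)))

  ndMean <- mean(nd)
  ndSD <- sqrt(mean((nd - ndMean)^2))
  cnt <- tabulate(pmin(floor(nd * 10) + 1, 10), 10)
  p <- cnt / N
  ent <- -sum(ifelse(p > 0, p * log2(p), 0))
  areaRatio <- sum(pmax(nd - ndMean, 0)) / (ndMean * N)

  px <- which(m == 1L, arr.ind = TRUE)
  dy <- px[, 1] - rp$centroid[1]
  dx <- px[, 2] - rp$centroid[2]
  mu20 <- mean(dx^2); mu02 <- mean(dy^2); mu11 <- mean(dx * dy)
  tr <- mu20 + mu02
  det2 <- sqrt(max((mu20 - mu02)^2 + 4 * mu11^2, 0))
  l1 <- (tr + det2) / 2
  l2 <- max((tr - det2) / 2, 1e-12)
  elong <- sqrt(l1 / l2)
  dirAngle <- 0.5 * atan2(2 * mu11, mu20 - mu02)
  dirAngle <- dirAngle %% pi
  aAx <- 2 * sqrt(l1)  # semi-axes of the inertia-equivalent solid ellipse
  bAx <- 2 * sqrt(l2)

  sm <- circularSmooth(nd, max(3, round(N / 16)))
  leaflets <- length(circularPeaks(sm, 0.05))

  dd <- nd[c(2:N, 1)] - nd
  sg <- sign(dd)
  # radial changes below one pixel are contour quantization noise, not
  # structure; treating them as flat keeps the crossing count scale-free
  sg[abs(dd) < 1 / max(rp$d)] <- 0
  sgNZ <- sg[sg != 0]
  spic <- if (length(sgNZ) < 2) 0 else
    sum(sgNZ != sgNZ[c(2:length(sgNZ), 1)]) / N
  rough <- mean(abs(dd))

  sides <- minAreaRectSides(cbind(b[, 2], b[, 1]))
  bboxAR <- sides[1] / max(sides[2], 1e-12)

  # inertia-equivalent ellipse rendered on the same grid
  rows <- matrix(rep(seq_len(nrow(m)), times = ncol(m)), nrow(m))
  cols <- matrix(rep(seq_len(ncol(m)), each = nrow(m)), nrow(m))
  ddy <- rows - rp$centroid[1]
  ddx <- cols - rp$centroid[2]
  # principal axis direction measured with the y axis flipped to match
  # atan2(-dy, dx) in radialProfile; dirAngle here uses image coordinates
  u <- cos(dirAngle) * ddx + sin(dirAngle) * ddy
  v <- -sin(dirAngle) * ddx + cos(dirAngle) * ddy
  ell <- (u / aAx)^2 + (v / bAx)^2 <= 1
  inter <- sum(ell & m == 1L)
  uni <- sum(ell | m == 1L)

  c(roundness = 4 * pi * A / P^2,
    bbox_aspect_ratio = bboxAR,
    nrl_mean = ndMean,
    nrl_sd = ndSD,
    nrl_entropy = ent,
    area_ratio = areaRatio,
    elongation = elong,
    leaflet_count = leaflets,
    spiculation = spic,
    boundary_roughness = rough,
    direction_angle = dirAngle,
    norm_ellipse_circumference = P / ramanujanPerimeter(aAx, bAx),
    norm_ellipse_contour = inter / uni)
}

#' Names of the 13 shape feature columns, in canonical order
#' @return character vector of length 13.
#' @export
shapeFeatureNames <- function() {
  c("roundness", "bbox_aspect_ratio", "nrl_mean", "nrl_sd", "nrl_entropy",
    "area_ratio", "elongation", "leaflet_count", "spiculation",
    "boundary_roughness", "direction_angle", "norm_ellipse_circumference",
    "norm_ellipse_contour")
}
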