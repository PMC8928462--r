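# Fixtures are built in code; no binary data ships with the package.

diskMask <- function(r, S = 2 * ceiling(r) + 12) {
  ctr <- (S + 1) / 2
  m <- matrix(0, S, S)
  m[(row(m) - ctr)^2 + (col(m) - ctr)^2 <= r^2] <- 1
  m
}

# solid ellipse with semi-axes a >= b, orientation theta (radians, measured
# from the column axis in pixel coordinates)
ellipseMask <- function(a, b, theta = 0, S = 2 * ceiling(a) + 12) {
  ctr <- (S + 1) / 2
  dy <- row(matrix(0, S, S)) - ctr
  dx <- col(matrix(0, S, S)) - ctr
  u <- cos(theta) * dx + sin(theta) * dy
  v <- -sin(theta) * dx + cos(theta) * dy
  m <- matrix(0, S, S)
  m[(u / a)^2 + (v / b)^2 <= 1] <- 1
  m
}

rotate90 <- function(m) t(m)[, nrow(m):1]

# brute-force GLCM oracle: loop over every pixel pair at the offset,
# returning raw symmetrized integer counts
bruteGLCMCounts <- function(q, levels, distance, angle) {
  off <- switch(as.character(angle),
                "0" = c(0, distance), "45" = c(-distance, distance),
                "90" = c(-distance, 0), "135" = c(-distance, -distance))
  cnt <- matrix(0L, levels, levels)
  for (i in seq_len(nrow(q))) for (j in seq_len(ncol(q))) {
    i2 <- i + off[1]; j2 <- j + off[2]
    if (i2 < 1 || i2 > nrow(q) || j2 < 1 || j2 > ncol(q)) next
    a <- q[i, j]; b <- q[i2, j2]
    if (is.na(a) || is.na(b)) next
    cnt[a + 1, b + 1] <- cnt[a + 1, b + 1] + 1L
  }
  cnt + t(cnt)
}

# brute-force AUC oracle: concordance over all positive x negative pairs
bruteAUC <- function(scores, positive) {
  sp <- scores[positive]; sn <- scores[!positive]
  tot <- 0
  for (x in sp) for (y in sn) tot <- tot + (x > y) + 0.5 * (x == y)
  tot / (length(sp) * length(sn))
}

# small high-contrast phantoms for segmentation runs
easySegPhantom <- function(seed) {
  set.seed(seed)
  makePhantom(phantomSpec(
    imageSize = 32L, baseRadius = runif(1, 6, 9),
    lobulationOrder = sample(2:4, 1), lobulationAmp = runif(1, 0, 0.15),
    spiculeCount = 0L, noiseSD = 6, seed = seed))
}

table1SubtypeCounts <- function() {
  c(LuminalA = 105L, LuminalB = 178L, `HER2+` = 101L, TN = 86L)
}

smallSubtypeCounts <- function(n) {
  base <- c(LuminalA = 0L, LuminalB = 0L, `HER2+` = 0L, TN = 0L)
  base + tabulate(rep_len(1:4, n), 4)
}
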