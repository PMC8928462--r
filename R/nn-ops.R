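# Internal building blocks of the convolutional encoder-decoder.
#
# Feature maps are stored as (H*W) x C matrices with pixels in the
# column-major order of the underlying H x W image matrix. Convolutions are
# evaluated as matrix products against an im2col expansion whose gather
# indices depend only on (H, W), so all index geometry is precomputed once
# per resolution level and shared across epochs and images.

# gather/scatter geometry for one resolution (3x3 conv, zero padding 1)
convGeometry <- function(H, W) {
  Hp <- H + 2L
  rr <- rep(seq_len(H), times = W)
  cc <- rep(seq_len(W), each = H)
  core <- (rr + 1L) + cc * Hp
  nbr <- matrix(0L, H * W, 9L)
  k <- 0L
  for (dc in -1:1) for (dr in -1:1) {
    k <- k + 1L
    nbr[, k] <- (rr + 1L + dr) + (cc + dc) * Hp
  }
  list(H = H, W = W, Hp = Hp, Wp = W + 2L, core = core, nbr = nbr)
}

# child linear indices of each 2x2 block: parent grid oH x oW inside an
# image of height H = 2*oH
poolGeometry <- function(H, W) {
  oH <- H %/% 2L; oW <- W %/% 2L
  or <- rep(seq_len(oH), times = oW)
  oc <- rep(seq_len(oW), each = oH)
  list(oH = oH, oW = oW,
       i11 = (2L * or - 1L) + (2L * oc - 2L) * H,
       i21 = (2L * or) + (2L * oc - 2L) * H,
       i12 = (2L * or - 1L) + (2L * oc - 1L) * H,
       i22 = (2L * or) + (2L * oc - 1L) * H)
}

im2col <- function(x, geom) {
  Cin <- ncol(x)
  xpad <- matrix(0, geom$Hp * geom$Wp, Cin)
  xpad[geom$core, ] <- x
  M <- xpad[as.vector(geom$nbr), , drop = FALSE]
  dim(M) <- c(nrow(x), 9L * Cin)  # columns ordered (offset, channel)
  M
}

col2im <- function(dXcol, Cin, geom) {
  dxpad <- matrix(0, geom$Hp * geom$Wp, Cin)
  for (k in 1:9) {
    cols <- seq.int(k, 9L * Cin, by = 9L)
    dxpad[geom$nbr[, k], ] <- dxpad[geom$nbr[, k], ] +
      dXcol[, cols, drop = FALSE]
  }
  dxpad[geom$core, , drop = FALSE]
}

# residual conv unit: relu(conv3x3(x) + conv1x1(x) + b); the 1x1 path is
# the (projection) shortcut, so the unit degrades gracefully to a linear
# map when the 3x3 kernel is uninformative
resconvForward <- function(x, layer, geom) {
  Xcol <- im2col(x, geom)
  z <- Xcol %*% layer$W3 + x %*% layer$W1 +
    matrix(layer$b, nrow(x), length(layer$b), byrow = TRUE)
  list(out = z * (z > 0), Xcol = Xcol, x = x, z = z)
}

resconvBackward <- function(dOut, layer, cache, geom) {
  dz <- dOut * (cache$z > 0)
  list(dW3 = crossprod(cache$Xcol, dz),
       dW1 = crossprod(cache$x, dz),
       db = colSums(dz),
       dx = col2im(dz %*% t(layer$W3), ncol(cache$x), geom) +
         dz %*% t(layer$W1))
}

maxpoolForward <- function(x, pg) {
  m <- x[pg$i11, , drop = FALSE]
  arg <- matrix(1L, nrow(m), ncol(m))
  kidx <- list(pg$i11, pg$i21, pg$i12, pg$i22)
  for (k in 2:4) {
    cand <- x[kidx[[k]], , drop = FALSE]
    upd <- cand > m
    m[upd] <- cand[upd]
    arg[upd] <- k
  }
  list(out = m, arg = arg, n = nrow(x))
}

maxpoolBackward <- function(dOut, cache, pg) {
  dx <- matrix(0, cache$n, ncol(dOut))
  kidx <- list(pg$i11, pg$i21, pg$i12, pg$i22)
  for (k in 1:4) {
    dx[kidx[[k]], ] <- dx[kidx[[k]], ] + dOut * (cache$arg == k)
  }
  dx
}

upsampleForward <- function(x, pg) {
  y <- matrix(0, 4L * nrow(x), ncol(x))
  y[pg$i11, ] <- x; y[pg$i21, ] <- x; y[pg$i12, ] <- x; y[pg$i22, ] <- x
  y
}

upsampleBackward <- function(dOut, pg) {
  dOut[pg$i11, , drop = FALSE] + dOut[pg$i21, , drop = FALSE] +
    dOut[pg$i12, , drop = FALSE] + dOut[pg$i22, , drop = FALSE]
}

initResconv <- function(Cin, Cout) {
  list(W3 = matrix(rnorm(9 * Cin * Cout, sd = sqrt(2 / (9 * Cin))),
                   9 * Cin, Cout),
       W1 = matrix(rnorm(Cin * Cout, sd = sqrt(2 / Cin)), Cin, Cout),
       b = rep(0, Cout))
}

# build parameter list for depth D, base channels C, single input channel
initUnetParams <- function(depth, baseChannels) {
  ch <- baseChannels * 2^(seq_len(depth) - 1)
  p <- list(enc = vector("list", depth), dec = vector("list", depth))
  inCh <- 1L
  for (d in seq_len(depth)) {
    p$enc[[d]] <- initResconv(inCh, ch[d])
    inCh <- ch[d]
  }
  p$bottleneck <- initResconv(ch[depth], 2L * ch[depth])
  up <- 2L * ch[depth]
  for (d in rev(seq_len(depth))) {
    p$dec[[d]] <- initResconv(up + ch[d], ch[d])
    up <- ch[d]
  }
  p$head <- list(W = matrix(rnorm(ch[1], sd = sqrt(1 / ch[1])), ch[1], 1),
                 b = 0)
  p
}

# geometry for every resolution level 0..depth
unetGeometry <- function(H, W, depth) {
  conv <- vector("list", depth + 1)
  pool <- vector("list", depth)
  h <- H; w <- W
  for (l in 0:depth) {
    conv[[l + 1]] <- convGeometry(h, w)
    if (l < depth) {
      pool[[l + 1]] <- poolGeometry(h, w)
      h <- h %/% 2L; w <- w %/% 2L
    }
  }
  list(conv = conv, pool = pool)
}

# full forward pass; x is an (H*W) x 1 matrix of normalized intensities
unetForward <- function(x, params, geom, depth) {
  skips <- caches <- vector("list", depth)
  cur <- x
  for (d in seq_len(depth)) {
    cc <- resconvForward(cur, params$enc[[d]], geom$conv[[d]])
    caches[[d]] <- cc
    skips[[d]] <- cc$out
    pl <- maxpoolForward(cc$out, geom$pool[[d]])
    caches[[d]]$pool <- pl
    cur <- pl$out
  }
  bn <- resconvForward(cur, params$bottleneck, geom$conv[[depth + 1]])
  cur <- bn$out
  decCaches <- vector("list", depth)
  for (d in rev(seq_len(depth))) {
    up <- upsampleForward(cur, geom$pool[[d]])
    cat_ <- cbind(up, skips[[d]])
    dc <- resconvForward(cat_, params$dec[[d]], geom$conv[[d]])
    dc$upCols <- ncol(up)
    decCaches[[d]] <- dc
    cur <- dc$out
  }
  logits <- cur %*% params$head$W + params$head$b
  list(logits = logits, enc = caches, bottleneck = bn, dec = decCaches,
       headIn = cur)
}

# full backward pass from dLogits; returns gradients shaped like params
unetBackward <- function(dLogits, fw, params, geom, depth) {
  g <- list(enc = vector("list", depth), dec = vector("list", depth))
  g$head <- list(W = crossprod(fw$headIn, dLogits),
                 b = sum(dLogits))
  cur <- dLogits %*% t(params$head$W)
  dskip <- vector("list", depth)
  for (d in seq_len(depth)) {
    bb <- resconvBackward(cur, params$dec[[d]], fw$dec[[d]], geom$conv[[d]])
    g$dec[[d]] <- list(W3 = bb$dW3, W1 = bb$dW1, b = bb$db)
    nUp <- fw$dec[[d]]$upCols
    dskip[[d]] <- bb$dx[, (nUp + 1):ncol(bb$dx), drop = FALSE]
    # gradient wrt the deeper tensor: decoder block d+1's output, or the
    # bottleneck output when d == depth (loop runs shallow to deep)
    cur <- upsampleBackward(bb$dx[, 1:nUp, drop = FALSE], geom$pool[[d]])
  }
  bb <- resconvBackward(cur, params$bottleneck, fw$bottleneck,
                        geom$conv[[depth + 1]])
  g$bottleneck <- list(W3 = bb$dW3, W1 = bb$dW1, b = bb$db)
  cur <- bb$dx
  for (d in rev(seq_len(depth))) {
    dpool <- maxpoolBackward(cur, fw$enc[[d]]$pool, geom$pool[[d]])
    dact <- dpool + dskip[[d]]
    bb <- resconvBackward(dact, params$enc[[d]], fw$enc[[d]],
                          geom$conv[[d]])
    g$enc[[d]] <- list(W3 = bb$dW3, W1 = bb$dW1, b = bb$db)
    cur <- bb$dx
  }
  g
}

# Adam with additive L2 weight decay; params/grads share one nested shape
adamInit <- function(params) rapply(params, function(p) p * 0, how = "replace")

adamStep <- function(params, grads, mState, vState, lr, wd, t,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      if (!is.null(names(p)) && !is.null(names(g))) g <- g[names(p)]
      out <- mapply(walk, p, g, m, v, SIMPLIFY = FALSE)
      return(list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    g <- g + wd * p
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  walk(params, grads, mState, vState)
}
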