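# Minimal convolutional network primitives used by the bundled U-Net
# predictor: im2col-based 2D/3D convolution, 2x max pooling, nearest
# upsampling, channel concatenation and Adam. Feature maps are arrays with
# nd spatial dimensions followed by a channel dimension; single-sample
# forward/backward with gradient accumulation across a mini-batch.

.newConv <- function(k, nd, cIn, cOut, relu) {
  fanIn <- k^nd * cIn
  L <- new.env(parent = emptyenv())
  L$k <- k; L$nd <- nd; L$cIn <- cIn; L$cOut <- cOut; L$relu <- relu
  L$W <- matrix(stats::rnorm(fanIn * cOut, sd = sqrt(2 / fanIn)), fanIn, cOut)
  L$b <- numeric(cOut)
  L$mW <- matrix(0, fanIn, cOut); L$vW <- matrix(0, fanIn, cOut)
  L$mb <- numeric(cOut); L$vb <- numeric(cOut)
  L$gW <- matrix(0, fanIn, cOut); L$gb <- numeric(cOut)
  L
}

.im2col <- function(x, nd) {
  d <- dim(x)
  sp <- d[seq_len(nd)]
  C <- d[nd + 1L]
  P <- prod(sp)
  if (nd == 2L) {
    xp <- array(0, c(sp[1] + 2L, sp[2] + 2L, C))
    xp[1L + seq_len(sp[1]), 1L + seq_len(sp[2]), ] <- x
    cols <- matrix(0, P, 9L * C)
    j <- 0L
    for (c in seq_len(C)) for (dj in 0:2) for (di in 0:2) {
      j <- j + 1L
      cols[, j] <- xp[di + seq_len(sp[1]), dj + seq_len(sp[2]), c]
    }
  } else {
    xp <- array(0, c(sp + 2L, C))
    xp[1L + seq_len(sp[1]), 1L + seq_len(sp[2]), 1L + seq_len(sp[3]), ] <- x
    cols <- matrix(0, P, 27L * C)
    j <- 0L
    for (c in seq_len(C)) for (dk in 0:2) for (dj in 0:2) for (di in 0:2) {
      j <- j + 1L
      cols[, j] <- xp[di + seq_len(sp[1]), dj + seq_len(sp[2]),
                      dk + seq_len(sp[3]), c]
    }
  }
  cols
}

.col2im <- function(dcols, sp, C, nd) {
  if (nd == 2L) {
    dxp <- array(0, c(sp[1] + 2L, sp[2] + 2L, C))
    j <- 0L
    for (c in seq_len(C)) for (dj in 0:2) for (di in 0:2) {
      j <- j + 1L
      ri <- di + seq_len(sp[1]); rj <- dj + seq_len(sp[2])
      dxp[ri, rj, c] <- dxp[ri, rj, c] + matrix(dcols[, j], sp[1], sp[2])
    }
    dxp[1L + seq_len(sp[1]), 1L + seq_len(sp[2]), , drop = FALSE]
  } else {
    dxp <- array(0, c(sp + 2L, C))
    j <- 0L
    for (c in seq_len(C)) for (dk in 0:2) for (dj in 0:2) for (di in 0:2) {
      j <- j + 1L
      ri <- di + seq_len(sp[1]); rj <- dj + seq_len(sp[2])
      rk <- dk + seq_len(sp[3])
      dxp[ri, rj, rk, c] <- dxp[ri, rj, rk, c] +
        array(dcols[, j], sp)
    }
    dxp[1L + seq_len(sp[1]), 1L + seq_len(sp[2]), 1L + seq_len(sp[3]), ,
        drop = FALSE]
  }
}

.convForward <- function(L, x) {
  d <- dim(x)
  sp <- d[seq_len(L$nd)]
  cols <- if (L$k == 1L) matrix(x, prod(sp), L$cIn) else .im2col(x, L$nd)
  y <- cols %*% L$W
  y <- sweep(y, 2L, L$b, "+")
  act <- NULL
  if (L$relu) {
    act <- y > 0
    y <- y * act
  }
  list(y = array(y, c(sp, L$cOut)), cache = list(cols = cols, act = act, sp = sp))
}

.convBackward <- function(L, cache, dY) {
  sp <- cache$sp
  dy <- matrix(dY, prod(sp), L$cOut)
  if (L$relu) dy <- dy * cache$act
  L$gW <- L$gW + crossprod(cache$cols, dy)
  L$gb <- L$gb + colSums(dy)
  dcols <- dy %*% t(L$W)
  if (L$k == 1L) array(dcols, c(sp, L$cIn))
  else .col2im(dcols, sp, L$cIn, L$nd)
}

.poolOffsets <- function(nd) {
  if (nd == 2L) as.matrix(expand.grid(di = 0:1, dj = 0:1))
  else as.matrix(expand.grid(di = 0:1, dj = 0:1, dk = 0:1))
}

.poolForward <- function(x, nd) {
  d <- dim(x)
  sp <- d[seq_len(nd)]
  offs <- .poolOffsets(nd)
  sel <- lapply(seq_len(nd), function(i) seq(1L, sp[i], by = 2L))
  y <- NULL; arg <- NULL
  for (i in seq_len(nrow(offs))) {
    cand <- if (nd == 2L)
      x[sel[[1]] + offs[i, 1], sel[[2]] + offs[i, 2], , drop = FALSE]
    else
      x[sel[[1]] + offs[i, 1], sel[[2]] + offs[i, 2],
        sel[[3]] + offs[i, 3], , drop = FALSE]
    if (is.null(y)) {
      y <- cand
      arg <- array(1L, dim(cand))
    } else {
      better <- cand > y
      y[better] <- cand[better]
      arg[better] <- i
    }
  }
  list(y = y, cache = list(arg = arg, sp = sp))
}

.poolBackward <- function(cache, dY, nd) {
  sp <- cache$sp
  C <- dim(dY)[nd + 1L]
  offs <- .poolOffsets(nd)
  sel <- lapply(seq_len(nd), function(i) seq(1L, sp[i], by = 2L))
  dX <- array(0, c(sp, C))
  for (i in seq_len(nrow(offs))) {
    routed <- dY * (cache$arg == i)
    if (nd == 2L)
      dX[sel[[1]] + offs[i, 1], sel[[2]] + offs[i, 2], ] <- routed
    else
      dX[sel[[1]] + offs[i, 1], sel[[2]] + offs[i, 2],
         sel[[3]] + offs[i, 3], ] <- routed
  }
  dX
}

.upForward <- function(x, nd) {
  d <- dim(x)
  if (nd == 2L)
    x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), ,
      drop = FALSE]
  else
    x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L),
      rep(seq_len(d[3]), each = 2L), , drop = FALSE]
}

.upBackward <- function(dY, nd) {
  d <- dim(dY)
  sp <- d[seq_len(nd)] %/% 2L
  offs <- .poolOffsets(nd)
  sel <- lapply(seq_len(nd), function(i) seq(1L, d[i], by = 2L))
  dX <- NULL
  for (i in seq_len(nrow(offs))) {
    part <- if (nd == 2L)
      dY[sel[[1]] + offs[i, 1], sel[[2]] + offs[i, 2], , drop = FALSE]
    else
      dY[sel[[1]] + offs[i, 1], sel[[2]] + offs[i, 2],
         sel[[3]] + offs[i, 3], , drop = FALSE]
    dX <- if (is.null(dX)) part else dX + part
  }
  dX
}

.concatChannels <- function(a, b, nd) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[seq_len(nd)], da[nd + 1L] + db[nd + 1L]))
  if (nd == 2L) {
    out[, , seq_len(da[3])] <- a
    out[, , da[3] + seq_len(db[3])] <- b
  } else {
    out[, , , seq_len(da[4])] <- a
    out[, , , da[4] + seq_len(db[4])] <- b
  }
  out
}

.splitChannels <- function(x, c1, nd) {
  if (nd == 2L) list(x[, , seq_len(c1), drop = FALSE],
                     x[, , -seq_len(c1), drop = FALSE])
  else list(x[, , , seq_len(c1), drop = FALSE],
            x[, , , -seq_len(c1), drop = FALSE])
}

.zeroGrads <- function(layers) {
  for (L in layers) { L$gW[] <- 0; L$gb[] <- 0 }
  invisible(NULL)
}

.adamStep <- function(layers, lr, scale, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (L in layers) {
    gW <- L$gW * scale; gb <- L$gb * scale
    L$mW <- beta1 * L$mW + (1 - beta1) * gW
    L$vW <- beta2 * L$vW + (1 - beta2) * gW^2
    L$mb <- beta1 * L$mb + (1 - beta1) * gb
    L$vb <- beta2 * L$vb + (1 - beta2) * gb^2
    mWh <- L$mW / (1 - beta1^t); vWh <- L$vW / (1 - beta2^t)
    mbh <- L$mb / (1 - beta1^t); vbh <- L$vb / (1 - beta2^t)
    L$W <- L$W - lr * mWh / (sqrt(vWh) + eps)
    L$b <- L$b - lr * mbh / (sqrt(vbh) + eps)
  }
  invisible(NULL)
}
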