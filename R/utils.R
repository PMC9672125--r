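# Internal array helpers shared across modules.

# Translate a 3D array by an integer offset, filling vacated voxels.
# out[z] = a[z - off] where defined, else `fill`.
.shift3 <- function(a, off, fill) {
  d <- dim(a)
  out <- array(fill, d)
  idx <- vector("list", 3L)
  src <- vector("list", 3L)
  for (i in 1:3) {
    o <- off[i]
    if (o >= 0) {
      if (o >= d[i]) return(out)
      idx[[i]] <- (o + 1L):d[i]
      src[[i]] <- 1L:(d[i] - o)
    } else {
      if (-o >= d[i]) return(out)
      idx[[i]] <- 1L:(d[i] + o)
      src[[i]] <- (1L - o):d[i]
    }
  }
  out[idx[[1]], idx[[2]], idx[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

.checkCongruent <- function(a, b, what = "masks") {
  if (!identical(dim(a@data), dim(b@data)))
    stop(sprintf("%s are not congruent: shapes %s vs %s", what,
                 paste(dim(a@data), collapse = "x"),
                 paste(dim(b@data), collapse = "x")))
  invisible(TRUE)
}

# Evaluate expr under a temporary RNG seed, restoring global state after.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Derive a stream of child seeds from one master seed (kept < 2^31).
.childSeeds <- function(masterSeed, n) {
  .withSeed(masterSeed, sample.int(.Machine$integer.max - 1L, n))
}

# Label 6-connected foreground components by iterative minimum propagation,
# restricted to the foreground bounding box for speed.
# Returns an integer array: 0 = background, 1..m = component ids (renumbered).
.labelComponents <- function(mask) {
  d <- dim(mask)
  if (!any(mask)) return(array(0L, d))
  rng <- lapply(1:3, function(i) {
    hit <- which(apply(mask, i, any))
    range(hit)
  })
  sub <- mask[rng[[1]][1]:rng[[1]][2], rng[[2]][1]:rng[[2]][2],
              rng[[3]][1]:rng[[3]][2], drop = FALSE]
  labSub <- .labelCore(sub)
  lab <- array(0L, d)
  lab[rng[[1]][1]:rng[[1]][2], rng[[2]][1]:rng[[2]][2],
      rng[[3]][1]:rng[[3]][2]] <- labSub
  lab
}

.labelCore <- function(mask) {
  lab <- array(0L, dim(mask))
  lab[mask] <- seq_len(sum(mask))
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  repeat {
    nxt <- lab
    for (i in seq_len(nrow(offs))) {
      nb <- .shift3(lab, offs[i, ], 0L)
      upd <- mask & nb > 0L & (nxt == 0L | nb < nxt)
      nxt[upd] <- nb[upd]
    }
    if (identical(nxt, lab)) break
    lab <- nxt
  }
  ids <- sort(unique(lab[lab > 0L]))
  if (length(ids)) lab[lab > 0L] <- match(lab[lab > 0L], ids)
  lab
}

# Linear indices of voxels inside the ball of `radius` around `center`,
# clipped to the grid.
.ballIndices <- function(d, center, radius) {
  r <- ceiling(radius)
  rng <- lapply(1:3, function(i)
    max(1L, center[i] - r):min(d[i], center[i] + r))
  g <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
  keep <- (g[, 1] - center[1])^2 + (g[, 2] - center[2])^2 +
    (g[, 3] - center[3])^2 <= radius^2
  g <- g[keep, , drop = FALSE]
  g[, 1] + d[1] * (g[, 2] - 1L) + d[1] * d[2] * (g[, 3] - 1L)
}

.arrayInd3 <- function(idx, d) {
  cbind((idx - 1L) %% d[1] + 1L,
        ((idx - 1L) %/% d[1]) %% d[2] + 1L,
        (idx - 1L) %/% (d[1] * d[2]) + 1L)
}
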