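#' Configuration for the synthetic dental phantom
#'
#' Describes a CBCT-like head volume: a soft-tissue head cross-section
#' containing a parabolic bone arch carrying tooth units (enamel crown
#' ellipsoid over a dentin root cylinder), on an air background, with
#' additive Gaussian noise. Default intensities follow typical CT values:
#' air -1000, soft tissue 50, bone 1200, dentin 2000, enamel 2800, metal
#' 3100 HU; the default grid is 64^3 voxels at 0.19 mm isotropic spacing
#' with 6 teeth and 30 HU noise; the default tooth cross-sections (crown
#' semi-axes 3.5 voxels, root radius 2.5) are wide enough to survive a
#' radius-2 morphological opening, as real teeth do at CBCT resolution.
#'
#' @param shape integer length-3 grid extent.
#' @param spacing voxel size in mm (scalar or length 3).
#' @param nTeeth number of tooth units along the arch (>= 0).
#' @param crownSemiAxes ellipsoid semi-axes of the enamel crown, voxels.
#' @param rootRadius,rootLength dentin root cylinder radius/length, voxels.
#' @param intensities named HU values (air, soft, bone, dentin, enamel,
#'   metal), strictly increasing in that order.
#' @param noiseSd additive Gaussian noise SD in HU (0 = noiseless).
#' @param seed RNG seed; the phantom is a pure function of the config.
#' @return A list of class "phantomConfig".
#' @export
phantomConfig <- function(shape = c(64L, 64L, 64L), spacing = 0.19,
                          nTeeth = 6L,
                          crownSemiAxes = c(3.5, 3.5, 4.5),
                          rootRadius = 2.5, rootLength = 12,
                          intensities = c(air = -1000, soft = 50,
                                          bone = 1200, dentin = 2000,
                                          enamel = 2800, metal = 3100),
                          noiseSd = 30, seed = 1L) {
  cfg <- list(shape = as.integer(shape), spacing = spacing,
              nTeeth = as.integer(nTeeth), crownSemiAxes = crownSemiAxes,
              rootRadius = rootRadius, rootLength = rootLength,
              intensities = intensities, noiseSd = noiseSd,
              seed = as.integer(seed))
  class(cfg) <- "phantomConfig"
  need <- c("air", "soft", "bone", "dentin", "enamel", "metal")
  if (!all(need %in% names(intensities)))
    stop("config error: intensities must name ", paste(need, collapse = ", "))
  if (any(diff(intensities[need]) <= 0))
    stop("config error: intensities must be ordered air < soft < bone < dentin < enamel < metal")
  if (any(cfg$shape < 8L)) stop("config error: shape too small for a phantom")
  if (noiseSd < 0) stop("config error: noiseSd must be >= 0")
  cfg
}

#' Generate a synthetic dental phantom and its tooth ground truth
#'
#' Builds a dental-arch phantom: a parabolic bone arch inside a
#' soft-tissue head section on air, carrying \code{nTeeth} tooth units
#' (enamel crown ellipsoid over a dentin root cylinder), plus additive
#' Gaussian noise on the volume. The returned mask marks exactly the tooth
#' voxels (crown + root) and is noise-free. All outputs are pure functions
#' of the config (including its seed).
#'
#' @param cfg a \code{\link{phantomConfig}}.
#' @return A list: \code{volume} (\linkS4class{ScanVolume}), \code{mask}
#'   (\linkS4class{BinaryMask}).
#' @export
makePhantom <- function(cfg = phantomConfig()) {
  stopifnot(inherits(cfg, "phantomConfig"))
  d <- cfg$shape
  hu <- cfg$intensities
  a <- cfg$crownSemiAxes
  zRootBase <- round(0.25 * d[3])
  zCrownCtr <- zRootBase + cfg$rootLength + a[3]
  if (zCrownCtr + a[3] > d[3] || cfg$nTeeth > 0 &&
      (2 * max(a[1], cfg$rootRadius) + 2 > d[1]))
    stop("config error: tooth geometry overflows the grid")
  xs <- slice.index(array(0L, d), 1L)
  ys <- slice.index(array(0L, d), 2L)
  zs <- slice.index(array(0L, d), 3L)
  cx <- (d[1] + 1) / 2
  cy <- (d[2] + 1) / 2
  soft <- ((xs - cx) / (0.47 * d[1]))^2 + ((ys - cy) / (0.47 * d[2]))^2 <= 1
  # dental arch: parabola y(x) opening toward the back of the head
  x0 <- 0.22 * d[1]
  x1 <- 0.78 * d[1]
  yApex <- 0.28 * d[2]
  curv <- (0.62 - 0.28) * d[2] / ((x1 - cx)^2)
  yArch <- yApex + curv * (xs - cx)^2
  bone <- soft & abs(ys - yArch) <= max(2.5, 0.05 * d[2]) &
    zs >= zRootBase - 2 & zs <= zCrownCtr + a[3]
  dentin <- array(FALSE, d)
  enamel <- array(FALSE, d)
  if (cfg$nTeeth > 0L) {
    txs <- if (cfg$nTeeth == 1L) cx else seq(x0, x1, length.out = cfg$nTeeth)
    for (i in seq_len(cfg$nTeeth)) {
      xi <- txs[i]
      yi <- yApex + curv * (xi - cx)^2
      root <- (xs - xi)^2 + (ys - yi)^2 <= cfg$rootRadius^2 &
        zs >= zRootBase & zs < zRootBase + cfg$rootLength
      crown <- ((xs - xi) / a[1])^2 + ((ys - yi) / a[2])^2 +
        ((zs - zCrownCtr) / a[3])^2 <= 1
      dentin <- dentin | root
      enamel <- enamel | crown
    }
    enamel <- enamel & !dentin  # root interior stays dentin
  }
  vol <- array(hu[["air"]], d)
  vol[soft] <- hu[["soft"]]
  vol[bone] <- hu[["bone"]]
  vol[dentin] <- hu[["dentin"]]
  vol[enamel] <- hu[["enamel"]]
  if (cfg$noiseSd > 0)
    vol <- vol + .withSeed(cfg$seed, array(stats::rnorm(prod(d), 0, cfg$noiseSd), d))
  list(volume = ScanVolume(vol, cfg$spacing),
       mask = BinaryMask(dentin | enamel, cfg$spacing))
}

#' Insert metallic voxels next to tooth crowns
#'
#' Sets \code{nVoxels} crown-adjacent voxels (neighbours of enamel-density
#' voxels that are themselves below the enamel threshold) to the metal HU
#' value, emulating metallic implants/braces/crowns so MDB screening can
#' be exercised with exact voxel counts.
#'
#' @param vol a \linkS4class{ScanVolume} (typically a phantom).
#' @param nVoxels number of voxels to convert (0 = unchanged).
#' @param seed RNG seed for the placement.
#' @param metalHU HU value written (default 3100).
#' @param enamelThreshold HU level defining enamel-density voxels
#'   (default 2500).
#' @return The modified \linkS4class{ScanVolume}.
#' @export
addMetal <- function(vol, nVoxels, seed = 1L, metalHU = 3100,
                     enamelThreshold = 2500) {
  stopifnot(is(vol, "ScanVolume"))
  if (nVoxels == 0) return(vol)
  a <- vol@data
  enamel <- a > enamelThreshold
  near <- .dilateArr(enamel, structuringBall(1.5)) & !enamel
  cand <- which(near)
  if (length(cand) < nVoxels)
    stop("config error: only ", length(cand),
         " crown-adjacent voxels available for ", nVoxels, " metal voxels")
  pick <- .withSeed(seed, sample(cand, nVoxels))
  a[pick] <- metalHU
  ScanVolume(a, vol@spacing)
}

.dilateArr <- function(arr, B) {
  out <- NULL
  for (i in seq_len(nrow(B@offsets))) {
    s <- .shift3(arr, B@offsets[i, ], FALSE)
    out <- if (is.null(out)) s else out | s
  }
  out
}

#' Configuration of prediction degradation
#'
#' Error model for simulated segmentation predictions, mirroring the modes
#' single models show on real scans: diminutive false-positive speckles on
#' tooth-free tissue, partial false-negative dropout of tooth components,
#' and boundary jitter.
#'
#' @param fpSpeckleRate expected FP speckles per axial slice (Poisson).
#' @param speckleSize speckle ball radius in voxels (default 1, i.e. 7
#'   voxels - strictly smaller than the radius-2 opening element, so E&D
#'   provably removes them).
#' @param fnDropRate probability that a connected tooth component is
#'   partially eroded (a radius-2 ball removed around a random voxel).
#' @param boundaryJitter radius of random local grow/shrink patches on the
#'   mask boundary (0 disables).
#' @param seed RNG seed.
#' @return A list of class "degradationConfig".
#' @export
degradationConfig <- function(fpSpeckleRate = 0.5, speckleSize = 1L,
                              fnDropRate = 0.1, boundaryJitter = 0L,
                              seed = 1L) {
  if (fpSpeckleRate < 0) stop("config error: fpSpeckleRate must be >= 0")
  if (speckleSize < 1) stop("config error: speckleSize must be >= 1")
  if (fnDropRate < 0 || fnDropRate > 1)
    stop("config error: fnDropRate must lie in [0, 1]")
  structure(list(fpSpeckleRate = fpSpeckleRate,
                 speckleSize = as.integer(speckleSize),
                 fnDropRate = fnDropRate,
                 boundaryJitter = as.integer(boundaryJitter),
                 seed = as.integer(seed)),
            class = "degradationConfig")
}

# Deterministic per-truth quantities shared by every degradation draw:
# component labels, boundary voxels and the speckle exclusion zone.
.degradePrecomp <- function(gt, cfg) {
  list(
    boundary = if (any(gt))
      which(gt & .dilateArr(!gt, structuringBall(1))) else integer(0),
    lab = if (cfg$fnDropRate > 0 && any(gt)) .labelComponents(gt) else NULL,
    excl = if (any(gt)) .dilateArr(gt, structuringBall(cfg$speckleSize + 1))
           else gt)
}

# Draw the degradation event stream for one realisation. `scale` thins the
# Poisson rates and the component-drop probability (used to mix shared and
# private error streams when simulating correlated voters).
.degradeEvents <- function(gt, cfg, seed, scale = 1, pre = NULL) {
  d <- dim(gt)
  if (scale <= 0) return(list())
  if (is.null(pre)) pre <- .degradePrecomp(gt, cfg)
  .withSeed(seed, {
    events <- list()
    if (cfg$boundaryJitter > 0L && any(gt)) {
      boundary <- pre$boundary
      fgSlices <- sum(apply(gt, 3L, any))
      nJit <- stats::rpois(1L, 0.5 * scale * fgSlices)
      if (length(boundary) && nJit > 0) {
        ctr <- sample(boundary, nJit, replace = TRUE)
        grow <- stats::runif(nJit) < 0.5
        for (j in seq_len(nJit))
          events[[length(events) + 1L]] <- list(
            type = if (grow[j]) "grow" else "shrink",
            center = .arrayInd3(ctr[j], d)[1, ], radius = cfg$boundaryJitter)
      }
    }
    if (cfg$fnDropRate > 0 && any(gt)) {
      lab <- pre$lab
      for (comp in seq_len(max(lab))) {
        if (stats::runif(1) >= cfg$fnDropRate * scale) next
        vox <- which(lab == comp)
        ctr <- vox[sample.int(length(vox), 1L)]
        events[[length(events) + 1L]] <- list(
          type = "drop", center = .arrayInd3(ctr, d)[1, ], radius = 2)
      }
    }
    if (cfg$fpSpeckleRate > 0) {
      excl <- pre$excl
      for (z in seq_len(d[3])) {
        n <- stats::rpois(1L, cfg$fpSpeckleRate * scale)
        if (n == 0L) next
        open <- which(!excl[, , z])
        if (!length(open)) next
        pick <- sample(open, min(n, length(open)), replace = FALSE)
        for (ix in pick) {
          events[[length(events) + 1L]] <- list(
            type = "speckle",
            center = c((ix - 1L) %% d[1] + 1L, (ix - 1L) %/% d[1] + 1L, z),
            radius = cfg$speckleSize)
        }
      }
    }
    events
  })
}

.applyEvents <- function(gt, events) {
  m <- gt
  d <- dim(m)
  ord <- c(grow = 1L, shrink = 2L, drop = 3L, speckle = 4L)
  types <- vapply(events, `[[`, character(1), "type")
  for (ev in events[order(ord[types])]) {
    idx <- .ballIndices(d, ev$center, ev$radius)
    m[idx] <- ev$type %in% c("grow", "speckle")
  }
  m
}

#' Degrade a ground-truth mask into a simulated prediction
#'
#' Applies, in order: boundary jitter (random local grow/shrink patches on
#' the mask boundary), false-negative dropout (radius-2 ball removed from
#' randomly chosen tooth components), and false-positive speckles (balls
#' of the configured radius planted on background at the configured
#' per-axial-slice Poisson rate, at least one speckle radius away from the
#' truth). Fully reproducible from the config's seed.
#'
#' @param gt ground-truth \linkS4class{BinaryMask}.
#' @param cfg a \code{\link{degradationConfig}}.
#' @param withLog also return the event log and speckle count.
#' @return A \linkS4class{BinaryMask}, or (with \code{withLog}) a list
#'   \code{mask}, \code{nSpeckles}, \code{events}.
#' @export
degradePrediction <- function(gt, cfg, withLog = FALSE) {
  stopifnot(is(gt, "BinaryMask"), inherits(cfg, "degradationConfig"))
  events <- .degradeEvents(gt@data, cfg, cfg$seed, scale = 1)
  m <- .applyEvents(gt@data, events)
  mask <- BinaryMask(m, gt@spacing)
  if (!withLog) return(mask)
  types <- vapply(events, `[[`, character(1), "type")
  list(mask = mask, nSpeckles = sum(types == "speckle"), events = events)
}

#' Simulate a set of degraded voter predictions
#'
#' Generates one degraded mask per voter. Inter-voter error correlation
#' rho is realised by Poisson thinning: a shared error stream drawn at
#' rate rho * lambda is applied to every voter, and each voter adds a
#' private stream at rate (1 - rho) * lambda. With rho = 0 voter errors
#' are independent; with rho = 1 (and identical configs) all voters share
#' one error realisation and their masks are identical.
#'
#' @param gt ground-truth \linkS4class{BinaryMask}.
#' @param cfgs a single \code{\link{degradationConfig}} applied to every
#'   voter, or a named list with one config per voter (the first config
#'   drives the shared stream).
#' @param nVoters number of voters when \code{cfgs} is a single config.
#' @param rho inter-voter error correlation in [0, 1].
#' @param masterSeed seed from which all voter seeds derive.
#' @return A \linkS4class{PredictionSet} named voter1..voterK (or by the
#'   names of \code{cfgs}).
#' @export
simulatePredictionSet <- function(gt, cfgs, nVoters = NULL, rho = 0,
                                  masterSeed = 1L) {
  stopifnot(is(gt, "BinaryMask"))
  if (rho < 0 || rho > 1) stop("config error: rho must lie in [0, 1]")
  if (inherits(cfgs, "degradationConfig")) {
    if (is.null(nVoters)) stop("nVoters required with a single config")
    cfgs <- stats::setNames(rep(list(cfgs), nVoters),
                            paste0("voter", seq_len(nVoters)))
  }
  if (is.null(names(cfgs)))
    names(cfgs) <- paste0("voter", seq_along(cfgs))
  seeds <- .childSeeds(masterSeed, length(cfgs) + 1L)
  pre0 <- .degradePrecomp(gt@data, cfgs[[1]])
  preFor <- function(cfg) {
    if (identical(cfg$speckleSize, cfgs[[1]]$speckleSize) &&
        (cfg$fnDropRate > 0) == (cfgs[[1]]$fnDropRate > 0)) pre0
    else .degradePrecomp(gt@data, cfg)
  }
  shared <- if (rho > 0)
    .degradeEvents(gt@data, cfgs[[1]], seeds[1], scale = rho, pre = pre0)
  else list()
  masks <- lapply(seq_along(cfgs), function(i) {
    private <- if (rho < 1)
      .degradeEvents(gt@data, cfgs[[i]], seeds[i + 1L], scale = 1 - rho,
                     pre = preFor(cfgs[[i]]))
    else list()
    BinaryMask(.applyEvents(gt@data, c(shared, private)), gt@spacing)
  })
  names(masks) <- names(cfgs)
  PredictionSet(masks)
}
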