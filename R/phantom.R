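#' Calcium lesion specification for a CT phantom
#'
#' Describes one spherical calcified lesion assigned to a coronary artery
#' territory. A voxel belongs to the lesion iff its centre lies inside the
#' sphere. Lesions with `peakHu < 130` are permitted so that negative-control
#' phantoms (calcium below the scoring threshold) can be built deliberately.
#'
#' @slot artery One of "LM", "LAD", "LCX", "RCA".
#' @slot center Lesion centre in world coordinates (mm).
#' @slot radius Sphere radius (mm).
#' @slot peakHu Peak attenuation (HU).
#' @slot huProfile "uniform" (all lesion voxels at `peakHu`) or
#'   "radial-falloff" (linear decrease from `peakHu` at the centre to 130 at
#'   the sphere surface).
#'
#' @export
setClass("LesionSpec",
         representation(artery = "character", center = "numeric",
                        radius = "numeric", peakHu = "numeric",
                        huProfile = "character"))

setValidity("LesionSpec", function(object) {
  msg <- character()
  if (!object@artery %in% ARTERIES) msg <- c(msg, "unknown artery")
  if (length(object@center) != 3L) msg <- c(msg, "center must have 3 mm coordinates")
  if (object@radius <= 0) msg <- c(msg, "radius must be positive")
  if (!object@huProfile %in% c("uniform", "radial-falloff"))
    msg <- c(msg, "huProfile must be 'uniform' or 'radial-falloff'")
  if (length(msg)) msg else TRUE
})

#' @rdname LesionSpec-class
#' @param artery,center,radius,peakHu,huProfile See slot descriptions.
#' @return A `LesionSpec`.
#' @export
lesionSpec <- function(artery, center, radius, peakHu,
                       huProfile = c("uniform", "radial-falloff")) {
  new("LesionSpec", artery = artery, center = as.numeric(center),
      radius = radius, peakHu = peakHu, huProfile = match.arg(huProfile))
}

#' CT phantom specification
#'
#' Parameters of a synthetic non-contrast calcium-scoring CT: an ellipsoidal
#' pericardium whose outer shell carries epicardial adipose tissue (EAT) with
#' Hounsfield units drawn from a Gaussian mixture restricted to the adipose
#' window, plus spherical calcified lesions assigned to artery territories.
#'
#' @slot gridShape Integer length-3 voxel grid dimensions.
#' @slot voxelSpacing Voxel spacing in mm (x, y, slice thickness).
#' @slot pericardiumCenter Ellipsoid centre (mm).
#' @slot pericardiumSemiAxes Ellipsoid semi-axes (mm).
#' @slot eatShellRho Inner normalized radius of the EAT shell: EAT candidates
#'   are pericardium voxels with normalized ellipsoid radius in
#'   `[eatShellRho, 1]`.
#' @slot eatFraction Fraction of shell voxels assigned to EAT (Bernoulli).
#' @slot eatHuMixture Data frame with columns `mean`, `sd`, `weight`: the EAT
#'   HU mixture; weights sum to 1 and means lie in the adipose window.
#' @slot lesions List of [LesionSpec-class].
#' @slot backgroundHu HU of non-EAT, non-lesion tissue.
#' @slot seed Integer RNG seed.
#'
#' @export
setClass("PhantomSpec",
         representation(gridShape = "integer", voxelSpacing = "numeric",
                        pericardiumCenter = "numeric",
                        pericardiumSemiAxes = "numeric",
                        eatShellRho = "numeric", eatFraction = "numeric",
                        eatHuMixture = "data.frame", lesions = "list",
                        backgroundHu = "numeric", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (length(object@gridShape) != 3L || any(object@gridShape < 1L))
    msg <- c(msg, "gridShape must be 3 positive integers")
  if (length(object@voxelSpacing) != 3L || any(object@voxelSpacing <= 0))
    msg <- c(msg, "voxelSpacing must be 3 positive values (mm)")
  if (any(object@pericardiumSemiAxes <= 0))
    msg <- c(msg, "pericardium semi-axes must be positive")
  if (object@eatShellRho <= 0 || object@eatShellRho >= 1)
    msg <- c(msg, "eatShellRho must lie in (0, 1)")
  if (object@eatFraction < 0 || object@eatFraction > 1)
    msg <- c(msg, "eatFraction must lie in [0, 1]")
  mix <- object@eatHuMixture
  if (!all(c("mean", "sd", "weight") %in% names(mix)))
    msg <- c(msg, "eatHuMixture needs columns mean, sd, weight")
  else {
    if (abs(sum(mix$weight) - 1) > 1e-8)
      msg <- c(msg, "eatHuMixture weights must sum to 1")
    if (any(mix$mean < ADIPOSE_WINDOW[1] | mix$mean > ADIPOSE_WINDOW[2]))
      msg <- c(msg, sprintf("eatHuMixture means must lie in the adipose window [%d, %d] HU",
                            ADIPOSE_WINDOW[1], ADIPOSE_WINDOW[2]))
    if (any(mix$sd < 0)) msg <- c(msg, "eatHuMixture sds must be non-negative")
  }
  if (!all(vapply(object@lesions, is, TRUE, "LesionSpec")))
    msg <- c(msg, "lesions must be LesionSpec objects")
  if (length(msg)) msg else TRUE
})

# Adipose HU window; also the default fat-omics histogram support.
ADIPOSE_WINDOW <- c(-190, -30)

#' @rdname PhantomSpec-class
#' @param gridShape,voxelSpacing,pericardiumCenter,pericardiumSemiAxes,eatShellRho,eatFraction,eatHuMixture,lesions,backgroundHu,seed
#'   See slot descriptions; defaults give a small heart-sized phantom.
#' @return A `PhantomSpec`.
#' @examples
#' spec <- phantomSpec(seed = 1)
#' phantom <- generatePhantom(spec)
#' phantom$volume
#' @export
phantomSpec <- function(gridShape = c(48L, 48L, 16L),
                        voxelSpacing = c(1, 1, 3),
                        pericardiumCenter = NULL,
                        pericardiumSemiAxes = c(18, 18, 20),
                        eatShellRho = 0.75,
                        eatFraction = 1,
                        eatHuMixture = data.frame(mean = c(-100, -70),
                                                  sd = c(20, 15),
                                                  weight = c(0.7, 0.3)),
                        lesions = list(),
                        backgroundHu = 40,
                        seed = 1L) {
  gridShape <- as.integer(gridShape)
  if (is.null(pericardiumCenter))
    pericardiumCenter <- (gridShape - 1) * voxelSpacing / 2
  new("PhantomSpec", gridShape = gridShape,
      voxelSpacing = as.numeric(voxelSpacing),
      pericardiumCenter = as.numeric(pericardiumCenter),
      pericardiumSemiAxes = as.numeric(pericardiumSemiAxes),
      eatShellRho = eatShellRho, eatFraction = eatFraction,
      eatHuMixture = eatHuMixture, lesions = lesions,
      backgroundHu = backgroundHu, seed = as.integer(seed))
}

# World (mm) coordinates of voxel centres along each axis.
.axisCoords <- function(n, sp) (seq_len(n) - 1) * sp

# n x 3 matrix of world coordinates for given 1-based voxel indices.
.worldCoords <- function(idx, spacing) {
  sweep(idx - 1, 2, spacing, `*`)
}

#' Generate a CT phantom with aligned region masks
#'
#' Rasterizes a [PhantomSpec-class] into a Hounsfield-unit volume plus masks
#' for the pericardium interior, the EAT shell, and one calcium territory per
#' artery that has lesions. Deterministic: the same spec (including its seed)
#' reproduces the output bit-exactly.
#'
#' @param spec A [PhantomSpec-class].
#' @param territoryMargin Territory masks extend this many mm beyond each
#'   lesion sphere.
#' @return A list with elements `volume` ([CTVolume-class]), `pericardium`,
#'   `eat` ([RegionMask-class]), and `territories` (named list of
#'   [RegionMask-class], one per artery with lesions).
#' @examples
#' ph <- generatePhantom(phantomSpec(seed = 7))
#' sum(ph$eat@mask)
#' @export
generatePhantom <- function(spec, territoryMargin = 2) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  set.seed(spec@seed)
  d <- spec@gridShape
  sp <- spec@voxelSpacing
  cx <- .axisCoords(d[1], sp[1])
  cy <- .axisCoords(d[2], sp[2])
  cz <- .axisCoords(d[3], sp[3])

  # Normalized ellipsoid radius at every voxel centre.
  rx <- (cx - spec@pericardiumCenter[1]) / spec@pericardiumSemiAxes[1]
  ry <- (cy - spec@pericardiumCenter[2]) / spec@pericardiumSemiAxes[2]
  rz <- (cz - spec@pericardiumCenter[3]) / spec@pericardiumSemiAxes[3]
  rho2 <- outer(outer(rx^2, ry^2, `+`), rz^2, `+`)
  pericardium <- rho2 <= 1

  shell <- pericardium & rho2 >= spec@eatShellRho^2
  eat <- shell
  if (spec@eatFraction < 1) {
    keep <- stats::runif(sum(shell)) < spec@eatFraction
    eat[shell] <- keep
  }

  hu <- array(spec@backgroundHu, dim = d)
  nEat <- sum(eat)
  if (nEat > 0) {
    mix <- spec@eatHuMixture
    comp <- sample.int(nrow(mix), nEat, replace = TRUE, prob = mix$weight)
    draw <- stats::rnorm(nEat, mix$mean[comp], mix$sd[comp])
    # keep EAT attenuation inside the adipose window
    hu[eat] <- pmin(pmax(draw, ADIPOSE_WINDOW[1]), ADIPOSE_WINDOW[2])
  }

  lesionVoxels <- vector("list", length(spec@lesions))
  for (li in seq_along(spec@lesions)) {
    les <- spec@lesions[[li]]
    ctr <- les@center
    inGrid <- all(ctr >= 0) && all(ctr <= (d - 1) * sp)
    if (!inGrid)
      stop(sprintf("lesion %d (%s) center (%s) lies outside the grid",
                   li, les@artery, paste(signif(ctr, 4), collapse = ", ")))
    dx2 <- (cx - ctr[1])^2
    dy2 <- (cy - ctr[2])^2
    dz2 <- (cz - ctr[3])^2
    dist2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
    inside <- dist2 <= les@radius^2
    vox <- which(inside)
    if (les@huProfile == "uniform") {
      hu[vox] <- les@peakHu
    } else {
      frac <- sqrt(dist2[vox]) / les@radius
      hu[vox] <- les@peakHu - (les@peakHu - 130) * frac
    }
    lesionVoxels[[li]] <- vox
  }

  # territory ambiguity: lesions of different arteries must not overlap
  if (length(spec@lesions) > 1) {
    arteries <- vapply(spec@lesions, function(l) l@artery, "")
    for (i in seq_along(lesionVoxels)) for (j in seq_len(i - 1)) {
      if (arteries[i] != arteries[j] &&
          length(intersect(lesionVoxels[[i]], lesionVoxels[[j]])))
        stop(sprintf("lesions %d (%s) and %d (%s) overlap: artery territory is ambiguous",
                     j, arteries[j], i, arteries[i]))
    }
  }

  territories <- list()
  for (art in ARTERIES) {
    sel <- vapply(spec@lesions, function(l) l@artery == art, TRUE)
    if (!any(sel)) next
    terr <- array(FALSE, dim = d)
    for (les in spec@lesions[sel]) {
      r <- les@radius + territoryMargin
      dx2 <- (cx - les@center[1])^2
      dy2 <- (cy - les@center[2])^2
      dz2 <- (cz - les@center[3])^2
      terr <- terr | (outer(outer(dx2, dy2, `+`), dz2, `+`) <= r^2)
    }
    territories[[art]] <- RegionMask(terr, sp, role = art)
  }

  list(volume = CTVolume(hu, sp),
       pericardium = RegionMask(pericardium, sp, role = "pericardium"),
       eat = RegionMask(eat, sp, role = "eat"),
       territories = territories)
}
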