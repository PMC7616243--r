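#' @include cardioscar-package.R
NULL

.EXCLUSION_REASONS <- c("none", "low_myocardium", "self_intersection", "no_rv")
.REGIONS <- c("septal", "lateral")
.VARIANTS <- c("vae_scar", "u_scar", "u_scar_lat")

#' PhantomSpec: parameters of the synthetic short-axis phantom
#'
#' Describes one synthetic "patient": a stack of short-axis slices with an
#' annular LV myocardium, an attached right-ventricle (RV) crescent centred
#' on the septum, and optional scar drawn as an angular sector of the
#' myocardium with an intensity shift and local wall thinning.
#'
#' @slot imageSize side of the square slice grid in pixels.
#' @slot nSlices number of slices apex to base.
#' @slot lvRadiusRange range (min, max) of the mid-ventricular epicardial
#'   radius in pixels; a per-case radius is drawn uniformly.
#' @slot wallThicknessRange range of the myocardial wall thickness in pixels.
#' @slot rvAttachmentArc angular extent (degrees, in (0, 180)) of the RV
#'   crescent attachment centred on the septal direction (+x).
#' @slot scarPresent named logical, one flag per region (septal, lateral).
#' @slot scarBurden named numeric in [0, 1]: target scar fraction of each
#'   region's myocardium.
#' @slot scarIntensityShift additive intensity offset (HU-like) applied to
#'   scar pixels; negative values emulate hypo-enhancement.
#' @slot scarThinning fraction in [0, 1) by which the wall is locally
#'   thinned over the scar sector.
#' @slot noiseSd standard deviation of additive Gaussian intensity noise.
#' @slot seed integer seed; all phantom randomness derives from it.
#' @export
setClass("PhantomSpec",
  representation(
    imageSize = "integer", nSlices = "integer",
    lvRadiusRange = "numeric", wallThicknessRange = "numeric",
    rvAttachmentArc = "numeric", scarPresent = "logical",
    scarBurden = "numeric", scarIntensityShift = "numeric",
    scarThinning = "numeric", noiseSd = "numeric", seed = "integer"
  )
)

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (object@imageSize < 16) msg <- c(msg, "imageSize: must be >= 16 pixels")
  if (object@nSlices < 1) msg <- c(msg, "nSlices: must be >= 1")
  if (length(object@lvRadiusRange) != 2 || any(object@lvRadiusRange <= 0) ||
      diff(object@lvRadiusRange) < 0)
    msg <- c(msg, "lvRadiusRange: must be an increasing positive pair")
  if (length(object@wallThicknessRange) != 2 ||
      any(object@wallThicknessRange <= 0) ||
      diff(object@wallThicknessRange) < 0)
    msg <- c(msg, "wallThicknessRange: wall thickness must be > 0")
  if (object@rvAttachmentArc <= 0 || object@rvAttachmentArc >= 180)
    msg <- c(msg, "rvAttachmentArc: must lie in (0, 180) degrees")
  if (!identical(sort(names(object@scarPresent)), sort(.REGIONS)))
    msg <- c(msg, "scarPresent: needs named flags 'septal' and 'lateral'")
  if (!identical(sort(names(object@scarBurden)), sort(.REGIONS)))
    msg <- c(msg, "scarBurden: needs named values 'septal' and 'lateral'")
  if (any(object@scarBurden < 0 | object@scarBurden > 1))
    msg <- c(msg, "scarBurden: must lie in [0, 1]")
  if (object@scarThinning < 0 || object@scarThinning >= 1)
    msg <- c(msg, "scarThinning: must lie in [0, 1)")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd: must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a PhantomSpec
#'
#' @param imageSize,nSlices,lvRadiusRange,wallThicknessRange,rvAttachmentArc
#'   geometry parameters, see [PhantomSpec-class].
#' @param scarPresent,scarBurden,scarIntensityShift,scarThinning scar
#'   parameters per region.
#' @param noiseSd,seed noise level and random seed.
#' @return a validated `PhantomSpec`.
#' @examples
#' spec <- phantomSpec(imageSize = 128, nSlices = 8, seed = 1)
#' @export
phantomSpec <- function(imageSize = 600L, nSlices = 60L,
                        lvRadiusRange = NULL,
                        wallThicknessRange = NULL,
                        rvAttachmentArc = 100,
                        scarPresent = c(septal = FALSE, lateral = FALSE),
                        scarBurden = c(septal = 0, lateral = 0),
                        scarIntensityShift = -80,
                        scarThinning = 0.3,
                        noiseSd = 25,
                        seed = 1L) {
  imageSize <- as.integer(imageSize)
  # geometry defaults scale with the grid so reduced-size phantoms keep the
  # same proportions as the 600 px reference
  sc <- imageSize / 600
  if (is.null(lvRadiusRange)) lvRadiusRange <- c(130, 170) * sc
  if (is.null(wallThicknessRange)) wallThicknessRange <- c(35, 55) * sc
  new("PhantomSpec",
    imageSize = imageSize, nSlices = as.integer(nSlices),
    lvRadiusRange = as.numeric(lvRadiusRange),
    wallThicknessRange = as.numeric(wallThicknessRange),
    rvAttachmentArc = as.numeric(rvAttachmentArc),
    scarPresent = scarPresent[.REGIONS],
    scarBurden = as.numeric(scarBurden[.REGIONS]) |>
      setNames(.REGIONS),
    scarIntensityShift = as.numeric(scarIntensityShift),
    scarThinning = as.numeric(scarThinning),
    noiseSd = as.numeric(noiseSd), seed = as.integer(seed)
  )
}

#' SliceRecord: one short-axis sample
#'
#' A single short-axis CTA slice with its anatomical and scar masks.
#' `epiMask` is the epicardial interior (endocardial blood pool plus
#' myocardium); the myocardium is `epiMask & !endoMask`.
#'
#' @slot image intensity matrix (HU-like).
#' @slot endoMask,epiMask,rvMask,scarMask binary 0/1 matrices, same size as
#'   `image`.
#' @slot patientId character id.
#' @slot sliceIndex 0-based index along apex (0) to base.
#' @slot plane list with `origin` and `normal` (mm, heart coordinates), or
#'   empty for purely synthetic slices.
#' @export
setClass("SliceRecord",
  representation(
    image = "matrix", endoMask = "matrix", epiMask = "matrix",
    rvMask = "matrix", scarMask = "matrix",
    patientId = "character", sliceIndex = "integer", plane = "list"
  )
)

setValidity("SliceRecord", function(object) {
  msg <- character()
  d <- dim(object@image)
  for (m in c("endoMask", "epiMask", "rvMask", "scarMask")) {
    mm <- slot(object, m)
    if (!identical(dim(mm), d)) msg <- c(msg, paste0(m, ": size mismatch"))
    if (!all(mm %in% c(0, 1))) msg <- c(msg, paste0(m, ": must be binary"))
  }
  if (object@sliceIndex < 0) msg <- c(msg, "sliceIndex: must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a SliceRecord object
#'
#' @rdname SliceRecord-class
#' @export
sliceRecord <- function(image, endoMask, epiMask, rvMask, scarMask,
                        patientId = "synthetic", sliceIndex = 0L,
                        plane = list()) {
  new("SliceRecord", image = image, endoMask = endoMask, epiMask = epiMask,
      rvMask = rvMask, scarMask = scarMask, patientId = patientId,
      sliceIndex = as.integer(sliceIndex), plane = plane)
}

#' RegionLabels: per-slice septal/lateral scar labels
#'
#' @slot septalScar,lateralScar logical scar labels (10\% rule).
#' @slot excluded logical; when TRUE the scar labels are to be ignored.
#' @slot exclusionReason one of `"none"`, `"low_myocardium"`,
#'   `"self_intersection"`, `"no_rv"`.
#' @slot septalFraction,lateralFraction realized scar fraction of each
#'   region's myocardium, in [0, 1] (NA when excluded).
#' @export
setClass("RegionLabels",
  representation(
    septalScar = "logical", lateralScar = "logical",
    excluded = "logical", exclusionReason = "character",
    septalFraction = "numeric", lateralFraction = "numeric"
  )
)

setValidity("RegionLabels", function(object) {
  msg <- character()
  if (!object@exclusionReason %in% .EXCLUSION_REASONS)
    msg <- c(msg, paste("exclusionReason: must be one of",
                        paste(.EXCLUSION_REASONS, collapse = ", ")))
  if (!object@excluded && object@exclusionReason != "none")
    msg <- c(msg, "exclusionReason: must be 'none' when not excluded")
  fr <- c(object@septalFraction, object@lateralFraction)
  if (any(!is.na(fr) & (fr < 0 | fr > 1)))
    msg <- c(msg, "fractions: must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct a RegionLabels object
#'
#' @rdname RegionLabels-class
#' @export
regionLabels <- function(septalScar = NA, lateralScar = NA, excluded = FALSE,
                         exclusionReason = "none",
                         septalFraction = NA_real_,
                         lateralFraction = NA_real_) {
  new("RegionLabels", septalScar = as.logical(septalScar),
      lateralScar = as.logical(lateralScar), excluded = excluded,
      exclusionReason = exclusionReason,
      septalFraction = as.numeric(septalFraction),
      lateralFraction = as.numeric(lateralFraction))
}

#' RigidTransform: rotation + translation in mm
#'
#' Maps points as `x' = R x + t`. Proper rigid: `R` orthonormal with
#' determinant +1.
#'
#' @slot rotation 3x3 orthonormal matrix.
#' @slot translation length-3 numeric (mm).
#' @export
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric")
)

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  msg <- character()
  if (!identical(dim(R), c(3L, 3L))) msg <- c(msg, "rotation: must be 3x3")
  else {
    if (max(abs(crossprod(R) - diag(3))) > 1e-6)
      msg <- c(msg, "rotation: must be orthonormal")
    if (abs(det(R) - 1) > 1e-6)
      msg <- c(msg, "rotation: determinant must be +1 (no reflection)")
  }
  if (length(object@translation) != 3)
    msg <- c(msg, "translation: must be length 3")
  if (length(msg)) msg else TRUE
})

#' Construct a rigid transform
#'
#' @param rotation 3x3 orthonormal rotation matrix (determinant +1).
#' @param translation length-3 translation in mm.
#' @return a `RigidTransform`.
#' @export
rigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  new("RigidTransform", rotation = rotation,
      translation = as.numeric(translation))
}

#' SurfaceMesh: triangulated surface with named landmarks
#'
#' @slot points n x 3 matrix of coordinates in mm.
#' @slot faces m x 3 integer matrix of 1-based vertex indices.
#' @slot landmarks named list of length-3 points (e.g. `rv_junction_anterior`,
#'   `rv_junction_inferior`, `apex`, `base_center`).
#' @slot label one of `"endocardium"`, `"epicardium"`, `"rv"`, `"scar"`.
#' @export
setClass("SurfaceMesh",
  representation(points = "matrix", faces = "matrix",
                 landmarks = "list", label = "character")
)

setValidity("SurfaceMesh", function(object) {
  msg <- character()
  if (ncol(object@points) != 3) msg <- c(msg, "points: must be n x 3")
  if (nrow(object@points) < 4)
    msg <- c(msg, "points: need at least 4 points")
  if (nrow(object@faces) > 0) {
    if (ncol(object@faces) != 3) msg <- c(msg, "faces: must be m x 3")
    else if (min(object@faces) < 1 || max(object@faces) > nrow(object@points))
      msg <- c(msg, "faces: vertex index out of range")
  }
  if (anyDuplicated(names(object@landmarks)))
    msg <- c(msg, "landmarks: names must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct a SurfaceMesh object
#'
#' @rdname SurfaceMesh-class
#' @export
surfaceMesh <- function(points, faces = matrix(integer(), 0, 3),
                        landmarks = list(), label = "endocardium") {
  storage.mode(faces) <- "integer"
  dimnames(points) <- NULL
  dimnames(faces) <- NULL
  new("SurfaceMesh", points = points, faces = faces,
      landmarks = landmarks, label = label)
}

#' MeshSet: the surfaces describing one heart
#'
#' @slot endo,epi left-ventricle endocardial / epicardial surfaces.
#' @slot rv right-ventricle surface (or NULL).
#' @slot scar scar surface (or NULL; MRI-derived in the real pipeline).
#' @export
setClass("MeshSet",
  representation(endo = "ANY", epi = "ANY", rv = "ANY", scar = "ANY")
)

#' Construct a MeshSet object
#'
#' @rdname MeshSet-class
#' @export
meshSet <- function(endo, epi = NULL, rv = NULL, scar = NULL) {
  new("MeshSet", endo = endo, epi = epi, rv = rv, scar = scar)
}

#' CTAVolume: a 3D CT angiography intensity grid
#'
#' @slot voxels 3D numeric array (i, j, k).
#' @slot spacing mm per voxel along each array axis.
#' @slot origin mm position of voxel (1,1,1) centre.
#' @slot orientation 3x3 direction-cosine matrix; column d is the patient-space
#'   direction of array axis d.
#' @export
setClass("CTAVolume",
  representation(voxels = "array", spacing = "numeric",
                 origin = "numeric", orientation = "matrix")
)

setValidity("CTAVolume", function(object) {
  msg <- character()
  if (length(dim(object@voxels)) != 3) msg <- c(msg, "voxels: must be 3D")
  if (any(object@spacing <= 0)) msg <- c(msg, "spacing: must be > 0")
  if (max(abs(crossprod(object@orientation) - diag(3))) > 1e-6)
    msg <- c(msg, "orientation: must be orthonormal")
  if (length(msg)) msg else TRUE
})

#' Construct a CtaVolume object
#'
#' @rdname CtaVolume-class
#' @export
ctaVolume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                      orientation = diag(3)) {
  new("CTAVolume", voxels = voxels, spacing = as.numeric(spacing),
      origin = as.numeric(origin), orientation = orientation)
}

#' NetworkConfig: architecture hyperparameters
#'
#' @slot variant `"vae_scar"` (image-reconstructing VAE), `"u_scar"`
#'   (segmentation decoder with skip connections) or `"u_scar_lat"`
#'   (U-Scar with only the lateral branch).
#' @slot inputSize network input side in pixels (square input).
#' @slot latentDim latent space dimensionality (128 at full scale).
#' @slot encoderChannels channel widths per encoder level; the decoder
#'   mirrors them.
#' @slot branchLayers widths of the fully connected classification blocks
#'   (2x 1000 then 256 at full scale).
#' @slot dropout dropout rate in the classification branches, train mode only.
#' @slot branches regions classified: subset of `c("septal", "lateral")`.
#' @slot groups group-normalisation group count (capped at channel count).
#' @slot convsPerLevel convolution blocks per encoder/decoder level (2 is
#'   the usual U-Net pattern; 1 is a lighter variant).
#' @export
setClass("NetworkConfig",
  representation(
    variant = "character", inputSize = "integer", latentDim = "integer",
    encoderChannels = "integer", branchLayers = "integer",
    dropout = "numeric", branches = "character", groups = "integer",
    convsPerLevel = "integer"
  )
)

setValidity("NetworkConfig", function(object) {
  msg <- character()
  if (!object@variant %in% .VARIANTS)
    msg <- c(msg, paste("variant: must be one of",
                        paste(.VARIANTS, collapse = ", ")))
  if (object@latentDim < 1) msg <- c(msg, "latentDim: must be > 0")
  if (object@dropout < 0 || object@dropout >= 1)
    msg <- c(msg, "dropout: must lie in [0, 1)")
  if (!all(object@branches %in% .REGIONS))
    msg <- c(msg, "branches: must be a subset of septal/lateral")
  if (object@variant == "u_scar_lat" &&
      !identical(object@branches, "lateral"))
    msg <- c(msg, "branches: u_scar_lat classifies the lateral region only")
  depth <- length(object@encoderChannels)
  if (object@inputSize %% (2^depth) != 0)
    msg <- c(msg, sprintf(
      "inputSize: %d not divisible by 2^%d (encoder depth)",
      object@inputSize, depth))
  if (length(msg)) msg else TRUE
})

#' Construct a NetworkConfig
#'
#' Defaults follow the full-scale design: latent size 128, five encoder
#' levels, classification branches of two 1000-wide layers then a 256-wide
#' layer, dropout 0.5. `u_scar_lat` forces `branches = "lateral"`.
#'
#' @param variant,inputSize,latentDim,encoderChannels,branchLayers,dropout,branches,groups
#'   see [NetworkConfig-class].
#' @return a validated `NetworkConfig`.
#' @examples
#' cfg <- networkConfig("u_scar_lat", inputSize = 64,
#'                      encoderChannels = c(8, 16, 32, 64), latentDim = 32,
#'                      branchLayers = c(64, 32))
#' @export
networkConfig <- function(variant = c("u_scar", "vae_scar", "u_scar_lat"),
                          inputSize = 256L, latentDim = 128L,
                          encoderChannels = c(16L, 32L, 64L, 128L, 256L),
                          branchLayers = c(1000L, 1000L, 256L),
                          dropout = 0.5,
                          branches = NULL, groups = 8L,
                          convsPerLevel = 2L) {
  variant <- match.arg(variant)
  if (is.null(branches))
    branches <- if (variant == "u_scar_lat") "lateral" else .REGIONS
  new("NetworkConfig", variant = variant, inputSize = as.integer(inputSize),
      latentDim = as.integer(latentDim),
      encoderChannels = as.integer(encoderChannels),
      branchLayers = as.integer(branchLayers), dropout = dropout,
      branches = branches, groups = as.integer(groups),
      convsPerLevel = as.integer(convsPerLevel))
}

#' ScarNetwork: a built network with its parameter store
#'
#' Parameters live in an environment so optimiser updates are in place;
#' use [networkParameters()] to inspect them.
#'
#' @slot config the [NetworkConfig-class] the network was built from.
#' @slot params environment holding named parameter arrays.
#' @export
setClass("ScarNetwork",
  representation(config = "NetworkConfig", params = "environment")
)

#' MetricsReport: per-region classification metrics
#'
#' @slot perRegion data.frame with columns region, auc, auc_ci_low,
#'   auc_ci_high, sensitivity, specificity, n_slices, n_positive. AUC fields
#'   are NA (with `auc_reason`) when only one class is present.
#' @slot accuracy plain accuracy for a single-branch model, mean of
#'   per-region accuracies otherwise.
#' @export
setClass("MetricsReport",
  representation(perRegion = "data.frame", accuracy = "numeric")
)

#' FoldSplit: one cross-validation fold at patient level
#'
#' @slot foldIndex 0-based fold index.
#' @slot trainPatients,valPatients disjoint patient-id sets.
#' @export
setClass("FoldSplit",
  representation(foldIndex = "integer", trainPatients = "character",
                 valPatients = "character")
)

setValidity("FoldSplit", function(object) {
  if (length(intersect(object@trainPatients, object@valPatients)) > 0)
    "trainPatients/valPatients: a patient may not be in both sets"
  else TRUE
})
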