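#' @include AllClasses.R mesh.R
NULL

#' PhantomCase: a generated synthetic patient
#'
#' @slot patientId character id.
#' @slot slices list of [SliceRecord-class], ordered apex to base.
#' @slot truth list of [RegionLabels-class], one per slice, computed from
#'   the generator's own pixel bookkeeping.
#' @slot spec the generating [PhantomSpec-class].
#' @export
setClass("PhantomCase",
  representation(patientId = "character", slices = "list",
                 truth = "list", spec = "PhantomSpec")
)

setMethod("show", "PhantomCase", function(object) {
  kept <- sum(!vapply(object@truth, function(l) l@excluded, TRUE))
  cat(sprintf("PhantomCase %s: %d slices (%d kept), %d x %d px\n",
              object@patientId, length(object@slices), kept,
              object@spec@imageSize, object@spec@imageSize))
})

# run expr under a private RNG state, restoring the caller's stream
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# wrapped absolute angular distance in radians
.angDist <- function(a, b) {
  d <- (a - b + pi) %% (2 * pi) - pi
  abs(d)
}

# long-axis taper: half-ellipsoid rising from apex (t = 0) to base (t = 1),
# with an extra quadratic pinch over the apical 10% so that the smallest
# apical slices fall under the minimum-myocardium filter naturally
.taperScale <- function(t) {
  sMid <- sqrt(pmax(0, 1 - ((t - 1) / 1.15)^2))
  apexF <- pmin(1, t / 0.1)^2
  sMid * apexF
}

.RV_START <- 0.12  # RV crescent absent below this apex fraction

.sliceGeometry <- function(t, rEpiMid, wallMid) {
  s <- .taperScale(t)
  rEpi <- rEpiMid * s
  wall <- wallMid * (0.7 + 0.3 * s)
  list(rEpi = rEpi, rEndo = max(0, rEpi - wall), wall = wall,
       hasRV = t >= .RV_START && rEpi > 1)
}

#' Generate one synthetic phantom case
#'
#' Builds `nSlices` short-axis slices of an annular left ventricle with an
#' attached right-ventricle crescent centred on the septal direction (+x).
#' Scar, when requested, is an angular sector of the target region's
#' myocardium whose pixel count is chosen to realise `scarBurden` exactly
#' (up to rounding); scar pixels receive `scarIntensityShift` and the wall
#' is locally thinned by `scarThinning`. The stack tapers toward the apex
#' so that the minimum-myocardium and missing-RV exclusion filters fire on
#' apical slices, as they do on real data.
#'
#' Ground-truth [RegionLabels-class] use the 10\% scar-volume rule on the
#' generator's own pixel counts.
#'
#' @param spec a [PhantomSpec-class]
#' @param patientId id stored on each slice.
#' @return a [PhantomCase-class]
#' @examples
#' case <- generatePhantomCase(phantomSpec(imageSize = 128, nSlices = 6,
#'   scarPresent = c(septal = FALSE, lateral = TRUE),
#'   scarBurden = c(septal = 0, lateral = 0.3), seed = 7))
#' @export
generatePhantomCase <- function(spec,
                                patientId = sprintf("phantom_%04d", spec@seed)) {
  validObject(spec)
  sz <- spec@imageSize
  .withSeed(spec@seed, {
    cx <- sz / 2 + runif(1, -0.02, 0.02) * sz
    cy <- sz / 2 + runif(1, -0.02, 0.02) * sz
    rEpiMid <- runif(1, spec@lvRadiusRange[1], spec@lvRadiusRange[2])
    wallMid <- runif(1, spec@wallThicknessRange[1], spec@wallThicknessRange[2])
    # scar centres: septal scar sits on the septum; lateral scar clusters in
    # the lateral free wall opposite the septum (LCx territory), with
    # per-patient spread
    latDeg <- min(240, max(120, rnorm(1, 180, 30)))
    thetaScar <- c(septal = 0, lateral = latDeg * pi / 180)
    arcRad <- spec@rvAttachmentArc * pi / 180
    adjRad <- defaultAdjacencyRadius(sz)
    rvThick <- 0.5 * wallMid

    X <- matrix(rep(seq_len(sz) - cx, each = sz), sz, sz)   # column offsets
    Y <- matrix(rep(seq_len(sz) - cy, times = sz), sz, sz)  # row offsets
    R <- sqrt(X^2 + Y^2)
    TH <- atan2(Y, X)
    inArc <- .angDist(TH, 0) <= arcRad / 2

    # intensity model (HU-like): contrast-filled blood pools bright,
    # myocardium intermediate, background dark
    int <- c(bg = -50, myo = 120, blood = 400, rv = 350)

    slices <- vector("list", spec@nSlices)
    truth <- vector("list", spec@nSlices)
    for (i in seq_len(spec@nSlices)) {
      t <- (i - 0.5) / spec@nSlices
      g <- .sliceGeometry(t, rEpiMid, wallMid)

      # local epicardial radius, thinned over scar sectors
      rEpiLoc <- matrix(g$rEpi, sz, sz)
      if (spec@scarThinning > 0 && g$hasRV) {
        extent <- c(septal = arcRad + 2 * adjRad / max(g$rEpi, 1),
                    lateral = 2 * pi - arcRad - 2 * adjRad / max(g$rEpi, 1))
        for (rg in .REGIONS) {
          if (spec@scarPresent[rg] && spec@scarBurden[rg] > 0) {
            hw <- spec@scarBurden[rg] * extent[rg] / 2
            inThin <- .angDist(TH, thetaScar[rg]) <= hw
            rEpiLoc[inThin] <- g$rEpi - spec@scarThinning * g$wall
          }
        }
      }

      endo <- (R <= g$rEndo) * 1
      epiInt <- (R <= rEpiLoc) * 1
      myo <- epiInt * (1 - endo)
      rv <- if (g$hasRV)
        ((R > rEpiLoc) & (R <= rEpiLoc + rvThick) & inArc) * 1
      else matrix(0, sz, sz)

      scar <- matrix(0, sz, sz)
      frac <- c(septal = NA_real_, lateral = NA_real_)
      if (g$hasRV && sum(rv) > 0 && sum(myo) > 0 &&
          any(spec@scarPresent & spec@scarBurden > 0)) {
        septalMask <- computeSeptalMask(myo, rv, adjRad)
        regionMasks <- list(septal = septalMask,
                            lateral = myo * (1 - septalMask))
        for (rg in .REGIONS) {
          n_rg <- sum(regionMasks[[rg]])
          if (n_rg == 0) next
          frac[rg] <- 0
          if (!spec@scarPresent[rg] || spec@scarBurden[rg] <= 0) next
          idx <- which(regionMasks[[rg]] == 1)
          target <- round(spec@scarBurden[rg] * n_rg)
          if (target > 0) {
            d <- .angDist(TH[idx], thetaScar[rg])
            scar[idx[order(d)[seq_len(target)]]] <- 1
            frac[rg] <- target / n_rg
          }
        }
      } else if (g$hasRV && sum(rv) > 0 && sum(myo) > 0) {
        septalMask <- computeSeptalMask(myo, rv, adjRad)
        frac["septal"] <- if (sum(septalMask) > 0) 0 else NA_real_
        frac["lateral"] <- if (sum(myo) - sum(septalMask) > 0) 0 else NA_real_
      }

      img <- matrix(int["bg"], sz, sz)
      img[myo == 1] <- int["myo"]
      img[endo == 1] <- int["blood"]
      img[rv == 1] <- int["rv"]
      img[scar == 1] <- int["myo"] + spec@scarIntensityShift
      if (spec@noiseSd > 0)
        img <- img + matrix(rnorm(sz * sz, 0, spec@noiseSd), sz, sz)

      slices[[i]] <- sliceRecord(img, endo, epiInt, rv, scar,
                                 patientId = patientId, sliceIndex = i - 1L)

      myoCount <- sum(myo)
      truth[[i]] <-
        if (myoCount < 50)
          regionLabels(excluded = TRUE, exclusionReason = "low_myocardium")
        else if (!g$hasRV || sum(rv) == 0)
          regionLabels(excluded = TRUE, exclusionReason = "no_rv")
        else
          regionLabels(septalScar = !is.na(frac["septal"]) && frac["septal"] >= 0.10,
                       lateralScar = !is.na(frac["lateral"]) && frac["lateral"] >= 0.10,
                       septalFraction = frac["septal"],
                       lateralFraction = frac["lateral"])
    }
    new("PhantomCase", patientId = patientId, slices = slices,
        truth = truth, spec = spec)
  })
}

#' Generate a matched fixed/moving surface-mesh pair
#'
#' Builds left-ventricle endocardial and epicardial surfaces (plus the RV
#' crescent) consistent with the phantom geometry of `spec`, with apex,
#' base-centre and RV-junction landmarks. The moving set is the fixed set
#' mapped through `transform`, with optional Gaussian point jitter, and
#' serves as a registration fixture with known ground-truth transform.
#'
#' @param spec a [PhantomSpec-class]; mesh size derives from its geometry
#'   at a 120 mm field of view.
#' @param transform a [RigidTransform-class] mapping fixed to moving space.
#' @param noiseSd point jitter standard deviation in mm (also applied to
#'   landmarks).
#' @return list with elements `fixed` and `moving`, each a [MeshSet-class].
#' @export
generateMeshPair <- function(spec, transform = rigidTransform(),
                             noiseSd = 0) {
  validObject(spec)
  validObject(transform)
  mmPerPx <- 120 / spec@imageSize
  L <- 90  # apex-base length in mm
  .withSeed(spec@seed, {
    runif(2)  # keep the draw sequence aligned with generatePhantomCase
    rEpiMid <- runif(1, spec@lvRadiusRange[1], spec@lvRadiusRange[2]) * mmPerPx
    wallMid <- runif(1, spec@wallThicknessRange[1], spec@wallThicknessRange[2]) * mmPerPx
    arcRad <- spec@rvAttachmentArc * pi / 180
    rEpiFn <- function(z) pmax(0.5, rEpiMid * .taperScale(z / L))
    rEndoFn <- function(z) {
      s <- .taperScale(z / L)
      pmax(0.25, rEpiMid * s - wallMid * (0.7 + 0.3 * s))
    }
    zs <- seq(0.02 * L, L, length.out = 30)
    rvJunA <- c(rEpiFn(L / 2) * cos(arcRad / 2),
                rEpiFn(L / 2) * sin(arcRad / 2), L / 2)
    rvJunI <- c(rEpiFn(L / 2) * cos(-arcRad / 2),
                rEpiFn(L / 2) * sin(-arcRad / 2), L / 2)
    lm <- list(apex = c(0, 0, 0), base_center = c(0, 0, L),
               rv_junction_anterior = rvJunA, rv_junction_inferior = rvJunI)
    endo <- .tubeMesh(zs, rEndoFn, nTheta = 48, label = "endocardium",
                      landmarks = lm)
    epi <- .tubeMesh(zs, rEpiFn, nTheta = 48, label = "epicardium",
                     landmarks = lm)
    rv <- .ringSectorMesh(seq(.RV_START * L, 0.97 * L, length.out = 16),
                          innerFn = rEpiFn,
                          outerFn = function(z) rEpiFn(z) + 0.5 * wallMid,
                          thetaRange = c(-arcRad / 2, arcRad / 2),
                          label = "rv")
    scar <- NULL
    if (any(spec@scarPresent & spec@scarBurden > 0)) {
      rg <- .REGIONS[spec@scarPresent & spec@scarBurden > 0][1]
      thetaC <- if (rg == "septal") 0 else pi
      hw <- spec@scarBurden[rg] * pi / 2
      scar <- .ringSectorMesh(seq(0.35 * L, 0.75 * L, length.out = 8),
                              innerFn = function(z) rEndoFn(z) + 0.15 * wallMid,
                              outerFn = function(z) rEpiFn(z) - 0.15 * wallMid,
                              thetaRange = c(thetaC - hw, thetaC + hw),
                              label = "scar")
    }
    fixed <- meshSet(endo = endo, epi = epi, rv = rv, scar = scar)
    jitter <- function(mesh) {
      if (is.null(mesh)) return(NULL)
      m <- applyTransform(mesh, transform)
      if (noiseSd > 0) {
        m@points <- m@points + matrix(rnorm(length(m@points), 0, noiseSd),
                                      ncol = 3)
        m@landmarks <- lapply(m@landmarks, function(p) p + rnorm(3, 0, noiseSd))
      }
      m
    }
    moving <- meshSet(endo = jitter(endo), epi = jitter(epi),
                      rv = jitter(rv), scar = jitter(scar))
    list(fixed = fixed, moving = moving)
  })
}

#' Generate a synthetic patient cohort
#'
#' Draws per-patient phantom specs with scar assigned at the given
#' patient-level prevalences, emulating the class balance of a CTA scar
#' cohort (about 11\% septal, 18\% lateral at slice level in the reference
#' data). Scar burden for positive patients is drawn uniformly from
#' `burdenRange`, well above the 10\% labeling threshold.
#'
#' @param nPatients number of synthetic patients.
#' @param imageSize,nSlices per-case grid size and slice count.
#' @param prevalence named numeric, fraction of patients with scar per
#'   region.
#' @param burdenRange range of scar burden for scar-positive patients.
#' @param noiseSd intensity noise level passed to each spec.
#' @param seed cohort seed; per-case seeds derive from it.
#' @return list of [PhantomCase-class]
#' @export
phantomCohort <- function(nPatients, imageSize = 600L, nSlices = 60L,
                          prevalence = c(septal = 0.11, lateral = 0.18),
                          burdenRange = c(0.2, 0.45),
                          noiseSd = 25, seed = 1L) {
  .withSeed(seed, {
    nPos <- round(prevalence * nPatients)
    septalIds <- sample(nPatients, nPos["septal"])
    lateralIds <- sample(nPatients, nPos["lateral"])
    caseSeeds <- sample.int(1e7, nPatients)
    lapply(seq_len(nPatients), function(i) {
      present <- c(septal = i %in% septalIds, lateral = i %in% lateralIds)
      burden <- ifelse(present, runif(2, burdenRange[1], burdenRange[2]), 0)
      names(burden) <- .REGIONS
      spec <- phantomSpec(imageSize = imageSize, nSlices = nSlices,
                          scarPresent = present, scarBurden = burden,
                          noiseSd = noiseSd, seed = caseSeeds[i])
      generatePhantomCase(spec, patientId = sprintf("P%03d", i))
    })
  })
}
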