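#' @include AllClasses.R mesh.R registration.R
NULL

# world point(s) -> continuous (1-based) voxel index
.worldToIndex <- function(volume, pts) {
  rel <- sweep(pts, 2, volume@origin) %*% volume@orientation
  sweep(rel, 2, volume@spacing, "/") + 1
}

# vectorised trilinear interpolation with out-of-grid fill
.trilinear <- function(voxels, idx, fill) {
  d <- dim(voxels)
  i0 <- floor(idx)
  f <- idx - i0
  inside <- idx[, 1] >= 1 & idx[, 1] <= d[1] &
    idx[, 2] >= 1 & idx[, 2] <= d[2] &
    idx[, 3] >= 1 & idx[, 3] <= d[3]
  # clamp so corner lookups stay in range; filled afterwards
  i0[, 1] <- pmin(pmax(i0[, 1], 1), d[1] - 1)
  i0[, 2] <- pmin(pmax(i0[, 2], 1), d[2] - 1)
  i0[, 3] <- pmin(pmax(i0[, 3], 1), d[3] - 1)
  f <- pmin(pmax(idx - i0, 0), 1)
  at <- function(a, b, c) voxels[cbind(i0[, 1] + a, i0[, 2] + b, i0[, 3] + c)]
  v <- (1 - f[, 1]) * ((1 - f[, 2]) * ((1 - f[, 3]) * at(0, 0, 0) + f[, 3] * at(0, 0, 1)) +
                       f[, 2] * ((1 - f[, 3]) * at(0, 1, 0) + f[, 3] * at(0, 1, 1))) +
    f[, 1] * ((1 - f[, 2]) * ((1 - f[, 3]) * at(1, 0, 0) + f[, 3] * at(1, 0, 1)) +
              f[, 2] * ((1 - f[, 3]) * at(1, 1, 0) + f[, 3] * at(1, 1, 1)))
  v[!inside] <- fill
  v
}

.applyToMeshSet <- function(meshes, t) {
  meshSet(endo = if (!is.null(meshes@endo)) applyTransform(meshes@endo, t),
          epi = if (!is.null(meshes@epi)) applyTransform(meshes@epi, t),
          rv = if (!is.null(meshes@rv)) applyTransform(meshes@rv, t),
          scar = if (!is.null(meshes@scar)) applyTransform(meshes@scar, t))
}

#' Convert a CTA volume and its meshes to heart coordinates
#'
#' The heart coordinate system places the apex at the origin with the
#' long (apex to base) axis along +z, so short-axis planes are
#' z = constant, and the septal direction (towards the midpoint of the
#' RV-junction landmarks) along +x in plane. The voxel grid is untouched;
#' the volume's origin/orientation metadata and the mesh vertices are
#' mapped, and the (invertible) scanner-to-heart transform is returned in
#' the `heartTransform` attribute of the volume.
#'
#' @param volume a [CTAVolume-class] in scanner coordinates.
#' @param meshes a [MeshSet-class] whose `endo` mesh carries `apex`,
#'   `base_center` and RV-junction landmarks (scanner coordinates).
#' @return list with elements `volume` and `meshes` in heart coordinates.
#' @export
toHeartCoordinates <- function(volume, meshes) {
  lm <- meshes@endo@landmarks
  need <- c("apex", "base_center", "rv_junction_anterior", "rv_junction_inferior")
  miss <- need[!need %in% names(lm)]
  if (length(miss))
    stop("toHeartCoordinates: missing landmark(s): ", paste(miss, collapse = ", "))
  zax <- lm$base_center - lm$apex
  zax <- zax / sqrt(sum(zax^2))
  sept <- (lm$rv_junction_anterior + lm$rv_junction_inferior) / 2 - lm$apex
  xax <- sept - sum(sept * zax) * zax
  if (sqrt(sum(xax^2)) < 1e-9)
    stop("toHeartCoordinates: septal direction parallel to long axis")
  xax <- xax / sqrt(sum(xax^2))
  yax <- c(zax[2] * xax[3] - zax[3] * xax[2],
           zax[3] * xax[1] - zax[1] * xax[3],
           zax[1] * xax[2] - zax[2] * xax[1])
  R <- rbind(xax, yax, zax); dimnames(R) <- NULL
  t <- rigidTransform(R, drop(-R %*% lm$apex))
  vol2 <- ctaVolume(volume@voxels, volume@spacing,
                    origin = drop(R %*% volume@origin) + t@translation,
                    orientation = R %*% volume@orientation)
  attr(vol2, "heartTransform") <- t
  list(volume = vol2, meshes = .applyToMeshSet(meshes, t))
}

# plane/mesh cross-section -> scanline even-odd fill on the slice grid.
# grid: gridSize x gridSize pixels over a square fov (mm) centred on the
# long axis; pixel centre (r, c) sits at x = (c - (g+1)/2) * px (septal
# direction along columns), y = (r - (g+1)/2) * px.
.rasterizeMesh <- function(mesh, z0, gridSize, fov) {
  p <- mesh@points; f <- mesh@faces
  zs <- p[, 3]
  if (any(abs(zs - z0) < 1e-9)) z0 <- z0 + 1e-7  # avoid vertex-on-plane ties
  below <- zs < z0
  cross <- below[f[, 1]] + below[f[, 2]] + below[f[, 3]]
  faces <- f[cross == 1 | cross == 2, , drop = FALSE]
  px <- fov / gridSize
  out <- matrix(0, gridSize, gridSize)
  if (nrow(faces) == 0) return(out)
  segs <- matrix(0, nrow(faces), 4)
  for (i in seq_len(nrow(faces))) {
    tri <- faces[i, ]
    pts2 <- matrix(0, 2, 2); k <- 0
    for (ed in list(c(1, 2), c(2, 3), c(3, 1))) {
      a <- p[tri[ed[1]], ]; b <- p[tri[ed[2]], ]
      if ((a[3] < z0) != (b[3] < z0)) {
        s <- (z0 - a[3]) / (b[3] - a[3])
        k <- k + 1
        pts2[k, ] <- a[1:2] + s * (b[1:2] - a[1:2])
      }
    }
    segs[i, ] <- c(pts2[1, ], pts2[2, ])
  }
  half <- (gridSize + 1) / 2
  ymin <- pmin(segs[, 2], segs[, 4]); ymax <- pmax(segs[, 2], segs[, 4])
  for (r in seq_len(gridSize)) {
    yr <- (r - half) * px
    hit <- which(ymin <= yr & ymax > yr)
    if (length(hit) == 0) next
    y1 <- segs[hit, 2]; y2 <- segs[hit, 4]
    x1 <- segs[hit, 1]; x2 <- segs[hit, 3]
    xs <- sort(x1 + (yr - y1) * (x2 - x1) / (y2 - y1))
    xc <- (seq_len(gridSize) - half) * px
    out[r, ] <- findInterval(xc, xs) %% 2
  }
  out
}

#' Rasterize mesh cross-sections on a slice plane
#'
#' A pixel belongs to a mask iff its 3D centre lies inside the closed
#' surface: the plane-mesh cross-section contours are filled by even-odd
#' scanline counting. All meshes must be watertight.
#'
#' @param meshes a [MeshSet-class] in heart coordinates.
#' @param plane list with `origin` (the plane passes through it, normal to
#'   the long axis, i.e. z = origin[3]).
#' @param gridSpec list with `gridSize` (pixels) and `fov` (mm).
#' @return list of binary matrices: `endo`, `epi`, `rv`, `scar` (the
#'   latter two all-zero when the mesh is absent).
#' @export
rasterizeMasks <- function(meshes, plane,
                           gridSpec = list(gridSize = 600L, fov = 120)) {
  g <- gridSpec$gridSize; fov <- gridSpec$fov
  z0 <- plane$origin[3]
  one <- function(mesh, name) {
    if (is.null(mesh)) return(matrix(0, g, g))
    if (!.isWatertight(mesh))
      stop("rasterizeMasks: mesh '", name, "' is not watertight")
    .rasterizeMesh(mesh, z0, g, fov)
  }
  list(endo = one(meshes@endo, "endocardium"),
       epi = one(meshes@epi, "epicardium"),
       rv = one(meshes@rv, "rv"),
       scar = one(meshes@scar, "scar"))
}

#' Sample evenly spaced short-axis slices from a CTA volume
#'
#' Places `nSlices` cutting planes normal to the long axis, cell-centred
#' between the apex and base landmarks (plane i at
#' `apex_z + (i + 0.5) * L / n`, avoiding degenerate end planes; a single
#' slice falls at the axis midpoint). Each plane is resampled to a
#' `gridSize` x `gridSize` image over a fixed `fov` mm square field of
#' view (default 120 mm at 600 px, i.e. 0.2 mm/px) by trilinear
#' interpolation, and the anatomical and scar masks are rasterized from
#' the meshes. Slice index 0 is the most apical.
#'
#' @param volume a [CTAVolume-class] in heart coordinates.
#' @param meshes a [MeshSet-class] in heart coordinates (endo carries the
#'   apex/base landmarks).
#' @param nSlices number of slices (60 in the reference pipeline).
#' @param gridSize,fov in-plane resolution (pixels) and physical extent (mm).
#' @param patientId id stored on each slice.
#' @return list of [SliceRecord-class]
#' @export
sampleShortAxis <- function(volume, meshes, nSlices = 60L,
                            gridSize = 600L, fov = 120,
                            patientId = "case") {
  lm <- meshes@endo@landmarks
  if (is.null(lm$apex) || is.null(lm$base_center))
    stop("sampleShortAxis: endo mesh must carry apex and base_center landmarks")
  zA <- lm$apex[3]; zB <- lm$base_center[3]
  L <- zB - zA
  if (abs(L) < 1e-9)
    stop("sampleShortAxis: apex and base coincide (degenerate axis)")
  half <- (gridSize + 1) / 2
  px <- fov / gridSize
  xc <- (seq_len(gridSize) - half) * px
  # pixel (row, col): x along columns, y along rows
  X <- matrix(rep(xc, each = gridSize), gridSize, gridSize)
  Y <- matrix(rep(xc, times = gridSize), gridSize, gridSize)
  fill <- min(volume@voxels)
  out <- vector("list", nSlices)
  for (i in seq_len(nSlices)) {
    z0 <- zA + (i - 0.5) * L / nSlices
    pts <- cbind(as.vector(X), as.vector(Y), z0)
    idx <- .worldToIndex(volume, pts)
    img <- matrix(.trilinear(volume@voxels, idx, fill), gridSize, gridSize)
    plane <- list(origin = c(0, 0, z0), normal = c(0, 0, 1))
    masks <- rasterizeMasks(meshes, plane,
                            gridSpec = list(gridSize = gridSize, fov = fov))
    out[[i]] <- sliceRecord(img, masks$endo, masks$epi, masks$rv, masks$scar,
                            patientId = patientId, sliceIndex = i - 1L,
                            plane = plane)
  }
  out
}
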