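#' @include AllClasses.R
NULL

# ---- small mesh helpers -----------------------------------------------------

.meshCentroid <- function(mesh) colMeans(mesh@points)

# every undirected edge of a watertight triangle mesh belongs to exactly 2 faces
.isWatertight <- function(mesh) {
  f <- mesh@faces
  if (nrow(f) == 0) return(FALSE)
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2)
}

#' Apply a rigid transform to a surface mesh
#'
#' Maps every vertex and landmark through `x' = R x + t`; faces are
#' untouched.
#'
#' @param mesh a [SurfaceMesh-class]
#' @param t a [RigidTransform-class]
#' @return the transformed [SurfaceMesh-class]
#' @export
applyTransform <- function(mesh, t) {
  stopifnot(is(mesh, "SurfaceMesh"), is(t, "RigidTransform"))
  p <- mesh@points %*% t(t@rotation)
  p <- sweep(p, 2, t@translation, "+")
  lm <- lapply(mesh@landmarks, function(q) drop(t@rotation %*% q) + t@translation)
  surfaceMesh(p, mesh@faces, lm, mesh@label)
}

#' Compose two rigid transforms
#'
#' `composeTransforms(a, b)` returns the transform applying `b` first,
#' then `a` (matrix convention: `x' = Ra (Rb x + tb) + ta`).
#'
#' @param a,b [RigidTransform-class] objects
#' @return a [RigidTransform-class]
#' @export
composeTransforms <- function(a, b) {
  rigidTransform(a@rotation %*% b@rotation,
                 drop(a@rotation %*% b@translation) + a@translation)
}

#' Invert a rigid transform
#' @param t a [RigidTransform-class]
#' @return the inverse [RigidTransform-class]
#' @export
invertTransform <- function(t) {
  rigidTransform(t(t@rotation), drop(-t(t@rotation) %*% t@translation))
}

#' Rotation about an arbitrary axis
#'
#' @param axis length-3 direction (normalised internally).
#' @param angleDeg rotation angle in degrees (right-handed).
#' @return 3x3 rotation matrix
#' @export
rotationAboutAxis <- function(axis, angleDeg) {
  u <- axis / sqrt(sum(axis^2))
  a <- angleDeg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

# ---- parametric builders (used by the phantom and by tests) -----------------

# closed tube of revolution: radius(z) rings along +z, fan caps at both ends.
# radiusFn(z) must be > 0 at the ring z values.
.tubeMesh <- function(zs, radiusFn, nTheta = 48, label = "endocardium",
                      landmarks = list()) {
  th <- seq(0, 2 * pi, length.out = nTheta + 1)[-(nTheta + 1)]
  pts <- NULL
  for (z in zs) {
    r <- radiusFn(z)
    pts <- rbind(pts, cbind(r * cos(th), r * sin(th), z))
  }
  nz <- length(zs)
  idx <- function(i, j) (i - 1) * nTheta + ((j - 1) %% nTheta) + 1
  faces <- NULL
  for (i in seq_len(nz - 1)) {
    for (j in seq_len(nTheta)) {
      a <- idx(i, j); b <- idx(i, j + 1); c <- idx(i + 1, j); d <- idx(i + 1, j + 1)
      faces <- rbind(faces, c(a, b, d), c(a, d, c))
    }
  }
  # caps
  nPts <- nrow(pts)
  pts <- rbind(pts, c(0, 0, zs[1]), c(0, 0, zs[nz]))
  apexI <- nPts + 1; baseI <- nPts + 2
  for (j in seq_len(nTheta)) {
    faces <- rbind(faces,
                   c(apexI, idx(1, j + 1), idx(1, j)),
                   c(baseI, idx(nz, j), idx(nz, j + 1)))
  }
  surfaceMesh(pts, faces, landmarks, label)
}

# watertight solid between two radial profiles over a theta arc, extruded in z.
# Used for the RV crescent and for scar shells.
.ringSectorMesh <- function(zs, innerFn, outerFn, thetaRange, nTheta = 32,
                            label = "rv", landmarks = list()) {
  th <- seq(thetaRange[1], thetaRange[2], length.out = nTheta)
  nz <- length(zs)
  inner <- outer <- NULL
  for (z in zs) {
    ri <- innerFn(z); ro <- outerFn(z)
    inner <- rbind(inner, cbind(ri * cos(th), ri * sin(th), z))
    outer <- rbind(outer, cbind(ro * cos(th), ro * sin(th), z))
  }
  pts <- rbind(inner, outer)
  iIn <- function(i, j) (i - 1) * nTheta + j
  iOut <- function(i, j) nz * nTheta + (i - 1) * nTheta + j
  faces <- NULL
  for (i in seq_len(nz - 1)) {
    for (j in seq_len(nTheta - 1)) {
      faces <- rbind(faces,
        c(iIn(i, j), iIn(i + 1, j), iIn(i, j + 1)),
        c(iIn(i, j + 1), iIn(i + 1, j), iIn(i + 1, j + 1)),
        c(iOut(i, j), iOut(i, j + 1), iOut(i + 1, j)),
        c(iOut(i, j + 1), iOut(i + 1, j + 1), iOut(i + 1, j)))
    }
  }
  for (j in seq_len(nTheta - 1)) {  # z caps: strips between inner and outer arcs
    faces <- rbind(faces,
      c(iIn(1, j), iIn(1, j + 1), iOut(1, j)),
      c(iIn(1, j + 1), iOut(1, j + 1), iOut(1, j)),
      c(iIn(nz, j), iOut(nz, j), iIn(nz, j + 1)),
      c(iIn(nz, j + 1), iOut(nz, j), iOut(nz, j + 1)))
  }
  for (i in seq_len(nz - 1)) {      # theta side walls
    faces <- rbind(faces,
      c(iIn(i, 1), iOut(i, 1), iIn(i + 1, 1)),
      c(iIn(i + 1, 1), iOut(i, 1), iOut(i + 1, 1)),
      c(iIn(i, nTheta), iIn(i + 1, nTheta), iOut(i, nTheta)),
      c(iIn(i + 1, nTheta), iOut(i + 1, nTheta), iOut(i, nTheta)))
  }
  surfaceMesh(pts, faces, landmarks, label)
}

# UV sphere, used as an analytic rasterization fixture
.sphereMesh <- function(radius = 30, center = c(0, 0, 0), n = 60,
                        label = "endocardium") {
  phi <- seq(0, pi, length.out = n + 1)
  th <- seq(0, 2 * pi, length.out = 2 * n + 1)[-(2 * n + 1)]
  pts <- NULL
  for (p in phi[-c(1, n + 1)]) {
    pts <- rbind(pts, cbind(radius * sin(p) * cos(th),
                            radius * sin(p) * sin(th),
                            radius * cos(p)))
  }
  nTheta <- length(th); nRing <- n - 1
  idx <- function(i, j) (i - 1) * nTheta + ((j - 1) %% nTheta) + 1
  faces <- NULL
  for (i in seq_len(nRing - 1)) {
    for (j in seq_len(nTheta)) {
      faces <- rbind(faces,
        c(idx(i, j), idx(i, j + 1), idx(i + 1, j + 1)),
        c(idx(i, j), idx(i + 1, j + 1), idx(i + 1, j)))
    }
  }
  nPts <- nrow(pts)
  pts <- rbind(pts, c(0, 0, radius), c(0, 0, -radius))
  topI <- nPts + 1; botI <- nPts + 2
  for (j in seq_len(nTheta)) {
    faces <- rbind(faces,
      c(topI, idx(1, j + 1), idx(1, j)),
      c(botI, idx(nRing, j), idx(nRing, j + 1)))
  }
  pts <- sweep(pts, 2, center, "+")
  surfaceMesh(pts, faces, list(), label)
}

# ---- PLY I/O ----------------------------------------------------------------

#' Write a surface mesh as ASCII PLY
#'
#' Landmarks are written to a JSON sidecar (`<path>.landmarks.json`) when
#' present.
#'
#' @param mesh a [SurfaceMesh-class]
#' @param path output file path (`.ply`)
#' @return `path`, invisibly
#' @export
writeMeshPLY <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  np <- nrow(mesh@points); nf <- nrow(mesh@faces)
  writeLines(c("ply", "format ascii 1.0",
               paste("comment label", mesh@label),
               paste("element vertex", np),
               "property float x", "property float y", "property float z",
               paste("element face", nf),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(apply(mesh@points, 1, function(p)
    paste(format(p, trim = TRUE, scientific = FALSE), collapse = " ")), con)
  if (nf > 0)
    writeLines(apply(mesh@faces - 1L, 1, function(f)
      paste(c(3, f), collapse = " ")), con)
  if (length(mesh@landmarks))
    jsonlite::write_json(mesh@landmarks,
                         paste0(path, ".landmarks.json"), auto_unbox = FALSE)
  invisible(path)
}

#' Read an ASCII PLY surface mesh
#'
#' @param path `.ply` file; a `<path>.landmarks.json` sidecar is read when
#'   present.
#' @param label mesh label override; defaults to the label comment in the
#'   file, else `"endocardium"`.
#' @return a [SurfaceMesh-class]
#' @export
readMeshPLY <- function(path, label = NULL) {
  lines <- readLines(path)
  hEnd <- which(lines == "end_header")[1]
  header <- lines[seq_len(hEnd)]
  if (header[1] != "ply" || !any(grepl("format ascii", header)))
    stop("readMeshPLY: only ASCII PLY is supported: ", path)
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", header, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", header, value = TRUE)))
  if (is.null(label)) {
    lab <- grep("^comment label ", header, value = TRUE)
    label <- if (length(lab)) sub("^comment label ", "", lab[1]) else "endocardium"
  }
  body <- lines[-seq_len(hEnd)]
  pts <- matrix(as.numeric(unlist(strsplit(body[seq_len(nv)], " +"))),
                ncol = 3, byrow = TRUE)
  faces <- matrix(integer(), 0, 3)
  if (length(nf) && nf > 0) {
    fl <- strsplit(body[nv + seq_len(nf)], " +")
    faces <- t(vapply(fl, function(x) as.integer(x[2:4]) + 1L, integer(3)))
  }
  lmPath <- paste0(path, ".landmarks.json")
  lm <- if (file.exists(lmPath))
    lapply(jsonlite::read_json(lmPath, simplifyVector = TRUE), as.numeric)
  else list()
  surfaceMesh(pts, faces, lm, label)
}
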