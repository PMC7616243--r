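#' @include AllClasses.R mesh.R
NULL

# blocked brute-force nearest neighbours: index into `ref` for each row of `q`
.nearestIndex <- function(q, ref, block = 1024L) {
  refSq <- rowSums(ref^2)
  out <- integer(nrow(q))
  for (s in seq(1, nrow(q), by = block)) {
    e <- min(s + block - 1, nrow(q))
    d2 <- outer(rowSums(q[s:e, , drop = FALSE]^2), refSq, "+") -
      2 * q[s:e, , drop = FALSE] %*% t(ref)
    out[s:e] <- max.col(-d2, ties.method = "first")
  }
  out
}

# least-squares rigid fit mapping P onto Q (Kabsch/Umeyama, no scaling)
.kabsch <- function(P, Q) {
  cP <- colMeans(P); cQ <- colMeans(Q)
  H <- crossprod(sweep(P, 2, cP), sweep(Q, 2, cQ))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  rigidTransform(R, cQ - drop(R %*% cP))
}

.principalAxis <- function(points) {
  c0 <- colMeans(points)
  s <- svd(sweep(points, 2, c0), nu = 0)
  if (s$d[2] < 1e-9 * max(s$d[1], 1))
    stop("alignMajorAxis: degenerate point cloud (rank < 2)")
  list(axis = s$v[, 1], center = c0, sv = s$d)
}

# minimal rotation taking unit vector a onto unit vector b
.rotationBetween <- function(a, b) {
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  cth <- sum(a * b)
  if (sqrt(sum(v^2)) < 1e-12)
    return(if (cth > 0) diag(3) else rotationAboutAxis(.anyOrthogonal(a), 180))
  K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + K + K %*% K / (1 + cth)
}

.anyOrthogonal <- function(a) {
  v <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- v - sum(v * a) * a
  v / sqrt(sum(v^2))
}

.longAxisOf <- function(mesh) {
  lm <- mesh@landmarks
  if (!is.null(lm$apex) && !is.null(lm$base_center)) {
    ax <- lm$base_center - lm$apex
    ax / sqrt(sum(ax^2))
  } else NULL
}

#' Stage 1: align the major axes of two meshes
#'
#' Finds the rigid transform that maps the moving mesh's principal axis
#' (largest-variance direction of its vertices) onto the fixed mesh's and
#' brings the centroids together. The axis sign is disambiguated by the
#' apex / base-centre landmarks when present, otherwise by choosing the
#' orientation with the smaller post-alignment surface distance.
#'
#' @param moving,fixed [SurfaceMesh-class] objects.
#' @return a [RigidTransform-class]
#' @export
alignMajorAxis <- function(moving, fixed) {
  pM <- .principalAxis(moving@points)
  pF <- .principalAxis(fixed@points)
  aM <- pM$axis; aF <- pF$axis
  lmM <- .longAxisOf(moving); lmF <- .longAxisOf(fixed)
  if (!is.null(lmM)) aM <- aM * sign(sum(aM * lmM))
  if (!is.null(lmF)) aF <- aF * sign(sum(aF * lmF))
  candidates <- if (is.null(lmM) || is.null(lmF)) list(aM, -aM) else list(aM)
  best <- NULL
  for (a in candidates) {
    R <- .rotationBetween(a, aF)
    t <- rigidTransform(R, pF$center - drop(R %*% pM$center))
    if (length(candidates) == 1) { best <- t; break }
    moved <- applyTransform(moving, t)
    sub <- moved@points[seq(1, nrow(moved@points), length.out = min(300, nrow(moved@points))), , drop = FALSE]
    rms <- sqrt(mean(rowSums((sub - fixed@points[.nearestIndex(sub, fixed@points), , drop = FALSE])^2)))
    if (is.null(best) || rms < attr(best, "rms")) {
      attr(t, "rms") <- rms; best <- t
    }
  }
  best
}

#' Stage 2: align the RV junction points about the long axis
#'
#' Refines `init` with a single-degree-of-freedom rotation about the
#' fixed mesh's long axis, chosen in closed form to minimise the summed
#' squared distance between corresponding RV-junction landmarks. This
#' fixes the axial roll left free by the major-axis stage; the labelled
#' correspondence (anterior to anterior, inferior to inferior) resolves
#' the 180-degree ambiguity.
#'
#' @param moving,fixed [SurfaceMesh-class] objects carrying
#'   `rv_junction_anterior` and `rv_junction_inferior` landmarks.
#' @param init a [RigidTransform-class] from the previous stage.
#' @return a [RigidTransform-class] (rotation composed with `init`).
#' @export
alignRvJunctions <- function(moving, fixed, init = rigidTransform()) {
  need <- c("rv_junction_anterior", "rv_junction_inferior")
  for (nm in need) {
    if (is.null(moving@landmarks[[nm]]))
      stop("alignRvJunctions: moving mesh is missing landmark '", nm, "'")
    if (is.null(fixed@landmarks[[nm]]))
      stop("alignRvJunctions: fixed mesh is missing landmark '", nm, "'")
  }
  axis <- .longAxisOf(fixed)
  if (is.null(axis)) {
    axis <- .principalAxis(fixed@points)$axis
  }
  pivot <- colMeans(fixed@points)
  movedLm <- lapply(moving@landmarks[need],
                    function(p) drop(init@rotation %*% p) + init@translation)
  # optimal in-plane rotation angle by 2D Procrustes around the axis
  num <- 0; den <- 0
  for (nm in need) {
    a <- movedLm[[nm]] - pivot
    b <- fixed@landmarks[[nm]] - pivot
    a <- a - sum(a * axis) * axis
    b <- b - sum(b * axis) * axis
    num <- num + sum(axis * c(a[2] * b[3] - a[3] * b[2],
                              a[3] * b[1] - a[1] * b[3],
                              a[1] * b[2] - a[2] * b[1]))
    den <- den + sum(a * b)
  }
  theta <- atan2(num, den)
  R <- rotationAboutAxis(axis, theta * 180 / pi)
  step <- rigidTransform(R, pivot - drop(R %*% pivot))
  composeTransforms(step, init)
}

#' Stage 3: iterative-closest-point refinement on the endocardium
#'
#' Point-to-point ICP: alternate nearest-neighbour correspondence from
#' the transformed moving endocardium to the fixed endocardium with a
#' least-squares rigid fit, until the RMS correspondence distance
#' improves by less than `tol` or `maxIter` is reached. The per-iteration
#' RMS is non-increasing. Non-convergence is flagged in the `icp`
#' attribute of the result, not raised as an error.
#'
#' @param moving,fixed endocardium [SurfaceMesh-class] objects.
#' @param init starting [RigidTransform-class].
#' @param maxIter,tol iteration cap and RMS improvement tolerance (mm).
#' @param maxPoints moving-vertex subsample cap for correspondence search.
#' @return a [RigidTransform-class] with an `icp` attribute: list with
#'   `rms` (per-iteration), `iterations`, `converged`.
#' @export
registerEndocardium <- function(moving, fixed, init = rigidTransform(),
                                maxIter = 100L, tol = 1e-4,
                                maxPoints = 1000L) {
  P0 <- moving@points
  if (nrow(P0) > maxPoints)
    P0 <- P0[round(seq(1, nrow(P0), length.out = maxPoints)), , drop = FALSE]
  Q <- fixed@points
  t <- init
  rmsTrace <- numeric()
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    P <- sweep(P0 %*% t(t@rotation), 2, t@translation, "+")
    nn <- .nearestIndex(P, Q)
    rms <- sqrt(mean(rowSums((P - Q[nn, , drop = FALSE])^2)))
    rmsTrace <- c(rmsTrace, rms)
    if (it > 1 && (rmsTrace[it - 1] - rms) < tol) { converged <- TRUE; break }
    t <- .kabsch(P0, Q[nn, , drop = FALSE])
  }
  attr(t, "icp") <- list(rms = rmsTrace, iterations = length(rmsTrace),
                         converged = converged)
  t
}

#' Three-step MRI-to-CTA mesh registration
#'
#' Composes the full registration the data-generation pipeline uses to
#' carry an MRI-derived scar surface into CTA space: (1) major-axis
#' alignment, (2) RV-junction roll correction about the long axis, (3)
#' iterative-closest-point fine-tuning on the whole endocardium. The
#' returned transform maps MRI-space coordinates to CTA space; apply it
#' to the scar mesh with [applyTransform()].
#'
#' @param mri,cta [MeshSet-class] objects whose `endo` meshes carry apex,
#'   base-centre and RV-junction landmarks.
#' @param maxIter,tol ICP settings, see [registerEndocardium()].
#' @return a [RigidTransform-class] with `icp` and `stages` attributes.
#' @examples
#' pair <- generateMeshPair(phantomSpec(imageSize = 128, nSlices = 6, seed = 3),
#'   rigidTransform(rotationAboutAxis(c(0, 0, 1), 10), c(5, -3, 2)))
#' t <- registerMriToCta(meshSet(endo = pair$moving$endo),
#'                       meshSet(endo = pair$fixed$endo))
#' @export
registerMriToCta <- function(mri, cta, maxIter = 100L, tol = 1e-4) {
  stopifnot(is(mri, "MeshSet"), is(cta, "MeshSet"))
  if (is.null(mri@endo) || is.null(cta@endo))
    stop("registerMriToCta: both mesh sets must contain an endocardium mesh")
  t1 <- tryCatch(alignMajorAxis(mri@endo, cta@endo),
                 error = function(e) stop("stage major_axis: ", conditionMessage(e)))
  t2 <- tryCatch(alignRvJunctions(mri@endo, cta@endo, t1),
                 error = function(e) stop("stage rv_junctions: ", conditionMessage(e)))
  t3 <- tryCatch(registerEndocardium(mri@endo, cta@endo, t2,
                                     maxIter = maxIter, tol = tol),
                 error = function(e) stop("stage endocardium_icp: ", conditionMessage(e)))
  attr(t3, "stages") <- list(major_axis = t1, rv_junctions = t2)
  t3
}

#' Mean symmetric surface distance between two meshes
#'
#' Average of the two directed mean nearest-vertex distances; the
#' registration-quality metric used by the synthetic recovery checks.
#'
#' @param a,b [SurfaceMesh-class] objects.
#' @return distance in mm
#' @export
meanSurfaceDistance <- function(a, b) {
  pa <- a@points; pb <- b@points
  dab <- sqrt(rowSums((pa - pb[.nearestIndex(pa, pb), , drop = FALSE])^2))
  dba <- sqrt(rowSums((pb - pa[.nearestIndex(pb, pa), , drop = FALSE])^2))
  (mean(dab) + mean(dba)) / 2
}
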