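refPair <- function(seed = 3, transform = rigidTransform(), noiseSd = 0) {
  generateMeshPair(phantomSpec(imageSize = 128, nSlices = 6, seed = seed),
                   transform, noiseSd = noiseSd)
}

test_that("major-axis alignment recovers identity, rotation and translation", {
  pair <- refPair()
  fx <- pair$fixed@endo
  t0 <- alignMajorAxis(fx, fx)
  expect_equal(rotation(t0), diag(3), tolerance = 1e-6)
  expect_equal(translation(t0), c(0, 0, 0), tolerance = 1e-6)

  # rotation about an axis orthogonal to the long (z) axis
  gen <- rigidTransform(rotationAboutAxis(c(1, 0, 0), 30), c(0, 0, 0))
  mv <- applyTransform(fx, gen)
  t1 <- alignMajorAxis(mv, fx)
  resid <- composeTransforms(t1, gen)
  ang <- acos(pmin(1, (sum(diag(rotation(resid))) - 1) / 2)) * 180 / pi
  expect_lt(ang, 1)

  # pure translation: rotation stays identity
  mv2 <- applyTransform(fx, rigidTransform(diag(3), c(7, -4, 3)))
  t2 <- alignMajorAxis(mv2, fx)
  expect_equal(rotation(t2), diag(3), tolerance = 1e-6)
  expect_equal(translation(t2), c(-7, 4, -3), tolerance = 1e-6)
})

test_that("degenerate point clouds raise a geometry error", {
  line <- surfaceMesh(cbind(seq_len(10), 0, 0), landmarks = list())
  expect_error(alignMajorAxis(line, line), "degenerate")
})

test_that("RV-junction stage fixes axial roll and resolves the 180-degree flip", {
  pair <- refPair()
  fx <- pair$fixed@endo
  landDist <- function(m) {
    sum(vapply(c("rv_junction_anterior", "rv_junction_inferior"),
               function(nm) sum((meshLandmarks(m)[[nm]] -
                                 meshLandmarks(fx)[[nm]])^2), 1))
  }
  # already aligned: the refinement is a no-op
  t0 <- alignRvJunctions(fx, fx, rigidTransform())
  expect_equal(rotation(t0), diag(3), tolerance = 1e-6)

  for (roll in c(45, 180)) {
    gen <- rigidTransform(rotationAboutAxis(c(0, 0, 1), roll), c(0, 0, 0))
    mv <- applyTransform(fx, gen)
    before <- landDist(mv)
    t1 <- alignRvJunctions(mv, fx, rigidTransform())
    after <- landDist(applyTransform(mv, t1))
    expect_lt(after, 1e-10)          # exact 1-DOF optimum, labels matched
    expect_lt(after, before)
  }
})

test_that("missing RV-junction landmarks raise an error naming the landmark", {
  pair <- refPair()
  fx <- pair$fixed@endo
  bare <- surfaceMesh(fx@points, fx@faces, landmarks = list())
  expect_error(alignRvJunctions(bare, fx), "rv_junction_anterior")
})

test_that("ICP: identity input converges immediately; RMS is non-increasing", {
  fx <- refPair()$fixed@endo
  t0 <- registerEndocardium(fx, fx, rigidTransform())
  icp <- attr(t0, "icp")
  expect_lt(icp$rms[1], 1e-9)
  expect_true(all(diff(icp$rms) <= 1e-9))

  gen <- rigidTransform(rotationAboutAxis(c(0.3, 1, 0.5), 12), c(6, -5, 4))
  pair <- refPair(transform = gen)
  t1 <- registerMriToCta(meshSet(endo = pair$moving@endo),
                         meshSet(endo = pair$fixed@endo))
  icp1 <- attr(t1, "icp")
  expect_true(all(diff(icp1$rms) <= 1e-9))
  msd <- meanSurfaceDistance(applyTransform(pair$moving@endo, t1),
                             pair$fixed@endo)
  expect_lt(msd, 0.5)
})

test_that("with point jitter the final ICP RMS is bounded by twice the noise", {
  for (seed in 1:20) {
    gen <- rigidTransform(rotationAboutAxis(c(0, 0, 1), 8), c(2, 2, -1))
    pair <- refPair(seed = seed, transform = gen, noiseSd = 0.5)
    t1 <- registerMriToCta(meshSet(endo = pair$moving@endo),
                           meshSet(endo = pair$fixed@endo))
    expect_lt(tail(attr(t1, "icp")$rms, 1), 2 * 0.5)
  }
})

test_that("composed stage transforms stay orthonormal to 1e-9", {
  gen <- rigidTransform(rotationAboutAxis(c(1, 2, 3), 14), c(9, -2, 5))
  pair <- refPair(transform = gen)
  t1 <- registerMriToCta(meshSet(endo = pair$moving@endo),
                         meshSet(endo = pair$fixed@endo))
  R <- rotation(t1)
  expect_lt(max(abs(crossprod(R) - diag(3))), 1e-9)
  expect_equal(det(R), 1, tolerance = 1e-9)
})

test_that("applyTransform round-trips through the inverse and shifts centroids exactly", {
  fx <- refPair()$fixed@endo
  t <- rigidTransform(rotationAboutAxis(c(1, 1, 0), 25), c(3, 4, -2))
  back <- applyTransform(applyTransform(fx, t), invertTransform(t))
  expect_lt(max(abs(back@points - fx@points)), 1e-9)

  shift <- rigidTransform(diag(3), c(2.5, -1, 7))
  moved <- applyTransform(fx, shift)
  expect_equal(colMeans(moved@points) - colMeans(fx@points), c(2.5, -1, 7),
               tolerance = 1e-12)
  expect_identical(moved@faces, fx@faces)
})
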