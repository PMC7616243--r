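heartFixture <- function(seed = 5, imageSize = 150) {
  pair <- generateMeshPair(phantomSpec(imageSize = imageSize, nSlices = 10,
                                       seed = seed))
  pair$fixed
}

test_that("heart-coordinate conversion maps the long axis to +z, apex below base", {
  meshes <- heartFixture()
  # move everything into an arbitrary scanner frame first
  t <- rigidTransform(rotationAboutAxis(c(1, -2, 0.5), 35), c(40, -12, 60))
  scanner <- meshSet(endo = applyTransform(meshes@endo, t),
                     epi = applyTransform(meshes@epi, t))
  vol <- ctaVolume(array(0, c(8, 8, 8)), spacing = c(10, 10, 10))
  hc <- toHeartCoordinates(vol, scanner)
  lm <- meshLandmarks(hc$meshes@endo)
  expect_equal(lm$apex, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(lm$base_center[1:2], c(0, 0), tolerance = 1e-9)
  expect_gt(lm$base_center[3], 0)       # base above apex on +z
  # septal direction lands in the +x half-plane
  sept <- (lm$rv_junction_anterior + lm$rv_junction_inferior) / 2
  expect_gt(sept[1], 0)
  expect_equal(sept[2], 0, tolerance = 1e-6)

  # transform is invertible: scanner -> heart -> scanner
  ht <- attr(hc$volume, "heartTransform")
  back <- applyTransform(hc$meshes@endo, invertTransform(ht))
  expect_lt(max(abs(back@points - scanner@endo@points)), 1e-6)
})

test_that("missing landmarks are a contract error", {
  meshes <- heartFixture()
  bare <- meshSet(endo = surfaceMesh(meshes@endo@points, meshes@endo@faces))
  vol <- ctaVolume(array(0, c(4, 4, 4)))
  expect_error(toHeartCoordinates(vol, bare), "apex")
})

test_that("sampleShortAxis: slice count, midpoint convention, constant volumes", {
  meshes <- heartFixture()
  vol <- ctaVolume(array(77, c(20, 20, 20)), spacing = c(8, 8, 8),
                   origin = c(-75, -75, -30))
  sl <- sampleShortAxis(vol, meshes, nSlices = 7, gridSize = 100, fov = 120)
  expect_length(sl, 7)
  # constant volume -> constant slices
  expect_lt(max(abs(sl[[4]]@image - 77)), 1e-9)
  # plane normals along the axis, constant spacing
  zs <- vapply(sl, function(s) s@plane$origin[3], 1)
  expect_lt(diff(range(diff(zs))), 1e-9)
  # single slice at the midpoint of the axis
  lm <- meshLandmarks(meshes@endo)
  s1 <- sampleShortAxis(vol, meshes, nSlices = 1, gridSize = 50, fov = 120)
  expect_equal(s1[[1]]@plane$origin[3], (lm$apex[3] + lm$base_center[3]) / 2)
})

test_that("resampling is intensity-bounded by the volume range", {
  meshes <- heartFixture()
  set.seed(4)
  vox <- array(rnorm(20^3, 100, 50), c(20, 20, 20))
  vol <- ctaVolume(vox, spacing = c(8, 8, 8), origin = c(-75, -75, -30))
  sl <- sampleShortAxis(vol, meshes, nSlices = 3, gridSize = 80, fov = 120)
  for (s in sl) {
    expect_gte(min(s@image), min(vox))
    expect_lte(max(s@image), max(vox))
  }
})

test_that("a sphere sliced through its centre rasterizes to a disk of the right area", {
  sph <- cardioscar:::.sphereMesh(radius = 30, center = c(0, 0, 0), n = 60)
  m <- rasterizeMasks(meshSet(endo = sph), list(origin = c(0, 0, 0)),
                      list(gridSize = 600L, fov = 120))
  area <- sum(m$endo) * (120 / 600)^2
  expect_equal(area, pi * 30^2, tolerance = 0.02 * pi * 30^2)
  # a plane outside the mesh extent gives an empty mask
  m2 <- rasterizeMasks(meshSet(endo = sph), list(origin = c(0, 0, 40)),
                       list(gridSize = 100L, fov = 120))
  expect_equal(sum(m2$endo), 0)
})

test_that("open meshes are rejected naming the mesh", {
  sph <- cardioscar:::.sphereMesh(radius = 20, n = 20)
  open <- surfaceMesh(sph@points, sph@faces[-1, , drop = FALSE])
  expect_error(
    rasterizeMasks(meshSet(endo = open), list(origin = c(0, 0, 0)),
                   list(gridSize = 50L, fov = 100)),
    "endocardium")
})

test_that("mesh-derived masks nest: endo inside epi, scar inside myocardium", {
  pair <- generateMeshPair(smallScarSpec(seed = 11, burden = 0.35,
                                         imageSize = 150, nSlices = 10))
  meshes <- pair$fixed
  sl <- sampleShortAxis(
    ctaVolume(array(0, c(10, 10, 10)), spacing = c(15, 15, 15),
              origin = c(-70, -70, -25)),
    meshes, nSlices = 5, gridSize = 120, fov = 120)
  mid <- sl[[3]]
  expect_true(all(mid@endoMask <= mid@epiMask))
  myo <- myocardiumMask(mid)
  expect_equal(myo, mid@epiMask * (1 - mid@endoMask))
  # scar rasterized from a shell strictly inside the myocardium
  expect_gt(sum(mid@scarMask), 0)
  outside <- sum(mid@scarMask * (1 - myo))
  expect_lte(outside / sum(mid@scarMask), 0.02)
})
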