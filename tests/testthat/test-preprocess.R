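test_that("zoom arithmetic: 600 px at factor 0.6 gives 360 px; factor 1 is a no-op", {
  rec <- annularSlice(sz = 600, rEndo = 90, rEpi = 150)
  z <- zoomSlice(rec, 0.6)
  expect_identical(dim(z@image), c(360L, 360L))
  expect_identical(dim(z@endoMask), c(360L, 360L))
  expect_true(all(z@endoMask %in% c(0, 1)))   # masks stay binary
  expect_identical(zoomSlice(rec, 1), rec)
  expect_error(zoomSlice(rec, 0), "factor")
  # all-ones mask survives nearest-neighbour zoom as all ones
  ones <- sliceRecord(rec@image, rec@endoMask * 0 + 1, rec@epiMask * 0 + 1,
                      rec@rvMask * 0 + 1, rec@scarMask * 0 + 1)
  zo <- zoomSlice(ones, 0.6)
  expect_true(all(zo@endoMask == 1))
})

test_that("crop is centred on the endocardial centroid with a bounded offset", {
  rec <- zoomSlice(annularSlice(sz = 150, rEndo = 12, rEpi = 22, rvArc = 100), 0.6)
  ns0 <- cropSlice(rec, size = 64, maxOffset = 0, training = TRUE)
  expect_identical(ns0$cropOffset, c(0L, 0L))
  w <- which(rec@endoMask == 1, arr.ind = TRUE)
  ctr <- round(colMeans(w))
  expect_identical(dim(ns0$image), c(64L, 64L))
  expect_identical(dim(ns0$seg), c(64L, 64L, 3L))
  # window centred at the centroid (checked through the endo channel centroid)
  wc <- which(ns0$seg[, , 1] == 1, arr.ind = TRUE)
  expect_equal(as.numeric(round(colMeans(wc))), c(33, 33), tolerance = 1)
  # fixed seed gives identical offsets
  set.seed(9); a <- cropSlice(rec, size = 64, maxOffset = 5)
  set.seed(9); b <- cropSlice(rec, size = 64, maxOffset = 5)
  expect_identical(a$cropOffset, b$cropOffset)
  expect_true(all(abs(a$cropOffset) <= 5))
  expect_identical(a$image, b$image)
})

test_that("the crop window shifts to keep the RV inside", {
  sz <- 96
  rec <- annularSlice(sz = sz, rEndo = 10, rEpi = 18, rvArc = 120)
  # push the anatomy towards the right edge by rolling the masks
  roll <- function(m, k) cbind(m[, (sz - k + 1):sz], m[, 1:(sz - k)])
  shifted <- sliceRecord(roll(rec@image, 20), roll(rec@endoMask, 20),
                         roll(rec@epiMask, 20), roll(rec@rvMask, 20),
                         roll(rec@scarMask, 20))
  ns <- cropSlice(shifted, size = 64, maxOffset = 0, training = FALSE)
  # every RV pixel of the source is inside the crop window
  expect_equal(sum(ns$seg[, , 3]), sum(shifted@rvMask))
})

test_that("intensity normalisation maps the window ends to 0 and 1", {
  expect_equal(normalizeIntensity(-200), 0)
  expect_equal(normalizeIntensity(800), 1)
  expect_equal(normalizeIntensity(300), 0.5)
  expect_equal(normalizeIntensity(c(-1e4, 1e4)), c(0, 1))  # clipped
  expect_equal(normalizeIntensity(0, window = c(-10, 10)), 0.5)
})

test_that("prepared datasets have the shape contract and carry labels unchanged", {
  cases <- list(generatePhantomCase(smallScarSpec(seed = 31, imageSize = 150,
                                                  nSlices = 5)))
  ds <- prepareDataset(cases, inputSize = 64, zoom = 0.6, maxOffset = 3,
                       seed = 2)
  n <- dim(ds$images)[3]
  expect_identical(dim(ds$images)[c(1, 2, 4)], c(64L, 64L, 1L))
  expect_identical(dim(ds$seg)[c(1, 2, 4)], c(64L, 64L, 3L))
  expect_true(all(ds$images >= 0 & ds$images <= 1))
  expect_true(all(ds$seg %in% c(0, 1)))
  expect_equal(nrow(ds$labels), n)
  # labels equal those computed on the native grid before zoom/crop
  lab <- labelCase(cases[[1]])
  kept <- lab[!lab$excluded, ]
  expect_equal(ds$labels$lateral_scar, kept$lateral_scar)
  expect_equal(ds$labels$septal_scar, kept$septal_scar)
})
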