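#' @include AllClasses.R labeling.R
NULL

#' Zoom a slice record
#'
#' Down-samples the square slice by `factor` (0.6 maps the native
#' 600 x 600 grid to 360 x 360). The image is bilinearly interpolated;
#' masks use nearest-neighbour resampling so they stay binary.
#'
#' @param record a [SliceRecord-class]
#' @param factor zoom factor > 0.
#' @return the zoomed [SliceRecord-class]
#' @export
zoomSlice <- function(record, factor = 0.6) {
  if (factor <= 0) stop("zoomSlice: factor must be > 0")
  d <- dim(record@image)
  if (d[1] != d[2]) stop("zoomSlice: input must be square")
  side <- round(d[1] * factor)
  if (factor == 1) return(record)
  img <- EBImage::resize(record@image, w = side, h = side, filter = "bilinear")
  rs <- function(m) {
    r <- EBImage::resize(m, w = side, h = side, filter = "none")
    (r > 0.5) * 1
  }
  sliceRecord(as.matrix(img), rs(record@endoMask), rs(record@epiMask),
              rs(record@rvMask), rs(record@scarMask),
              patientId = record@patientId, sliceIndex = record@sliceIndex,
              plane = record@plane)
}

#' Map intensities linearly to [0, 1]
#'
#' Values at or below the window minimum map to 0, at or above the
#' maximum to 1. The default window (-200 to 800, HU-like) spans
#' background through contrast-filled blood pool.
#'
#' @param image numeric matrix/array.
#' @param window length-2 numeric `(min, max)`.
#' @return array of the same shape in `[0, 1]`
#' @export
normalizeIntensity <- function(image, window = c(-200, 800)) {
  pmin(pmax((image - window[1]) / (window[2] - window[1]), 0), 1)
}

#' Crop a slice to the network input size
#'
#' The crop window is centred at the endocardial-mask centroid plus, in
#' training mode, a uniform integer offset in `[-maxOffset, maxOffset]`
#' per axis (so that not all inputs are perfectly centred); evaluation
#' uses a zero offset. If the RV mask would be clipped, the window is
#' shifted minimally to include it; when the RV cannot fit in any window
#' of this size, the crop falls back to the centroid window and the
#' sample is flagged `rvClipped`. Intensities are normalised to `[0, 1]`
#' with [normalizeIntensity()].
#'
#' @param record a (typically zoomed) [SliceRecord-class]
#' @param labels optional [RegionLabels-class] carried through unchanged
#'   (labels are computed before any geometric preprocessing).
#' @param size crop side in pixels.
#' @param maxOffset maximum |offset| per axis in pixels.
#' @param training logical: sample a random offset (from the current RNG
#'   stream) or use zero.
#' @param offset explicit `(drow, dcol)` override.
#' @param window intensity window for normalisation.
#' @return a NetworkSample: list with `image` (size x size in `[0, 1]`),
#'   `seg` (size x size x 3 binary array: endo, epi, rv), `scar`, `labels`,
#'   `patientId`, `sliceIndex`, `cropOffset`, `rvClipped`.
#' @export
cropSlice <- function(record, labels = NULL, size = 256L, maxOffset = 20L,
                      training = TRUE, offset = NULL,
                      window = c(-200, 800)) {
  d <- dim(record@image)
  if (d[1] < size || d[2] < size)
    stop("cropSlice: input ", d[1], "x", d[2], " smaller than crop size ", size)
  if (sum(record@endoMask) == 0)
    stop("cropSlice: endocardial mask is empty; cannot locate the region of interest")
  if (is.null(offset)) {
    offset <- if (training && maxOffset > 0)
      c(sample(-maxOffset:maxOffset, 1), sample(-maxOffset:maxOffset, 1))
    else c(0L, 0L)
  }
  w <- which(record@endoMask == 1, arr.ind = TRUE)
  ctr <- round(colMeans(w))
  start <- ctr - size %/% 2 + offset  # (row, col) of window corner, 1-based
  clamp <- function(s, dmax) pmin(pmax(s, 1), dmax - size + 1)
  start <- clamp(start, d)
  rvClipped <- FALSE
  if (sum(record@rvMask) > 0) {
    rw <- which(record@rvMask == 1, arr.ind = TRUE)
    lo <- apply(rw, 2, min); hi <- apply(rw, 2, max)
    if (any(hi - lo + 1 > size)) {
      rvClipped <- TRUE
      start <- clamp(ctr - size %/% 2, d)
    } else {
      # shift minimally so the RV bounding box fits inside the window
      start <- pmax(start, hi - size + 1)
      start <- pmin(start, lo)
      start <- clamp(start, d)
    }
  }
  rows <- start[1]:(start[1] + size - 1)
  cols <- start[2]:(start[2] + size - 1)
  seg <- array(c(record@endoMask[rows, cols], record@epiMask[rows, cols],
                 record@rvMask[rows, cols]), c(size, size, 3))
  structure(list(image = normalizeIntensity(record@image[rows, cols], window),
                 seg = seg, scar = record@scarMask[rows, cols],
                 labels = labels, patientId = record@patientId,
                 sliceIndex = record@sliceIndex,
                 cropOffset = as.integer(offset), rvClipped = rvClipped),
            class = "NetworkSample")
}

#' Prepare a network-ready dataset from phantom cases
#'
#' Runs the full preprocessing chain per kept slice (exclusion filters
#' and labeling on the native grid, then zoom and crop) and stacks the
#' results into `(H, W, N, C)` tensors for training. With
#' `training = TRUE` the crop offsets are drawn once per slice under
#' `seed` (static augmentation, as when preprocessed shards are written
#' to disk); with `training = FALSE` crops are centred.
#'
#' @param cases list of [PhantomCase-class] (or lists of
#'   [SliceRecord-class]).
#' @param inputSize crop/network size in pixels.
#' @param zoom zoom factor applied before cropping.
#' @param maxOffset crop offset bound (scaled from the 20 px default at
#'   256 px if NULL).
#' @param training random crop offsets (TRUE) or centred (FALSE).
#' @param seed RNG seed for the offsets.
#' @return list: `images` (H, W, N, 1), `seg` (H, W, N, 3), `labels`
#'   data.frame (patient_id, slice_index, septal_scar, lateral_scar).
#' @export
prepareDataset <- function(cases, inputSize = 256L, zoom = 0.6,
                           maxOffset = NULL, training = TRUE, seed = 1L) {
  if (is.null(maxOffset)) maxOffset <- max(1L, round(20 * inputSize / 256))
  .withSeed(seed, {
    imgs <- list(); segs <- list(); rows <- list()
    for (case in cases) {
      slices <- if (is(case, "PhantomCase")) case@slices else case
      lab <- labelCase(slices)
      for (k in seq_along(slices)) {
        if (lab$excluded[k]) next
        rec <- zoomSlice(slices[[k]], zoom)
        ns <- cropSlice(rec, size = inputSize, maxOffset = maxOffset,
                        training = training)
        imgs[[length(imgs) + 1]] <- ns$image
        segs[[length(segs) + 1]] <- ns$seg
        rows[[length(rows) + 1]] <- lab[k, c("patient_id", "slice_index",
                                             "septal_scar", "lateral_scar")]
      }
    }
    n <- length(imgs)
    if (n == 0) stop("prepareDataset: no slices survived the exclusion filters")
    images <- array(0, c(inputSize, inputSize, n, 1))
    seg <- array(0, c(inputSize, inputSize, n, 3))
    for (k in seq_len(n)) {
      images[, , k, 1] <- imgs[[k]]
      seg[, , k, ] <- segs[[k]]
    }
    list(images = images, seg = seg, labels = do.call(rbind, rows))
  })
}
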