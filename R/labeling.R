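#' @include AllClasses.R
NULL

#' Default septal adjacency radius
#'
#' 12 px at the native 600 x 600 slice size, scaled proportionally for
#' other grids (minimum 3 px).
#'
#' @param imageSize slice side in pixels.
#' @return adjacency radius in pixels
#' @export
defaultAdjacencyRadius <- function(imageSize) {
  max(3, round(12 * imageSize / 600))
}

#' Septal region of the myocardium
#'
#' The septal wall is defined by adjacency to the right ventricle: all
#' myocardium pixels within `adjacencyRadius` (Euclidean distance
#' transform) of any RV pixel. The remaining myocardium is the lateral
#' wall (which here includes the anterior and inferior segments).
#'
#' @param myocardium,rv binary matrices of equal size.
#' @param adjacencyRadius distance threshold in pixels.
#' @return binary matrix, a subset of `myocardium`.
#' @export
computeSeptalMask <- function(myocardium, rv,
                              adjacencyRadius = defaultAdjacencyRadius(nrow(myocardium))) {
  stopifnot(identical(dim(myocardium), dim(rv)))
  if (sum(rv) == 0)
    stop(structure(class = c("cardioscar_no_rv", "error", "condition"),
                   list(message = "computeSeptalMask: RV mask is empty (no_rv); slice should be excluded",
                        call = sys.call())))
  dist <- EBImage::distmap(1 - rv)
  (myocardium == 1 & dist <= adjacencyRadius) * 1
}

#' Label septal and lateral scar in one slice
#'
#' Splits the myocardium into septal (RV-adjacent) and lateral regions and
#' labels each region scar-positive when the scar mask covers at least
#' `threshold` (default 10\%) of that region's myocardial pixels
#' (inclusive comparison).
#'
#' @param myocardium,rv,scar binary matrices of equal size.
#' @param threshold scar-volume fraction for a positive label.
#' @param adjacencyRadius septal adjacency distance in pixels.
#' @return a [RegionLabels-class] (not excluded).
#' @examples
#' myo <- matrix(0, 64, 64); myo[20:44, 20:24] <- 1; myo[20:44, 40:44] <- 1
#' rv <- matrix(0, 64, 64); rv[20:44, 14:18] <- 1
#' scar <- matrix(0, 64, 64); scar[20:40, 40:42] <- 1
#' labelRegions(myo, rv, scar)
#' @export
labelRegions <- function(myocardium, rv, scar, threshold = 0.10,
                         adjacencyRadius = defaultAdjacencyRadius(nrow(myocardium))) {
  stopifnot(identical(dim(myocardium), dim(scar)))
  septal <- computeSeptalMask(myocardium, rv, adjacencyRadius)
  lateral <- myocardium * (1 - septal)
  nS <- sum(septal); nL <- sum(lateral)
  if (nS == 0 || nL == 0)
    stop("labelRegions: region with zero myocardium pixels (septal: ",
         nS, ", lateral: ", nL, ")")
  fS <- sum(scar * septal) / nS
  fL <- sum(scar * lateral) / nL
  regionLabels(septalScar = fS >= threshold, lateralScar = fL >= threshold,
               septalFraction = fS, lateralFraction = fL)
}

#' Slice exclusion filters
#'
#' Applies the three exclusion criteria in order: (1) minimum myocardial
#' volume of `minMyo` pixels (a smaller myocardium indicates the slice is
#' near the apex or above the base; the boundary is inclusive, a slice
#' with exactly `minMyo` pixels is kept); (2) no RV visible (apical
#' slices, where the septal region cannot be determined); (3)
#' self-intersecting myocardium (the aortic valve at the base), detected
#' as a mask-topology failure: the myocardium must be a single connected
#' component whose single interior hole contains the endocardial mask.
#'
#' @param record a [SliceRecord-class]
#' @param minMyo minimum myocardium pixel count to keep a slice.
#' @return list with elements `keep` (logical) and `reason` (one of
#'   `"none"`, `"low_myocardium"`, `"no_rv"`, `"self_intersection"`).
#' @export
slicePassesFilters <- function(record, minMyo = 50) {
  myo <- myocardiumMask(record)
  if (sum(myo) < minMyo)
    return(list(keep = FALSE, reason = "low_myocardium"))
  if (sum(record@rvMask) == 0)
    return(list(keep = FALSE, reason = "no_rv"))
  comps <- EBImage::bwlabel(myo)
  if (max(comps) != 1)
    return(list(keep = FALSE, reason = "self_intersection"))
  filled <- EBImage::fillHull(myo)
  hole <- filled - myo
  if (sum(hole) == 0 || sum(record@endoMask) == 0 ||
      any(record@endoMask == 1 & hole == 0))
    return(list(keep = FALSE, reason = "self_intersection"))
  holeComps <- EBImage::bwlabel(hole)
  if (max(holeComps) != 1)
    return(list(keep = FALSE, reason = "self_intersection"))
  list(keep = TRUE, reason = "none")
}

#' Label all slices of a case
#'
#' Runs the exclusion filters and region labeling over a list of slices
#' and returns one row per slice.
#'
#' @param slices list of [SliceRecord-class] (or a [PhantomCase-class]).
#' @param threshold scar-fraction threshold for a positive label.
#' @param minMyo minimum myocardium pixel count.
#' @param adjacencyRadius septal adjacency distance; default scales with
#'   the slice size.
#' @return data.frame with columns patient_id, slice_index, excluded,
#'   reason, septal_scar, lateral_scar, septal_fraction, lateral_fraction.
#' @export
labelCase <- function(slices, threshold = 0.10, minMyo = 50,
                      adjacencyRadius = NULL) {
  if (is(slices, "PhantomCase")) slices <- slices@slices
  rows <- lapply(slices, function(rec) {
    adj <- if (is.null(adjacencyRadius))
      defaultAdjacencyRadius(nrow(rec@image)) else adjacencyRadius
    flt <- slicePassesFilters(rec, minMyo = minMyo)
    if (!flt$keep) {
      data.frame(patient_id = rec@patientId, slice_index = rec@sliceIndex,
                 excluded = TRUE, reason = flt$reason,
                 septal_scar = NA, lateral_scar = NA,
                 septal_fraction = NA_real_, lateral_fraction = NA_real_)
    } else {
      lab <- labelRegions(myocardiumMask(rec), rec@rvMask, rec@scarMask,
                          threshold = threshold, adjacencyRadius = adj)
      data.frame(patient_id = rec@patientId, slice_index = rec@sliceIndex,
                 excluded = FALSE, reason = "none",
                 septal_scar = lab@septalScar, lateral_scar = lab@lateralScar,
                 septal_fraction = lab@septalFraction,
                 lateral_fraction = lab@lateralFraction)
    }
  })
  do.call(rbind, rows)
}

#' Class balance of a labeled dataset
#'
#' Counts scar-positive slices per region among non-excluded slices and
#' reports percentages to one decimal, the form in which cohort class
#' balance is usually quoted (e.g. 285 septal positives of 2682 slices is
#' 10.6\%).
#'
#' @param labels list of [RegionLabels-class], or a data.frame from
#'   [labelCase()].
#' @return data.frame with columns region, positives, total, percentage.
#' @export
classBalance <- function(labels) {
  if (is.data.frame(labels)) {
    kept <- labels[!labels$excluded, , drop = FALSE]
    if (nrow(kept) == 0) stop("classBalance: no non-excluded slices")
    pos <- c(septal = sum(kept$septal_scar), lateral = sum(kept$lateral_scar))
    total <- nrow(kept)
  } else {
    if (length(labels) == 0) stop("classBalance: empty label list")
    keep <- !vapply(labels, function(l) l@excluded, TRUE)
    kept <- labels[keep]
    if (length(kept) == 0) stop("classBalance: no non-excluded slices")
    pos <- c(septal = sum(vapply(kept, function(l) isTRUE(l@septalScar), TRUE)),
             lateral = sum(vapply(kept, function(l) isTRUE(l@lateralScar), TRUE)))
    total <- length(kept)
  }
  data.frame(region = .REGIONS, positives = as.integer(pos[.REGIONS]),
             total = total,
             percentage = round(100 * as.numeric(pos[.REGIONS]) / total, 1))
}

#' Write / read slice labels as CSV
#'
#' @param labels data.frame from [labelCase()].
#' @param path CSV file path.
#' @return `path` (write) or the data.frame (read).
#' @export
writeLabelsCSV <- function(labels, path) {
  write.csv(labels, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeLabelsCSV
#' @export
readLabelsCSV <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
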