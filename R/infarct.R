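#' Fraction of a region covered by a lesion
#'
#' Voxel-count intersection of a region mask with a lesion mask, divided by
#' the region's voxel count on the grid where the intersection is computed
#' (the subject DWI grid, after resampling).
#'
#' @param region_mask,lesion_mask Binary \code{\link{volume3d}}s on the same
#'   grid.
#' @return List with \code{fraction} in [0,1], \code{n_region} and
#'   \code{n_intersect} voxel counts.
#' @export
overlap_fraction <- function(region_mask, lesion_mask) {
  stopifnot(inherits(region_mask, "volume3d"), inherits(lesion_mask, "volume3d"))
  if (!identical(dim(region_mask$data), dim(lesion_mask$data)))
    stop("region and lesion masks are not on the same grid", call. = FALSE)
  if (!is_binary_volume(region_mask) || !is_binary_volume(lesion_mask))
    stop("masks must be binary", call. = FALSE)
  n_region <- sum(region_mask$data)
  if (n_region == 0) stop("empty region mask", call. = FALSE)
  n_int <- sum(region_mask$data * lesion_mask$data)
  list(fraction = n_int / n_region, n_region = n_region, n_intersect = n_int)
}

# Boundary-exact >= comparison of a voxel-count ratio against a decimal
# threshold: compares integer counts so that e.g. 120/400 vs 0.30 is decided
# without floating-point surprises. Thresholds are taken to 4 decimals.
meets_overlap_threshold <- function(n_intersect, n_region, threshold) {
  n_intersect * 10000 >= round(threshold * 10000) * n_region
}

#' Label occlusion-side regions as infarcted from a DWI lesion mask
#'
#' A region counts as infarcted when at least \code{threshold} (30\% by
#' default, boundary inclusive) of its voxels intersect the final infarct
#' lesion mask. The denominator is the region's voxel count after resampling
#' to the DWI grid. Only occlusion-side regions are labeled: the cohort this
#' models is unilateral large vessel occlusion.
#'
#' @param atlas \code{aspects_atlas} resampled onto the DWI grid.
#' @param lesion Binary lesion \code{\link{volume3d}} on the same grid.
#' @param occlusion_side \code{"left"} or \code{"right"}.
#' @param threshold Overlap fraction at or above which a region is
#'   infarcted (default 0.30).
#' @param patient_id Identifier copied into the output.
#' @return Data frame, one row per region: \code{patient_id}, \code{region},
#'   \code{overlap_fraction}, \code{n_region}, \code{n_intersect},
#'   \code{infarcted}.
#' @export
label_regions <- function(atlas, lesion, occlusion_side, threshold = 0.30,
                          patient_id = "subject") {
  stopifnot(inherits(atlas, "aspects_atlas"))
  occlusion_side <- match.arg(occlusion_side, c("left", "right"))
  rows <- lapply(ASPECTS_REGIONS, function(r) {
    ov <- overlap_fraction(atlas$masks[[region_key(r, occlusion_side)]], lesion)
    data.frame(patient_id = patient_id, region = r,
               overlap_fraction = ov$fraction,
               n_region = ov$n_region, n_intersect = ov$n_intersect,
               infarcted = meets_overlap_threshold(ov$n_intersect, ov$n_region,
                                                   threshold),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Lesion volume in millilitres
#'
#' @param lesion Binary \code{\link{volume3d}}.
#' @return Volume in mL: voxel count times voxel volume (mm^3) / 1000.
#' @export
infarct_volume_ml <- function(lesion) {
  stopifnot(inherits(lesion, "volume3d"))
  if (!is_binary_volume(lesion)) stop("lesion mask must be binary", call. = FALSE)
  sum(lesion$data) * prod(lesion$voxel_dims) / 1000
}

#' ASPECTS from region infarct labels
#'
#' One point is deducted from 10 for each infarcted region, so 10 means no
#' region affected and 0 means all ten affected.
#'
#' @param labels Either the data frame returned by \code{\link{label_regions}}
#'   (or any data frame with \code{region} and \code{infarcted} columns), or
#'   a logical vector of length 10 (optionally named by region).
#' @return Integer score 0-10.
#' @export
dwi_aspects <- function(labels) {
  if (is.data.frame(labels)) {
    regions <- labels$region
    infarcted <- labels$infarcted
  } else {
    infarcted <- labels
    regions <- names(labels)
  }
  if (length(infarcted) != 10L)
    stop("expected exactly 10 region labels, got ", length(infarcted),
         call. = FALSE)
  if (!is.null(regions)) {
    if (anyDuplicated(regions))
      stop("duplicate region labels: ",
           paste(unique(regions[duplicated(regions)]), collapse = ", "),
           call. = FALSE)
    if (!setequal(regions, ASPECTS_REGIONS))
      stop("labels must cover the 10 ASPECTS regions exactly", call. = FALSE)
  }
  if (anyNA(infarcted)) stop("missing infarct labels", call. = FALSE)
  10L - sum(as.logical(infarcted))
}

#' Patient-level record assembly
#'
#' Convenience constructor combining the per-patient quantities used by the
#' outcome statistics: poor outcome is defined as a 3-month modified Rankin
#' Scale score above 2.
#'
#' @param patient_id Identifier.
#' @param occlusion_side \code{"left"} or \code{"right"}.
#' @param dwi_aspects Integer 0-10 from \code{\link{dwi_aspects}}.
#' @param threshold_aspects Integer 0-10 from \code{\link{threshold_aspects}}.
#' @param infarct_volume_ml Final infarct volume in mL.
#' @param mrs_3month Modified Rankin Scale 0-6 (may be \code{NA}).
#' @param visual_aspects Optional expert visual reading 0-10.
#' @return One-row data frame including derived \code{poor_outcome}.
#' @export
patient_record <- function(patient_id, occlusion_side, dwi_aspects = NA_integer_,
                           threshold_aspects = NA_integer_,
                           infarct_volume_ml = NA_real_, mrs_3month = NA_integer_,
                           visual_aspects = NA_integer_) {
  for (s in list(dwi_aspects, threshold_aspects, visual_aspects))
    if (!is.na(s) && (s < 0 || s > 10))
      stop("ASPECTS scores must lie in 0-10", call. = FALSE)
  if (!is.na(mrs_3month) && (mrs_3month < 0 || mrs_3month > 6))
    stop("mRS must lie in 0-6", call. = FALSE)
  data.frame(patient_id = patient_id,
             occlusion_side = match.arg(occlusion_side, c("left", "right")),
             dwi_aspects = dwi_aspects, threshold_aspects = threshold_aspects,
             visual_aspects = visual_aspects,
             infarct_volume_ml = infarct_volume_ml, mrs_3month = mrs_3month,
             poor_outcome = if (is.na(mrs_3month)) NA else mrs_3month > 2,
             stringsAsFactors = FALSE)
}
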