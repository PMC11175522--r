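#' Mean attenuation of a region after Hounsfield-unit filtering
#'
#' Arithmetic mean of the CTA intensities inside a binary region mask,
#' restricted to voxels in the inclusive range \code{[hu_min, hu_max]}
#' (1-250 HU by default). The filter suppresses air/CSF, bone and
#' contrast-filled vessels, compensating for small coregistration errors and
#' bolus-timing differences between scans.
#'
#' @param cta CTA \code{\link{volume3d}} in Hounsfield units.
#' @param mask Binary \code{volume3d} on the same grid.
#' @param hu_min,hu_max Inclusive HU bounds (defaults 1 and 250).
#' @param region Optional region key, used to tag the error when no voxel
#'   survives the filter.
#' @return List with \code{mean} (HU) and \code{n} (included voxel count).
#' @export
region_mean_hu <- function(cta, mask, hu_min = 1, hu_max = 250, region = NULL) {
  stopifnot(inherits(cta, "volume3d"), inherits(mask, "volume3d"))
  if (!identical(dim(cta$data), dim(mask$data)))
    stop("cta and mask are not on the same grid", call. = FALSE)
  if (!is_binary_volume(mask)) stop("mask must be binary", call. = FALSE)
  vals <- cta$data[mask$data == 1]
  vals <- vals[vals >= hu_min & vals <= hu_max]
  if (!length(vals))
    stop("empty region after HU filter",
         if (!is.null(region)) paste0(": ", region), call. = FALSE)
  list(mean = mean(vals), n = length(vals))
}

#' Relative Hounsfield units of the ten occlusion-side ASPECTS regions
#'
#' For each ASPECTS region on the occluded side, divides its HU-filtered
#' mean attenuation by that of the corresponding contralateral region,
#' giving the dimensionless rHU ratio (1 = perfect hemispheric symmetry,
#' < 1 = hypo-attenuation on the occlusion side). The same HU filter is
#' applied to both hemispheres.
#'
#' @param cta Subject CTA \code{\link{volume3d}}.
#' @param atlas \code{aspects_atlas} already resampled onto the CTA grid
#'   (see \code{\link{resample_atlas}}).
#' @param occlusion_side \code{"left"} or \code{"right"}.
#' @param hu_min,hu_max Inclusive HU filter bounds (defaults 1 and 250).
#' @param patient_id Identifier copied into the output.
#' @return Data frame with one row per region: \code{patient_id},
#'   \code{region}, \code{hemisphere_occluded}, \code{rhu},
#'   \code{ipsi_mean_hu}, \code{contra_mean_hu}, \code{n_voxels_ipsi},
#'   \code{n_voxels_contra}.
#' @export
compute_rhu <- function(cta, atlas, occlusion_side, hu_min = 1, hu_max = 250,
                        patient_id = "subject") {
  stopifnot(inherits(cta, "volume3d"), inherits(atlas, "aspects_atlas"))
  occlusion_side <- match.arg(occlusion_side, c("left", "right"))
  rows <- lapply(ASPECTS_REGIONS, function(r) {
    ik <- region_key(r, occlusion_side)
    ck <- contralateral(ik)
    ipsi <- region_mean_hu(cta, atlas$masks[[ik]], hu_min, hu_max, region = ik)
    contra <- region_mean_hu(cta, atlas$masks[[ck]], hu_min, hu_max, region = ck)
    data.frame(patient_id = patient_id, region = r,
               hemisphere_occluded = occlusion_side,
               rhu = ipsi$mean / contra$mean,
               ipsi_mean_hu = ipsi$mean, contra_mean_hu = contra$mean,
               n_voxels_ipsi = ipsi$n, n_voxels_contra = contra$n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
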