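#' The ten ASPECTS regions
#'
#' Region identifiers for the Alberta Stroke Program Early CT Score: three
#' subcortical regions (caudate, internal capsule, lentiform nucleus) and
#' seven cortical regions (insular cortex, M1-M6), each present in both
#' hemispheres.
#'
#' @format Character vector of length 10.
#' @export
ASPECTS_REGIONS <- c("Caudate", "InternalCapsule", "LentiformNucleus",
                     "InsularCortex", "M1", "M2", "M3", "M4", "M5", "M6")

#' Enumerate all 20 region/hemisphere identifiers
#'
#' @return Data frame with columns \code{region}, \code{hemisphere} and
#'   \code{key} (the \code{"<region>_<hemisphere>"} string used to index
#'   atlas masks), 20 rows.
#' @export
aspects_region_table <- function() {
  g <- expand.grid(hemisphere = c("left", "right"), region = ASPECTS_REGIONS,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g <- g[, c("region", "hemisphere")]
  g$key <- paste(g$region, g$hemisphere, sep = "_")
  g
}

#' Build a region key
#' @param region One of \code{ASPECTS_REGIONS}.
#' @param hemisphere \code{"left"} or \code{"right"}.
#' @return Character key \code{"<region>_<hemisphere>"}.
#' @export
region_key <- function(region, hemisphere) {
  region <- match.arg(region, ASPECTS_REGIONS, several.ok = TRUE)
  hemisphere <- match.arg(hemisphere, c("left", "right"), several.ok = TRUE)
  paste(region, hemisphere, sep = "_")
}

#' Mirror a region identifier across hemispheres
#'
#' Returns the same anatomical region in the opposite hemisphere: the region
#' whose mean attenuation provides the denominator of the rHU ratio for an
#' occlusion-side region. An involution: applying it twice is the identity.
#'
#' @param key Region key (\code{"<region>_<left|right>"}), vectorised.
#' @return The contralateral key(s).
#' @export
contralateral <- function(key) {
  parts <- parse_region_key(key)
  other <- ifelse(parts$hemisphere == "left", "right", "left")
  paste(parts$region, other, sep = "_")
}

parse_region_key <- function(key) {
  m <- regmatches(key, regexec("^(.*)_(left|right)$", key))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad))
    stop("invalid region key: ", paste(key[bad], collapse = ", "), call. = FALSE)
  region <- vapply(m, `[`, "", 2L)
  unknown <- !region %in% ASPECTS_REGIONS
  if (any(unknown))
    stop("unknown ASPECTS region: ", paste(region[unknown], collapse = ", "),
         call. = FALSE)
  list(region = region, hemisphere = vapply(m, `[`, "", 3L))
}

#' Construct an ASPECTS atlas from 20 binary masks
#'
#' @param masks Named list of 20 binary \code{\link{volume3d}} masks, names
#'   being the region keys from \code{\link{aspects_region_table}}.
#' @param template_name Label for the template space the masks live in.
#' @param validate Run \code{\link{validate_atlas}} (default \code{TRUE}).
#' @return An object of class \code{aspects_atlas}.
#' @export
aspects_atlas <- function(masks, template_name = "MNI152", validate = TRUE) {
  atlas <- structure(list(masks = masks, template_name = template_name),
                     class = "aspects_atlas")
  if (validate) validate_atlas(atlas)
  atlas
}

#' @export
print.aspects_atlas <- function(x, ...) {
  d <- dim(x$masks[[1]]$data)
  cat("<aspects_atlas> ", length(x$masks), " region masks on a ",
      paste(d, collapse = " x "), " ", x$template_name, " grid\n", sep = "")
  invisible(x)
}

#' Validate an ASPECTS atlas
#'
#' Checks that all 20 region/hemisphere masks are present, binary and
#' non-empty, share one grid and affine, are pairwise disjoint (both within
#' and across hemispheres -- masks crossing the midline would corrupt the
#' rHU ratio), and that each region's left and right masks lie on opposite
#' sides of the template midsagittal plane.
#'
#' @param atlas An \code{aspects_atlas}.
#' @return \code{TRUE} invisibly; stops with a message naming every
#'   offending region otherwise.
#' @export
validate_atlas <- function(atlas) {
  stopifnot(inherits(atlas, "aspects_atlas"))
  keys <- aspects_region_table()$key
  missing <- setdiff(keys, names(atlas$masks))
  if (length(missing))
    stop("atlas is missing region(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  masks <- atlas$masks[keys]
  ref <- masks[[1]]
  problems <- character()
  for (k in keys) {
    m <- masks[[k]]
    if (!identical(dim(m$data), dim(ref$data)) ||
        max(abs(m$affine - ref$affine)) > 1e-4)
      problems <- c(problems, paste0(k, ": not on the shared template grid"))
    if (!is_binary_volume(m))
      problems <- c(problems, paste0(k, ": not binary"))
    else if (sum(m$data) == 0)
      problems <- c(problems, paste0(k, ": empty mask"))
  }
  if (!length(problems)) {
    lab <- Reduce(`+`, lapply(masks, `[[`, "data"))
    if (any(lab > 1)) {
      for (i in seq_along(keys)[-length(keys)])
        for (j in seq.int(i + 1L, length(keys)))
          if (any(masks[[i]]$data + masks[[j]]$data > 1))
            problems <- c(problems,
                          paste0("overlap between ", keys[i], " and ", keys[j]))
    }
    # midsagittal check: world-x centroids of the two hemispheres of each
    # region must straddle the grid's world-x midplane
    d <- dim(ref$data)
    corners <- as.matrix(expand.grid(c(0, d[1] - 1), c(0, d[2] - 1),
                                     c(0, d[3] - 1)))
    wx <- (cbind(corners, 1) %*% t(ref$affine))[, 1]
    xmid <- mean(range(wx))
    for (r in ASPECTS_REGIONS) {
      cl <- mask_centroid_x(masks[[paste0(r, "_left")]])
      cr <- mask_centroid_x(masks[[paste0(r, "_right")]])
      if (is.finite(cl) && is.finite(cr) && (cl - xmid) * (cr - xmid) >= 0)
        problems <- c(problems,
                      paste0(r, ": left/right masks on the same side of the midsagittal plane"))
    }
  }
  if (length(problems))
    stop("invalid atlas:\n  ", paste(problems, collapse = "\n  "), call. = FALSE)
  invisible(TRUE)
}

mask_centroid_x <- function(m) {
  idx <- which(m$data == 1)
  if (!length(idx)) return(NA_real_)
  d <- dim(m$data)
  i0 <- (idx - 1) %% d[1]
  j0 <- ((idx - 1) %/% d[1]) %% d[2]
  k0 <- (idx - 1) %/% (d[1] * d[2])
  mean((cbind(i0, j0, k0, 1) %*% t(m$affine))[, 1])
}

#' Load an ASPECTS atlas from disk
#'
#' Two layouts are supported: a directory of 20 binary NIfTI masks named
#' \code{<region>_<hemisphere>.nii[.gz]} (e.g. \code{Caudate_left.nii.gz}),
#' or a single integer-label NIfTI volume accompanied by a JSON sidecar
#' mapping label integers to region keys
#' (\code{\{"1": "Caudate_left", ...\}}).
#'
#' @param path Directory of masks, or a label-volume NIfTI file.
#' @param labels For the label-volume layout: path to the JSON label map.
#'   Defaults to the volume path with its NIfTI extension replaced by
#'   \code{.json}.
#' @param template_name Template-space label stored on the atlas.
#' @return A validated \code{aspects_atlas}.
#' @export
load_atlas <- function(path, labels = NULL, template_name = "MNI152") {
  if (dir.exists(path)) {
    keys <- aspects_region_table()$key
    masks <- lapply(keys, function(k) {
      f <- file.path(path, paste0(k, ".nii.gz"))
      if (!file.exists(f)) f <- file.path(path, paste0(k, ".nii"))
      if (!file.exists(f))
        stop("atlas is missing region(s): ", k, " (no ", k, ".nii[.gz] in ",
             path, ")", call. = FALSE)
      read_volume(f)
    })
    names(masks) <- keys
    return(aspects_atlas(masks, template_name))
  }
  if (!file.exists(path)) stop("atlas path not found: ", path, call. = FALSE)
  if (is.null(labels))
    labels <- sub("\\.nii(\\.gz)?$", ".json", path)
  if (!file.exists(labels))
    stop("label map not found: ", labels, call. = FALSE)
  lab <- read_volume(path)
  map <- jsonlite::read_json(labels, simplifyVector = TRUE)
  masks <- lapply(names(map), function(lv) {
    volume3d(array(as.numeric(lab$data == as.numeric(lv)), dim(lab$data)),
             lab$affine, lab$voxel_dims)
  })
  names(masks) <- unlist(map)
  aspects_atlas(masks, template_name)
}

#' Write an atlas to disk
#'
#' @param atlas An \code{aspects_atlas}.
#' @param path Output directory (created if needed).
#' @param format \code{"masks"} writes 20 \code{<key>.nii.gz} files;
#'   \code{"labels"} writes one integer-label volume \code{atlas.nii.gz}
#'   plus \code{atlas.json}.
#' @return \code{path}, invisibly.
#' @export
write_atlas <- function(atlas, path, format = c("masks", "labels")) {
  format <- match.arg(format)
  stopifnot(inherits(atlas, "aspects_atlas"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  keys <- aspects_region_table()$key
  if (format == "masks") {
    for (k in keys)
      write_volume(atlas$masks[[k]], file.path(path, paste0(k, ".nii.gz")))
  } else {
    ref <- atlas$masks[[1]]
    lab <- array(0, dim(ref$data))
    for (i in seq_along(keys))
      lab[atlas$masks[[keys[i]]]$data == 1] <- i
    write_volume(volume3d(lab, ref$affine, ref$voxel_dims),
                 file.path(path, "atlas.nii.gz"))
    map <- as.list(keys)
    names(map) <- as.character(seq_along(keys))
    jsonlite::write_json(map, file.path(path, "atlas.json"), auto_unbox = TRUE)
  }
  invisible(path)
}

#' Resample every atlas mask onto a subject grid
#'
#' Applies \code{\link{resample_mask}} to all 20 masks, carrying them from
#' template space into a subject's native CTA or DWI grid.
#'
#' @param atlas An \code{aspects_atlas} in template space.
#' @param reference Subject \code{volume3d} defining the output grid.
#' @param transform \code{affine_transform} mapping template-world to
#'   subject-world mm (the inverse of the subject-to-template registration).
#' @return An \code{aspects_atlas} on the subject grid (not re-validated:
#'   resampling can legitimately clip regions at the field-of-view edge).
#' @export
resample_atlas <- function(atlas, reference, transform = affine_transform(diag(4))) {
  stopifnot(inherits(atlas, "aspects_atlas"))
  masks <- lapply(atlas$masks, resample_mask, reference = reference,
                  transform = transform)
  structure(list(masks = masks, template_name = atlas$template_name),
            class = "aspects_atlas")
}
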