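#' 3-D volume with voxel-to-world geometry
#'
#' Container for a 3-D scalar grid (Hounsfield units for CTA, \{0,1\} for
#' masks) together with its 4x4 voxel-index-to-world affine (0-based voxel
#' indices, world coordinates in mm) and voxel dimensions.
#'
#' @param data 3-D numeric array.
#' @param affine 4x4 matrix mapping homogeneous 0-based voxel indices to
#'   world mm coordinates. Must be invertible with last row (0,0,0,1).
#' @param voxel_dims length-3 positive numeric, mm per axis. Defaults to the
#'   column norms of the affine's rotational part.
#' @return An object of class \code{volume3d}: a list with elements
#'   \code{data}, \code{affine}, \code{voxel_dims}.
#' @export
volume3d <- function(data, affine = diag(4), voxel_dims = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("expected 3-D volume", call. = FALSE)
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)))
    stop("affine must be a 4x4 matrix", call. = FALSE)
  if (max(abs(affine[4L, ] - c(0, 0, 0, 1))) > 1e-6)
    stop("affine last row must be (0, 0, 0, 1)", call. = FALSE)
  if (abs(det(affine)) < 1e-12)
    stop("singular affine", call. = FALSE)
  if (is.null(voxel_dims))
    voxel_dims <- sqrt(colSums(affine[1:3, 1:3]^2))
  voxel_dims <- as.numeric(voxel_dims)
  if (length(voxel_dims) != 3L || any(!is.finite(voxel_dims)) || any(voxel_dims <= 0))
    stop("voxel_dims must be 3 positive reals", call. = FALSE)
  structure(list(data = data, affine = unname(affine), voxel_dims = voxel_dims),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  cat("<volume3d> ", paste(dim(x$data), collapse = " x "),
      " voxels, ", paste(signif(x$voxel_dims, 4), collapse = " x "),
      " mm", if (is_binary_volume(x)) " (binary)", "\n", sep = "")
  invisible(x)
}

#' @export
dim.volume3d <- function(x) dim(x$data)

#' Test whether a volume contains only 0/1 values
#' @param vol A \code{volume3d}.
#' @return Logical scalar.
#' @export
is_binary_volume <- function(vol) {
  all(vol$data %in% c(0, 1))
}

#' Read a 3-D NIfTI volume
#'
#' Reads a NIfTI-1 file into a \code{\link{volume3d}}. Intensities are taken
#' as stored, with only the format's own \code{scl_slope}/\code{scl_inter}
#' scaling applied by the reader; no other rescaling is performed.
#'
#' @param path Path to a \code{.nii} or \code{.nii.gz} file.
#' @return A \code{volume3d}.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected 3-D volume, got ", length(d), "-D: ", path, call. = FALSE)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = dim(aff))
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  storage.mode(arr) <- "double"
  volume3d(arr, aff, abs(RNifti::pixdim(img)[1:3]))
}

#' Write a volume as NIfTI-1
#'
#' @param vol A \code{volume3d}.
#' @param path Output path (\code{.nii} or \code{.nii.gz}).
#' @return \code{path}, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume3d"))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$voxel_dims
  img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
  img <- RNifti::`qform<-`(img, structure(vol$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 4x4 world-to-world affine transform from a text file
#'
#' The file dialect is a plain whitespace-delimited 4x4 matrix in world mm
#' coordinates (one row per line). FSL FLIRT's native \code{.mat} convention
#' (scaled-voxel coordinates) is deliberately not parsed: it depends on the
#' image headers and qform flips, so such matrices must be converted to
#' world-mm form upstream.
#'
#' @param path Path to the text file.
#' @return An \code{affine_transform}: a 4x4 matrix whose last row is
#'   (0,0,0,1).
#' @export
read_affine <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ln <- readLines(path, warn = FALSE)
  ln <- ln[nzchar(trimws(ln))]
  if (length(ln) != 4L)
    stop("malformed affine file (expected 4 rows): ", path, call. = FALSE)
  rows <- suppressWarnings(lapply(strsplit(trimws(ln), "\\s+"), as.numeric))
  if (any(vapply(rows, length, 1L) != 4L) || anyNA(unlist(rows)))
    stop("malformed affine file (expected 4 numbers per row): ", path,
         call. = FALSE)
  affine_transform(do.call(rbind, rows))
}

#' Construct and validate an affine transform
#' @param matrix 4x4 numeric matrix, last row (0,0,0,1), invertible.
#' @return The matrix with class \code{affine_transform}.
#' @export
affine_transform <- function(matrix) {
  m <- unname(unclass(as.matrix(matrix)))
  if (!all(dim(m) == c(4L, 4L)))
    stop("affine transform must be 4x4", call. = FALSE)
  if (max(abs(m[4L, ] - c(0, 0, 0, 1))) > 1e-6)
    stop("affine transform last row must be (0, 0, 0, 1)", call. = FALSE)
  if (abs(det(m)) < 1e-12)
    stop("non-invertible affine transform", call. = FALSE)
  structure(m, class = "affine_transform")
}

#' Write an affine transform to a text file
#' @param transform An \code{affine_transform} or plain 4x4 matrix.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_affine <- function(transform, path) {
  m <- unclass(affine_transform(transform))
  writeLines(apply(m, 1L, function(r) paste(format(r, digits = 17), collapse = " ")),
             path)
  invisible(path)
}

#' Resample a binary mask onto a reference grid
#'
#' Nearest-neighbour resampling of a binary mask onto the voxel grid of a
#' reference volume, through the chain reference voxel index -> reference
#' affine -> world -> inverse of \code{transform} -> mask world -> inverse of
#' the mask affine -> mask voxel index. Nearest-neighbour (no partial-volume
#' weighting) keeps the output binary, which the voxel-count overlap rule
#' requires. Samples falling outside the mask grid are background (0).
#'
#' @param mask Binary \code{volume3d} to resample.
#' @param reference \code{volume3d} defining the output grid.
#' @param transform \code{affine_transform} mapping mask-world to
#'   reference-world mm coordinates (identity by default).
#' @return Binary \code{volume3d} on the reference grid. Warns when a
#'   non-empty mask lands entirely outside the reference field of view.
#' @export
resample_mask <- function(mask, reference, transform = affine_transform(diag(4))) {
  stopifnot(inherits(mask, "volume3d"), inherits(reference, "volume3d"))
  if (!is_binary_volume(mask))
    stop("mask must be binary", call. = FALSE)
  transform <- affine_transform(transform)
  # composite: reference voxel index -> mask voxel index (both 0-based)
  M <- solve(mask$affine) %*% solve(unclass(transform)) %*% reference$affine
  rd <- dim(reference$data)
  ijk <- as.matrix(expand.grid(i = 0:(rd[1] - 1L), j = 0:(rd[2] - 1L),
                               k = 0:(rd[3] - 1L), KEEP.OUT.ATTRS = FALSE))
  src <- cbind(ijk, 1) %*% t(M)
  src <- round(src[, 1:3, drop = FALSE])
  md <- dim(mask$data)
  inb <- src[, 1] >= 0 & src[, 1] < md[1] &
         src[, 2] >= 0 & src[, 2] < md[2] &
         src[, 3] >= 0 & src[, 3] < md[3]
  out <- numeric(nrow(src))
  if (any(inb)) {
    lin <- src[inb, 1] + md[1] * (src[inb, 2] + md[2] * src[inb, 3]) + 1
    out[inb] <- mask$data[lin]
  }
  if (sum(mask$data) > 0 && sum(out) == 0)
    warning("mask falls entirely outside the reference field of view",
            call. = FALSE)
  volume3d(array(out, rd), reference$affine, reference$voxel_dims)
}
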