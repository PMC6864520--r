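# NIfTI volume and landmark/report I/O. Conventions: voxel coordinates are
# 1-based in the R API and 0-based in files (landmark CSV); displacement
# components are stored as the 4th dimension of a 4D NIfTI in x, y, z order.

#' Read a NIfTI volume
#'
#' Accepts plain and gzipped NIfTI-1 (\code{.nii}, \code{.nii.gz}); 3D
#' scalar volumes and 4D arrays (descriptor fields, deformation fields).
#'
#' @param path file path.
#' @return a [VolumeRecord-class].
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  data <- array(as.numeric(img), dim(img))
  nd <- length(dim(data))
  if (nd < 3L || nd > 4L)
    stop("expected a 3D or 4D volume, got ", nd, " dimensions")
  spc <- RNifti::pixdim(img)[seq_len(min(3L, nd))]
  new("VolumeRecord", data = data, spacing = as.numeric(spc),
      source = normalizePath(path))
}

#' Write a volume to NIfTI
#'
#' Writes with double-precision payload so that read-back reproduces the
#' array bit-exactly.
#'
#' @param x a [VolumeRecord-class] or a plain numeric array.
#' @param path output path (\code{.nii} or \code{.nii.gz}).
#' @param spacing voxel size in mm per axis (used when \code{x} is a plain
#'   array).
#' @return invisibly, the path.
#' @export
writeVolume <- function(x, path, spacing = c(1, 1, 1)) {
  if (is(x, "VolumeRecord")) {
    data <- x@data
    spacing <- x@spacing
  } else if (is.array(x)) {
    data <- x
  } else stop("x must be a VolumeRecord or an array")
  img <- RNifti::asNifti(data)
  pd <- RNifti::pixdim(img)
  pd[seq_along(spacing)] <- spacing
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Write a deformation field as 4D NIfTI
#'
#' @param field a [DeformationField-class].
#' @param path output path.
#' @param spacing voxel size in mm.
#' @return invisibly, the path.
#' @export
writeDeformationField <- function(field, path, spacing = c(1, 1, 1)) {
  writeVolume(field@displacements, path, spacing)
}

#' Read a deformation field from 4D NIfTI
#'
#' @param path input path (4D, three components as the 4th dimension).
#' @return a [DeformationField-class].
#' @export
readDeformationField <- function(path) {
  rec <- readVolume(path)
  d <- dim(rec@data)
  if (length(d) != 4L || d[4L] != 3L)
    stop("deformation field file must be 4D with 3 components")
  new("DeformationField", displacements = rec@data)
}

#' Read landmarks from CSV
#'
#' The file must have a header \code{x,y,z} and one 0-based voxel
#' coordinate triple per row; coordinates are converted to the package's
#' 1-based convention on read.
#'
#' @param path CSV path.
#' @return a [LandmarkSet-class].
#' @export
readLandmarks <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) stop("landmark file is empty: ", path)
  df <- tryCatch(utils::read.csv(path, colClasses = "numeric"),
                 error = function(e)
                   stop("malformed landmark file: ", conditionMessage(e)))
  if (!all(c("x", "y", "z") %in% names(df)))
    stop("landmark CSV must have header columns x,y,z")
  if (nrow(df) == 0L) stop("landmark file has no rows")
  bad <- which(!stats::complete.cases(df[, c("x", "y", "z")]))
  if (length(bad))
    stop("malformed landmark row(s) at line(s): ",
         paste(bad + 1L, collapse = ", "))
  new("LandmarkSet",
      points = unname(as.matrix(df[, c("x", "y", "z")])) + 1)
}

#' Write landmarks to CSV
#'
#' Writes 0-based \code{x,y,z} voxel coordinates (the package API is
#' 1-based; conversion happens here).
#'
#' @param landmarks a [LandmarkSet-class].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeLandmarks <- function(landmarks, path) {
  df <- as.data.frame(landmarks@points - 1)
  names(df) <- c("x", "y", "z")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a registration report as JSON
#'
#' @param report a report list (from [registerFMIND()]), possibly extended
#'   with TRE results.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeReport <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

#' Dump a foveation operator's kernels as JSON
#'
#' Plain-text kernel table for inspection: per patch offset, the kernel
#' radius and row-major weights.
#'
#' @param operator a [FoveationOperator-class].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeOperator <- function(operator, path) {
  entries <- lapply(seq_len(nrow(operator@offsets)), function(i) {
    k <- operator@kernels[[i]]
    list(u = as.integer(operator@offsets[i, ]),
         radius = attr(k, "radius"),
         weights = as.vector(k))
  })
  obj <- list(patchShape = operator@patchShape, rho = operator@rho,
              theta = operator@theta, sigma0 = operator@sigma0,
              kernels = entries)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export a descriptor field as 4D NIfTI
#'
#' Channels become the 4th dimension, in search-offset order.
#'
#' @param desc a [DescriptorField-class].
#' @param path output path.
#' @param spacing voxel size in mm.
#' @return invisibly, the path.
#' @export
writeDescriptorField <- function(desc, path, spacing = c(1, 1, 1)) {
  writeVolume(desc@values, path, spacing)
}
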