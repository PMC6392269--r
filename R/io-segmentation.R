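#' Segmentation volume container
#'
#' Holds the segmented spinal canal as two logical masks (spinal cord;
#' dura-enclosed region including the cord) on a common voxel grid.  The
#' axial axis runs caudally: slice `fm_index` is the foramen magnum (z = 0)
#' and z increases toward the sacrum as
#' `z = (slice - fm_index) * spacing[axial_axis]`.
#'
#' @param cord logical array, spinal-cord mask.
#' @param dura logical array (same dim), dura-enclosed mask; must be a
#'   superset of `cord`.
#' @param spacing numeric voxel spacing in mm, one value per array axis.
#' @param axial_axis which array axis is axial (default 3).
#' @param fm_index 1-based slice index of the foramen magnum plane.
#' @return An object of class `segmentation_volume`.
#' @seealso [read_segmentation()], [slice_profiles()]
#' @export
segmentation_volume <- function(cord, dura, spacing, axial_axis = 3L,
                                fm_index = 1L) {
  if (!identical(dim(cord), dim(dura)))
    stop_validation("cord and dura masks must share dimensions")
  if (any(spacing <= 0)) stop_validation("voxel spacing must be positive")
  if (length(spacing) != length(dim(cord)))
    stop_validation("spacing must have one value per array axis")
  if (fm_index < 1L || fm_index > dim(cord)[axial_axis])
    stop_validation("fm_index outside volume")
  if (!any(dura)) stop_validation("dura-enclosed mask is empty")
  stray <- cord & !dura
  if (any(stray)) {
    csf_log(sum(stray), " cord voxel(s) outside the dura-enclosed region; ",
            "added to dura (label harmonisation)", level = "WARN")
    warning("cord voxels outside dura-enclosed region were added to dura",
            call. = FALSE)
    dura <- dura | cord
  }
  structure(list(cord = cord, dura = dura, spacing = as.numeric(spacing),
                 axial_axis = as.integer(axial_axis),
                 fm_index = as.integer(fm_index)),
            class = "segmentation_volume")
}

#' @export
print.segmentation_volume <- function(x, ...) {
  cat("<segmentation_volume> ", paste(dim(x$cord), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm, FM slice ", x$fm_index, "\n", sep = "")
  invisible(x)
}

#' Read a segmented spinal canal label volume (NIfTI)
#'
#' Reads a NIfTI integer label image and builds the cord / dura-enclosed
#' masks.  `label_map` assigns file labels to roles; by default label 1 is
#' the spinal cord and the dura-enclosed region is the union of labels 1 and
#' 2 (i.e. the file stores the most specific label per voxel, with label 2
#' the CSF-filled subarachnoid space).  Cord voxels falling outside the
#' dura-enclosed set are added to it with a warning, so that cord is always
#' a subset of dura.
#'
#' @param path path to a `.nii` / `.nii.gz` label volume.
#' @param label_map named list with elements `cord` and `dura`, each a
#'   vector of integer labels for that role.
#' @param axial_axis,fm_index see [segmentation_volume()].
#' @return A [segmentation_volume()].
#' @export
read_segmentation <- function(path, label_map = list(cord = 1L, dura = c(1L, 2L)),
                              axial_axis = 3L, fm_index = 1L) {
  if (!file.exists(path)) stop_format("cannot read segmentation: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop_format("not a readable NIfTI: ",
                                                  path, " (", conditionMessage(e), ")"))
  arr <- as.array(img)
  if (is.null(label_map$cord) || is.null(label_map$dura))
    stop_validation("label_map must assign both 'cord' and 'dura' roles")
  spacing <- RNifti::pixdim(img)
  if (length(spacing) < length(dim(arr)))
    spacing <- c(spacing, rep(1, length(dim(arr)) - length(spacing)))
  spacing <- spacing[seq_along(dim(arr))]
  cord <- array(arr %in% label_map$cord, dim = dim(arr))
  dura <- array(arr %in% label_map$dura, dim = dim(arr))
  if (!any(cord)) stop_validation("no voxels carry the 'cord' label(s): ",
                                  paste(label_map$cord, collapse = ","))
  if (!any(dura)) stop_validation("no voxels carry the 'dura' label(s): ",
                                  paste(label_map$dura, collapse = ","))
  segmentation_volume(cord, dura, spacing, axial_axis = axial_axis,
                      fm_index = fm_index)
}

#' Write a segmentation volume as a NIfTI label image
#'
#' Encodes the most specific label per voxel: 1 = spinal cord, 2 =
#' dura-enclosed region outside the cord (CSF), 0 = background.
#'
#' @param seg a [segmentation_volume()].
#' @param path output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_segmentation <- function(seg, path) {
  stopifnot(inherits(seg, "segmentation_volume"))
  lab <- array(0L, dim = dim(seg$cord))
  lab[seg$dura] <- 2L
  lab[seg$cord] <- 1L
  img <- RNifti::asNifti(lab, reference = NULL)
  RNifti::pixdim(img) <- seg$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}
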