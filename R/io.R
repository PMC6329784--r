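#' Write a 3-D map or 4-D series as NIfTI-1
#'
#' @param x 3-D array (map) or scans x voxels matrix plus mask (series).
#' @param path Output path (\code{.nii} or \code{.nii.gz}).
#' @param voxel_size Voxel edge length in mm (default 3).
#' @param tr Repetition time recorded in the header for 4-D images.
#' @return \code{path}, invisibly.
#' @export
write_map_nifti <- function(x, path, voxel_size = 3, tr = NULL) {
  img <- RNifti::asNifti(x)
  pd <- c(rep(voxel_size, 3), if (!is.null(tr)) tr)
  RNifti::pixdim(img) <- c(pd, rep(1, length(dim(x)) - length(pd)))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_map_nifti
#' @param vol A \code{"volume_series"}; volumes are unpacked into the mask.
#' @export
write_volume_nifti <- function(vol, path, voxel_size = 3) {
  dims <- dim(vol$mask)
  arr <- array(0, c(dims, nrow(vol$data)))
  idx <- which(vol$mask)
  for (s in seq_len(nrow(vol$data))) {
    sl <- array(0, dims)
    sl[idx] <- vol$data[s, ]
    arr[, , , s] <- sl
  }
  write_map_nifti(arr, path, voxel_size, tr = vol$tr)
}

#' Read a NIfTI file as a plain array
#'
#' @param path NIfTI path.
#' @return Numeric array.
#' @export
read_nifti_array <- function(path) {
  as.array(RNifti::readNifti(path))
}

#' Write a labelled square matrix as CSV
#'
#' @param m Matrix (e.g. a [square_matrix5()]).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_matrix_csv <- function(m, path) {
  df <- as.data.frame(as.matrix(m))
  utils::write.csv(cbind(label = rownames(df) %||% seq_len(nrow(df)), df),
                   path, row.names = FALSE)
  invisible(path)
}
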