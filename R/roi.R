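#' Extract sphere-averaged node time series from a 4D NIfTI image
#'
#' For each node centroid (world/MNI mm coordinates), averages the signal
#' over all voxels whose centers lie within `radius_mm` (Euclidean distance
#' in world coordinates, computed through the image affine -- no axis
#' orientation is assumed beyond the affine itself). Spheres that extend
#' beyond the field of view are averaged over their in-image voxels with a
#' warning; a sphere containing no voxel is an error.
#'
#' @param nifti_path Path to a 4D NIfTI-1 image.
#' @param centroids Data frame with columns `label`, `x`, `y`, `z` (mm).
#' @param radius_mm Sphere radius in mm (default 5).
#' @param schedule Optional `design_schedule` attached to the result.
#' @param subject Optional `subject_record`.
#' @return A `node_timeseries` with one column per centroid row.
#' @export
extract_roi_timeseries <- function(nifti_path, centroids, radius_mm = 5,
                                   schedule = NULL, subject = NULL) {
  if (!file.exists(nifti_path)) {
    stop("image not found: ", nifti_path, call. = FALSE)
  }
  need <- c("label", "x", "y", "z")
  if (!is.data.frame(centroids) || !all(need %in% names(centroids))) {
    stop("centroid table must have columns label, x, y, z", call. = FALSE)
  }
  if (radius_mm <= 0) stop("radius_mm must be > 0", call. = FALSE)

  img <- RNifti::readNifti(nifti_path)
  dm <- dim(img)
  if (length(dm) != 4L) stop("expected a 4D image, got ", length(dm), "D",
                             call. = FALSE)
  n_vol <- dm[4]

  # world coordinates of all voxel centers (1-based indices per RNifti)
  grid <- as.matrix(expand.grid(i = seq_len(dm[1]), j = seq_len(dm[2]),
                                k = seq_len(dm[3])))
  world <- RNifti::voxelToWorld(grid, img)

  n_nodes <- nrow(centroids)
  out <- matrix(NA_real_, n_vol, n_nodes,
                dimnames = list(NULL, centroids$label))
  n_voxels <- setNames(integer(n_nodes), centroids$label)
  vox <- matrix(img, prod(dm[1:3]), n_vol)  # voxel x volume
  for (nd in seq_len(n_nodes)) {
    ctr <- as.numeric(centroids[nd, c("x", "y", "z")])
    d2 <- (world[, 1] - ctr[1])^2 + (world[, 2] - ctr[2])^2 +
          (world[, 3] - ctr[3])^2
    inside <- d2 <= radius_mm^2
    if (!any(inside)) {
      stop("node '", centroids$label[nd],
           "': no voxel center within the sphere", call. = FALSE)
    }
    # clipped sphere: the full sphere's bounding box exceeds the image FOV
    lo <- apply(world, 2, min); hi <- apply(world, 2, max)
    if (any(ctr - radius_mm < lo) || any(ctr + radius_mm > hi)) {
      warning("node '", centroids$label[nd],
              "': sphere extends beyond the field of view; averaging ",
              sum(inside), " in-image voxel(s)", call. = FALSE)
    }
    out[, nd] <- colMeans(vox[inside, , drop = FALSE])
    n_voxels[nd] <- sum(inside)
  }
  attr(out, "n_voxels") <- n_voxels
  structure(list(subject = subject, schedule = schedule, data = out),
            class = "node_timeseries")
}

#' Write a small synthetic 4D NIfTI fixture
#'
#' Test utility: creates a synthetic 4D image with a given isotropic voxel
#' size and world-coordinate origin, filled with `background`, and sets all
#' voxels whose centers fall within spheres around the given centroids to
#' per-node values. Purely for exercising [extract_roi_timeseries()]; this
#' is not an emulation of real BOLD data.
#'
#' @param path Output .nii or .nii.gz path.
#' @param dim Spatial x temporal dimensions, length 4.
#' @param voxel_mm Isotropic voxel size (mm).
#' @param origin_mm World coordinate of the first voxel's center, length 3.
#' @param centroids Data frame `label`, `x`, `y`, `z`, `value`; may be NULL.
#' @param radius_mm Sphere radius for the painted values.
#' @param background Background intensity.
#' @return The path, invisibly.
#' @export
write_synthetic_nifti <- function(path, dim = c(12, 12, 12, 5),
                                  voxel_mm = 2, origin_mm = c(0, 0, 0),
                                  centroids = NULL, radius_mm = 5,
                                  background = 0) {
  arr <- array(background, dim)
  coords <- list(origin_mm[1] + (seq_len(dim[1]) - 1) * voxel_mm,
                 origin_mm[2] + (seq_len(dim[2]) - 1) * voxel_mm,
                 origin_mm[3] + (seq_len(dim[3]) - 1) * voxel_mm)
  if (!is.null(centroids)) {
    for (nd in seq_len(nrow(centroids))) {
      ctr <- as.numeric(centroids[nd, c("x", "y", "z")])
      for (i in seq_len(dim[1])) for (j in seq_len(dim[2]))
        for (k in seq_len(dim[3])) {
          d2 <- (coords[[1]][i] - ctr[1])^2 + (coords[[2]][j] - ctr[2])^2 +
                (coords[[3]][k] - ctr[3])^2
          if (d2 <= radius_mm^2) arr[i, j, k, ] <- centroids$value[nd]
        }
    }
  }
  img <- RNifti::asNifti(arr)
  # affine: voxel-size scaling; translation column = world coordinate of the
  # first voxel center. pixdim must be set before the xforms, otherwise the
  # scaling is lost when the header is serialized.
  RNifti::pixdim(img) <- c(voxel_mm, voxel_mm, voxel_mm, 1)
  aff <- diag(c(voxel_mm, voxel_mm, voxel_mm, 1))
  aff[1:3, 4] <- origin_mm
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}
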