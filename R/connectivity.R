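#' The packaged 20-node DMN parcellation
#'
#' Twenty regions of interest covering the default mode network
#' (posterior cingulate, medial prefrontal, temporo-parietal,
#' retrosplenial, parahippocampal and hippocampal nodes), with MNI
#' millimetre coordinates and Brodmann areas. Left/right homologues
#' differ only in the sign of x; midline nodes (dMPFC, vMPFC) sit at
#' x = 0. Seed extraction uses 6-mm spheres around these coordinates.
#'
#' @return Data frame with columns `name`, `region`, `brodmann`, `x`,
#'   `y`, `z`, `module` (20 rows).
#' @export
dmn_rois <- function() {
  path <- system.file("extdata", "dmn_rois.csv", package = "dmnet")
  if (path == "") stop("packaged ROI table not found")
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(tab) != 20 || !all(c("name", "x", "y", "z") %in% names(tab)))
    stop("packaged ROI table is corrupt")
  tab
}

#' Mean time series within a spherical seed
#'
#' Averages, per volume, all voxels whose center lies within
#' `radius_mm` (Euclidean distance in world/mm space, boundary
#' inclusive) of `center_mm`. World coordinates of voxel centers come
#' from the supplied affine; no resampling is performed.
#'
#' @param image4d 4-D array (x, y, z, t).
#' @param affine 4 x 4 voxel-to-world affine (0-based voxel indices).
#' @param center_mm length-3 world coordinate of the sphere center.
#' @param radius_mm sphere radius in mm.
#' @param label optional ROI name used in error messages.
#' @return Numeric vector of length T.
#' @export
extract_sphere_timeseries <- function(image4d, affine, center_mm,
                                      radius_mm = 6, label = NULL) {
  stopifnot(length(dim(image4d)) == 4, all(dim(affine) == c(4, 4)))
  if (abs(det(affine)) < .Machine$double.eps) stop("affine is singular")
  dims <- dim(image4d)[1:3]
  grid <- as.matrix(expand.grid(i = seq_len(dims[1]) - 1,
                                j = seq_len(dims[2]) - 1,
                                k = seq_len(dims[3]) - 1))
  world <- grid %*% t(affine[1:3, 1:3]) +
    matrix(affine[1:3, 4], nrow(grid), 3, byrow = TRUE)
  d2 <- rowSums(sweep(world, 2, center_mm)^2)
  inside <- d2 <= radius_mm^2
  if (!any(inside))
    stop("spherical seed", if (!is.null(label)) paste0(" '", label, "'"),
         " contains no voxels")
  flat <- matrix(image4d, prod(dims), dim(image4d)[4])
  colMeans(flat[inside, , drop = FALSE])
}

#' Seed-based ROI time series from a volumetric image
#'
#' Extracts the mean 6-mm-sphere signal for every ROI in the table.
#' `image` may be a 4-D array (with `affine` supplied) or a path to a
#' NIfTI file (read with the RNifti package, affine taken from the
#' header).
#'
#' @param image 4-D array or NIfTI file path.
#' @param affine 4 x 4 voxel-to-world affine; ignored for file input.
#' @param rois ROI table as from [dmn_rois()].
#' @param radius_mm sphere radius.
#' @return T x N matrix with ROI names as columns.
#' @export
roi_timeseries_from_image <- function(image, affine = NULL, rois = dmn_rois(),
                                      radius_mm = 6) {
  if (is.character(image)) {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop("reading NIfTI files requires the RNifti package")
    img <- RNifti::readNifti(image)
    affine <- structure(RNifti::xform(img), class = NULL, code = NULL)
    image <- as.array(img)
  }
  stopifnot(!is.null(affine))
  out <- sapply(seq_len(nrow(rois)), function(i)
    extract_sphere_timeseries(image, affine,
                              c(rois$x[i], rois$y[i], rois$z[i]),
                              radius_mm = radius_mm, label = rois$name[i]))
  colnames(out) <- rois$name
  out
}

#' Pearson functional connectivity matrix
#'
#' Pairwise Pearson correlations between regional time series. The
#' diagonal is fixed to zero: self-connections are excluded from every
#' edge-level operation downstream. Raw r is stored (no Fisher
#' transform); variance stabilization is applied only where the group
#' statistics require it.
#'
#' @param ts T x N matrix of regional signals (T >= 3).
#' @return Symmetric N x N matrix with zero diagonal.
#' @export
fc_matrix <- function(ts) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 3) stop("need at least 3 time points")
  sds <- apply(ts, 2, sd)
  if (any(sds == 0)) {
    bad <- colnames(ts)[sds == 0] %||% which(sds == 0)
    stop("zero-variance node(s): ", paste(bad, collapse = ", "))
  }
  C <- cor(ts)
  diag(C) <- 0
  C
}

#' Export the ROI table as a BrainNet-style .node file
#'
#' Plain-text format: x, y, z, color, size, label — one row per node.
#'
#' @param rois ROI table.
#' @param path output file.
#' @param color,size node display attributes (recycled).
#' @return `path`, invisibly.
#' @export
write_brainnet_node <- function(rois, path, color = 1, size = 1) {
  df <- data.frame(rois$x, rois$y, rois$z,
                   rep_len(color, nrow(rois)), rep_len(size, nrow(rois)),
                   rois$name)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export a matrix as a plain .edge file (N x N numeric, no labels)
#'
#' @param mat square matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_edge_matrix <- function(mat, path) {
  write.table(mat, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write / read a labeled connectivity matrix as TSV
#'
#' @param mat square matrix with dimnames.
#' @param path file path.
#' @return `write_fc_tsv`: `path` invisibly; `read_fc_tsv`: the matrix.
#' @export
write_fc_tsv <- function(mat, path) {
  write.table(mat, path, sep = "\t", quote = FALSE,
              row.names = TRUE, col.names = NA)
  invisible(path)
}

#' @rdname write_fc_tsv
#' @export
read_fc_tsv <- function(path) {
  df <- read.delim(path, row.names = 1, check.names = FALSE)
  as.matrix(df)
}
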