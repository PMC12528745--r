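#' Segment the tumor region of a preprocessed volume
#'
#' Candidate detection by fuzzy c-means clustering (3 clusters, fuzzifier
#' m = 2, tolerance 1e-5, at most 200 iterations) of the brain-voxel
#' intensities of the contrast-like channel; the candidate is the cluster
#' with the highest center.  Refinement: binary opening (radius 1),
#' closing (radius 2), keep the largest 26-connected component, fill
#' holes.  Cluster centers are initialized deterministically at the 10th,
#' 50th and 90th intensity percentiles, so identical input always yields
#' an identical mask.
#'
#' @param volume Preprocessed 4-channel volume ([preprocess_volume()]
#'   output, or any 4D array whose background is zero).
#' @param channel Channel driving the clustering (default 2, T1ce-like).
#' @param brain_mask Optional logical 3D brain mask; by default voxels
#'   where the first channel is positive.
#' @return Logical 3D segmentation mask aligned with the volume.
#' @export
segment_tumor <- function(volume, channel = 2L, brain_mask = NULL) {
  if (is.list(volume)) volume <- volume$volume
  d <- dim(volume)
  if (is.null(d) || length(d) != 4L) stop("segment_tumor: need a 4D array")
  if (is.null(brain_mask)) {
    brain_mask <- attr(volume, "brain_mask")
    if (is.null(brain_mask)) brain_mask <- volume[, , , 1] > 0
  }
  if (!any(brain_mask)) stop("segment_tumor: empty brain mask")
  v <- volume[, , , channel][brain_mask]

  centers <- matrix(stats::quantile(v, c(0.1, 0.5, 0.9), names = FALSE), 3, 1)
  if (any(duplicated(centers))) centers <- centers + c(-1e-6, 0, 1e-6)
  cm <- e1071::cmeans(matrix(v, ncol = 1), centers = centers, m = 2,
                      iter.max = 200L, method = "cmeans", verbose = FALSE,
                      control = list(reltol = 1e-5))
  tumor_cluster <- which.max(cm$centers[, 1])
  cand <- max.col(cm$membership) == tumor_cluster

  mask <- array(FALSE, dim = d[1:3])
  mask[brain_mask] <- cand
  mask <- .open3d(mask, 1L)
  mask <- .close3d(mask, 2L)
  if (any(mask)) {
    mask <- .largest_component(mask)
    mask <- .fill_holes3d(mask)
  }
  mask
}

#' Dice overlap between two binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)`; two empty masks agree perfectly and
#' score 1.
#'
#' @param pred,truth Logical (or 0/1) arrays of identical shape.
#' @return Scalar in `[0, 1]`.
#' @export
dice_score <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth))) {
    stop(sprintf("dice_score: shape mismatch [%s] vs [%s]",
                 paste(dim(pred), collapse = ","),
                 paste(dim(truth), collapse = ",")))
  }
  a <- as.logical(pred); b <- as.logical(truth)
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
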