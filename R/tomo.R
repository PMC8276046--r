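# Window offset tables for the median filters
square_offsets <- function(r) {
  as.matrix(expand.grid(dr = -r:r, dc = -r:r))
}
disc_offsets <- function(radius) {
  o <- square_offsets(ceiling(radius))
  o[o[, 1]^2 + o[, 2]^2 <= radius^2, , drop = FALSE]
}

#' Preprocess a neutron radiograph into a transmission frame
#'
#' Mirrors the standard radiograph cleanup: despeckle (3x3 median),
#' removal of bright outliers caused by gamma rays hitting the detector
#' (any pixel deviating from the median over a radius-`outlier_radius` disc
#' by more than `outlier_threshold` is replaced by that median; defaults
#' radius 2 px, threshold 50), then normalization by the pixel-wise mean of
#' the open-beam frames, turning counts into transmission values with mean
#' 1 outside the sample.
#'
#' @param frame 2D numeric matrix of detector counts.
#' @param open_beam list of 2D matrices (same dimensions) acquired without
#'   the sample; a single matrix is accepted.
#' @param outlier_radius disc radius in px.
#' @param outlier_threshold deviation threshold in count units.
#' @param despeckle apply the 3x3 median first (default TRUE).
#' @return Transmission matrix (dimensionless, open-beam regions near 1).
#' @export
preprocess_radiograph <- function(frame, open_beam, outlier_radius = 2,
                                  outlier_threshold = 50, despeckle = TRUE) {
  if (is.matrix(open_beam)) open_beam <- list(open_beam)
  stopifnot(length(open_beam) >= 1L,
            all(vapply(open_beam, function(m) all(dim(m) == dim(frame)), TRUE)))
  ob <- Reduce(`+`, open_beam) / length(open_beam)
  if (any(ob <= 0)) stop("zero open beam: non-positive mean open-beam pixel")
  x <- frame
  if (despeckle) x <- median_window_cpp(x, square_offsets(1L), -1)
  x <- median_window_cpp(x, disc_offsets(outlier_radius), outlier_threshold)
  x / ob
}

#' Quantify root volume in a reconstructed tomography stack
#'
#' Binarizes the whole stack at a transmission threshold (roots attenuate
#' more than the sand background, so root voxels are the low-transmission
#' class), counts root voxels per slice and overall, and converts the count
#' to a root system volume (RSV).
#'
#' @param stack a `tomo_stack` (or 3D array plus `voxel_mm`).
#' @param threshold numeric transmission cutoff, or `"auto"` for an Otsu
#'   threshold on the pooled stack histogram.
#' @param voxel_mm voxel edge (mm); taken from the `tomo_stack` if absent.
#' @param min_particle_vx optional particle-analysis size filter: root
#'   components (26-connectivity) smaller than this many voxels are
#'   dropped (default 0 = off).
#' @return List: `count`, `fraction`, `rsv_cm3`, `per_slice` (integer
#'   vector of per-slice counts), `threshold`.
#' @export
quantify_root_volume <- function(stack, threshold = "auto", voxel_mm = NULL,
                                 min_particle_vx = 0L) {
  vox <- if (inherits(stack, "tomo_stack")) stack$voxels else stack
  if (is.null(voxel_mm))
    voxel_mm <- if (inherits(stack, "tomo_stack")) stack$voxel_mm else
      stop("voxel_mm required")
  if (length(vox) == 0L) stop("empty stack")
  if (identical(threshold, "auto")) {
    rng <- range(vox)
    if (diff(rng) == 0) stop("degenerate histogram: constant stack")
    scaled <- matrix((as.numeric(vox) - rng[1]) / diff(rng) * 255, nrow = 1)
    t_int <- otsu_threshold(scaled)
    threshold <- rng[1] + (t_int + 0.5) / 255 * diff(rng)
  }
  root <- vox <= threshold
  if (min_particle_vx > 0L && any(root)) {
    keep <- particle_filter(root, min_particle_vx)
    root <- keep
  }
  per_slice <- apply(root, 3, sum)
  count <- sum(per_slice)
  list(count = as.integer(count),
       fraction = count / length(vox),
       rsv_cm3 = count * voxel_mm^3 / 1000,
       per_slice = as.integer(per_slice),
       threshold = threshold)
}

# Drop 26-connected root components smaller than min_vx voxels
particle_filter <- function(root, min_vx) {
  idx <- which(root)
  d <- dim(root)
  ai <- arrayInd(idx, d)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- off[rowSums(abs(off)) > 0, ]
  key <- (ai[, 3] - 1) * d[1] * d[2] + (ai[, 2] - 1) * d[1] + ai[, 1]
  pos <- seq_along(idx)
  names(pos) <- as.character(key)
  edges <- NULL
  for (k in seq_len(nrow(off))) {
    nb <- sweep(ai, 2, off[k, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    nk <- (nb[ok, 3] - 1) * d[1] * d[2] + (nb[ok, 2] - 1) * d[1] + nb[ok, 1]
    j <- pos[as.character(nk)]
    hit <- !is.na(j)
    if (any(hit))
      edges <- rbind(edges, cbind(pos[ok][hit], unname(j[hit])))
  }
  # union-find over root voxels
  parent <- seq_along(idx)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]
    i <- parent[i] }; i }
  if (!is.null(edges))
    for (e in seq_len(nrow(edges))) {
      a <- find(edges[e, 1]); b <- find(edges[e, 2])
      if (a != b) parent[a] <- b
    }
  comp <- vapply(seq_along(idx), find, 0L)
  sizes <- table(comp)
  good <- as.integer(names(sizes)[sizes >= min_vx])
  out <- array(FALSE, d)
  out[idx[comp %in% good]] <- TRUE
  out
}

#' Read a multi-page TIFF as a tomography stack
#'
#' @param path multi-page TIFF (8/16/32-bit).
#' @param voxel_mm voxel edge in mm.
#' @return A `tomo_stack` with slices along the third dimension.
#' @export
read_tomo_stack <- function(path, voxel_mm) {
  im <- EBImage::readImage(path)
  a <- EBImage::imageData(im)
  if (length(dim(a)) == 2L) a <- array(a, c(dim(a), 1L))
  tomo_stack(aperm(a, c(2, 1, 3)), voxel_mm = voxel_mm)
}
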