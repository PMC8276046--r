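#' Benchmark suites computed on the synthetic generator
#'
#' `diameter_benchmark()` renders a panel of noiseless single-root specs
#' with known width profiles, runs the full pipeline (segmentation,
#' skeletonization, ascending-path tracing, side-radius measurement) on
#' each, and returns the per-position absolute error between the measured
#' local diameter (`r_left + r_right + 1`) and the realized trunk width,
#' at every path position at least `exclude_branch_px` rows away from any
#' lateral branch point.
#'
#' `stitching_benchmark()` splits rendered images into overlapping halves
#' under small random perspective warps, re-estimates the alignment and
#' returns the mean inlier reprojection error of each pair.
#'
#' @param n_extra additional seeded width-profile variants beyond the
#'   built-in noiseless lateral-free/lateral-bearing fixtures.
#' @param exclude_branch_px half-height of the excluded zone around lateral
#'   branch points (rows).
#' @return `diameter_benchmark()`: named list of numeric vectors of absolute
#'   diameter errors in px, one per root.
#' @export
diameter_benchmark <- function(n_extra = 3L, exclude_branch_px = 5L) {
  names <- c("no_lateral_straight", "no_lateral_curved", "sparse_lateral",
             "dense_lateral", "curved_trunk", "steep_lateral", "wide_taper")
  specs <- fixture_specs(names)
  for (k in seq_len(n_extra)) {
    specs[[paste0("extra_", k)]] <- root_spec(
      trunk = data.frame(row = c(20, 110, 200, 290, 380),
                         col = 150 + c(0, 6, -5, 4, 0) * k),
      width = c(9 + 2 * k, 3),
      laterals = data.frame(s = c(0.3, 0.6), side = c(-1, 1),
                            angle = c(75, 95), length = c(45, 40), width = 3),
      seed = 200L + k)
  }
  out <- list()
  for (nm in names(specs)) {
    fx <- render_root(specs[[nm]])
    mask <- binarize_clean(fx$image, min_object_px = 0L)
    graph <- classify_points(skeletonize(mask))
    a <- find_anchors(graph, 1L)
    path <- trace_ascending(graph, a$start, a$breakpoint)
    prof <- side_radii(mask, path)
    d_px <- prof$r_left + prof$r_right + 1L
    # realized trunk width at each position, measured on the trunk-only
    # truth mask along the same scan axis the profiler used
    tm <- fx$truth$trunk_mask
    w_true <- vapply(seq_len(nrow(prof)), function(i) {
      r <- prof$row[i]; c <- prof$col[i]
      if (!tm[r, c]) return(NA_real_)
      dr <- prof$dr_right[i]; dc <- prof$dc_right[i]
      run <- 1L
      rr <- r + dr; cc <- c + dc
      while (rr >= 1 && rr <= nrow(tm) && cc >= 1 && cc <= ncol(tm) &&
             tm[rr, cc]) { run <- run + 1L; rr <- rr + dr; cc <- cc + dc }
      rr <- r - dr; cc <- c - dc
      while (rr >= 1 && rr <= nrow(tm) && cc >= 1 && cc <= ncol(tm) &&
             tm[rr, cc]) { run <- run + 1L; rr <- rr - dr; cc <- cc - dc }
      run
    }, 0)
    keep <- !is.na(w_true)
    bp <- fx$truth$branch_points
    if (!is.null(bp))
      keep <- keep & !vapply(prof$row, function(r)
        any(abs(bp$row - r) <= exclude_branch_px), TRUE)
    out[[nm]] <- abs(d_px[keep] - w_true[keep])
  }
  out
}

#' @rdname diameter_benchmark
#' @param n_pairs number of split pairs.
#' @param max_warp_px perspective warp amplitude passed to
#'   [split_for_stitching()].
#' @param seed base seed; pair k uses `seed + k` for both the warp and the
#'   robust estimator.
#' @return `stitching_benchmark()`: numeric vector of mean inlier
#'   reprojection errors in px, one per pair.
#' @export
stitching_benchmark <- function(n_pairs = 20L, max_warp_px = 3, seed = 1L) {
  imgs <- lapply(fixture_specs(c("noisy_mild", "noisy_blur")), render_root)
  errs <- numeric(n_pairs)
  for (k in seq_len(n_pairs)) {
    img <- imgs[[(k %% length(imgs)) + 1L]]$image
    sp <- split_for_stitching(img, overlap_px = 100L,
                              max_warp_px = max_warp_px, seed = seed + k)
    al <- estimate_alignment(sp$pair, seed = seed + 1000L + k)
    errs[k] <- al$mean_reproj_error_px
  }
  errs
}
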