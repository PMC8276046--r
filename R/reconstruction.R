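#' Left/right radius profile along an adventitious-root path
#'
#' For every path pixel the mask is scanned perpendicular to the local path
#' tangent (estimated over +/-2 path steps), on each side, until the first
#' background pixel. The scan is quantized to the image axis closer to the
#' perpendicular: near-vertical path segments — the usual case for an
#' adventitious root — are measured by horizontal scans, near-horizontal
#' segments by vertical scans, so the radius is an exact pixel count along
#' a raster line and the boundary is located with 1-px accuracy. The local
#' diameter is `r_left + r_right + 1`.
#'
#' "Right" is the right-hand side when travelling along the path from its
#' start (root tip, bottom) towards the breakpoint (top).
#'
#' @param mask `binary_mask` or logical matrix; every path pixel must be
#'   foreground.
#' @param path an `adventitious_path`.
#' @return A `radius_profile`: data.frame with columns `position`, `row`,
#'   `col`, `r_left`, `r_right`, `dr_right`, `dc_right`; attribute
#'   `mm_per_px`.
#' @export
side_radii <- function(mask, path) {
  g <- as_grid(mask)
  n <- nrow(path)
  rows <- path$row; cols <- path$col
  if (any(!g[cbind(rows, cols)]))
    stop("path off mask: a path pixel lies on background")
  nr <- nrow(g); nc <- ncol(g)
  r_left <- integer(n); r_right <- integer(n)
  dr_right <- integer(n); dc_right <- integer(n)
  for (i in seq_len(n)) {
    i0 <- max(1L, i - 2L); i1 <- min(n, i + 2L)
    tr <- rows[i1] - rows[i0]; tc <- cols[i1] - cols[i0]
    if (tr == 0 && tc == 0) { tr <- -1; tc <- 0 }
    # right-hand perpendicular of tangent (tr, tc) is (tc, -tr); quantize
    # to the nearer raster axis (ties go to the horizontal scan)
    pr <- tc; pc <- -tr
    d <- if (abs(pc) >= abs(pr)) c(0, sign(pc)) else c(sign(pr), 0)
    scan <- function(dr, dc) {
      k <- 0L
      rr <- rows[i] + dr; cc <- cols[i] + dc
      while (rr >= 1L && rr <= nr && cc >= 1L && cc <= nc && g[rr, cc]) {
        k <- k + 1L
        rr <- rr + dr; cc <- cc + dc
      }
      k
    }
    r_right[i] <- scan(d[1], d[2])
    r_left[i] <- scan(-d[1], -d[2])
    dr_right[i] <- d[1]; dc_right[i] <- d[2]
  }
  structure(data.frame(position = seq_len(n), row = rows, col = cols,
                       r_left = r_left, r_right = r_right,
                       dr_right = dr_right, dc_right = dc_right),
            mm_per_px = if (inherits(mask, "binary_mask"))
              attr(mask, "mm_per_px") else 25.4 / 300,
            class = c("radius_profile", "data.frame"))
}

#' Default peak-detection and classification parameters
#'
#' `th1` is the half-width of the clamp band around the running-median
#' baseline (lower threshold, px); `th2_mad_mult` sets the upper threshold
#' `Th2 = baseline + th2_mad_mult * MAD(radius - baseline)` that a bump must
#' reach to be classified. A classified peak is a lateral root when its
#' width is at most `width_max_lateral` px and its height at least
#' `height_min` px, and a nodule when it is wider than `width_max_lateral`
#' with area at least `area_min` px^2. Defaults are sized for 300-dpi scans
#' and were calibrated on the synthetic generator.
#'
#' @param baseline_window running-median window (odd, positions).
#' @param th1 lower threshold in px.
#' @param th2_mad_mult MAD multiplier for the upper threshold.
#' @param width_max_lateral,height_min,area_min class cutoffs (px, px, px^2).
#' @param max_iter suppression iteration cap.
#' @return Named list of parameters.
#' @export
peak_params <- function(baseline_window = 31L, th1 = 1, th2_mad_mult = 3,
                        width_max_lateral = 12L, height_min = 3,
                        area_min = 40, max_iter = 10L) {
  stopifnot(baseline_window %% 2L == 1L, th1 > 0, max_iter >= 1L)
  list(baseline_window = baseline_window, th1 = th1,
       th2_mad_mult = th2_mad_mult, width_max_lateral = width_max_lateral,
       height_min = height_min, area_min = area_min, max_iter = max_iter)
}

# Running-median baseline of one side's radii
radius_baseline <- function(r, window) {
  k <- min(window, if (length(r) %% 2L == 1L) length(r) else length(r) - 1L)
  if (k < 3L) return(rep(median(r), length(r)))
  stats::runmed(r, k, endrule = "median")
}

# Maximal runs where r > baseline + th1, as a data.frame of spans with
# height/width/area measured against the baseline
radius_runs <- function(r, baseline, th1) {
  above <- r > baseline + th1
  if (!any(above)) {
    return(data.frame(start = integer(), end = integer(), height = numeric(),
                      width = integer(), area = numeric(), peak = numeric()))
  }
  rl <- rle(above)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  keep <- rl$values
  starts <- starts[keep]; ends <- ends[keep]
  dev <- r - baseline
  data.frame(start = starts, end = ends,
             height = vapply(seq_along(starts), function(j)
               max(dev[starts[j]:ends[j]]), 0),
             width = ends - starts + 1L,
             area = vapply(seq_along(starts), function(j)
               sum(dev[starts[j]:ends[j]]), 0),
             peak = vapply(seq_along(starts), function(j)
               max(r[starts[j]:ends[j]]), 0))
}

#' Detect and classify radius-profile peaks
#'
#' Each side's radii are compared to a running-median baseline. A maximal
#' run of positions with `radius > baseline + Th1` that reaches the upper
#' threshold Th2 is a peak; it marks a lateral root or a nodule and is
#' classified from three parameters — height of the peak, width of the
#' peak, and area — see [peak_params()]. Sub-threshold bumps are discarded.
#'
#' @param profile a `radius_profile`.
#' @param params list from [peak_params()].
#' @return The profile with added attributes `peaks` (data.frame: side,
#'   start, end, height, width, area, klass), `baseline_left`,
#'   `baseline_right`, `thresholds` (c(Th1, Th2) with Th2 relative to a
#'   baseline of 0).
#' @export
detect_classify_peaks <- function(profile, params = peak_params()) {
  stopifnot(nrow(profile) > 0L)
  out <- profile
  peaks <- list()
  th2_abs <- numeric(2)
  for (side in c("left", "right")) {
    r <- profile[[paste0("r_", side)]]
    bl <- radius_baseline(r, params$baseline_window)
    attr(out, paste0("baseline_", side)) <- bl
    th2 <- max(params$th2_mad_mult * mad(r - bl), params$th1)
    th2_abs[(side == "right") + 1L] <- th2
    runs <- radius_runs(r, bl, params$th1)
    if (nrow(runs) == 0L) next
    runs <- runs[runs$peak > bl[runs$start] + th2 - 1e-9, , drop = FALSE]
    if (nrow(runs) == 0L) next
    klass <- ifelse(runs$width <= params$width_max_lateral &
                      runs$height >= params$height_min, "lateral",
             ifelse(runs$width > params$width_max_lateral &
                      runs$area >= params$area_min, "nodule", NA))
    runs$klass <- klass
    runs$side <- side
    runs <- runs[!is.na(runs$klass), , drop = FALSE]
    if (nrow(runs)) peaks[[side]] <- runs
  }
  pk <- if (length(peaks)) do.call(rbind, peaks) else
    data.frame(start = integer(), end = integer(), height = numeric(),
               width = integer(), area = numeric(), peak = numeric(),
               klass = character(), side = character())
  rownames(pk) <- NULL
  attr(out, "peaks") <- pk[, c("side", "start", "end", "height", "width",
                               "area", "klass")]
  attr(out, "thresholds") <- c(Th1 = params$th1, Th2 = max(th2_abs))
  attr(out, "peak_params") <- params
  out
}

#' Suppress radius-profile peaks with an iterated band-limited filter
#'
#' Within every span where a side's radius exceeds `baseline + Th1`, the
#' radii are replaced by the running-median baseline — the band-limited
#' reconstruction of the root's own width across the peak — clamped into
#' the band `[baseline - Th1, baseline + Th1]` between the two thresholds
#' around the local baseline. Peaks are then re-detected and the step
#' repeats until no span remains above the band or `max_iter` is reached.
#' The filtered radii trace the adventitious root's own width, with
#' lateral-root and nodule bulges removed.
#'
#' @param profile a `radius_profile`, ideally after
#'   [detect_classify_peaks()] (peaks are re-detected internally anyway).
#' @param params list from [peak_params()].
#' @return The profile with columns `r_left_f`, `r_right_f` (filtered,
#'   integer) added and attribute `suppress_iterations`.
#' @export
suppress_peaks <- function(profile, params = peak_params()) {
  out <- if (is.null(attr(profile, "peaks")))
    detect_classify_peaks(profile, params) else profile
  for (side in c("left", "right")) {
    r <- as.numeric(out[[paste0("r_", side)]])
    # the baseline is estimated once, from the raw profile: re-estimating it
    # from partially filtered radii would let each pass erode the root's own
    # width variation
    bl <- radius_baseline(r, params$baseline_window)
    iter <- 0L
    repeat {
      runs <- radius_runs(r, bl, params$th1)
      if (nrow(runs) == 0L || iter >= params$max_iter) break
      iter <- iter + 1L
      for (j in seq_len(nrow(runs))) {
        span <- runs$start[j]:runs$end[j]
        # band-limited fill: the running-median baseline is the low-pass
        # reconstruction of the root's own width across the peak; clamp
        # into the Th1 band around it
        r[span] <- clamp(bl[span], bl[span] - params$th1, bl[span] + params$th1)
      }
    }
    if (nrow(radius_runs(r, bl, params$th1)) > 0L)
      warning("no convergence: residual peaks after max_iter iterations")
    out[[paste0("r_", side, "_f")]] <- as.integer(round(pmax(r, 0)))
    attr(out, paste0("suppress_iterations_", side)) <- iter
  }
  out
}

#' Reconstruct the adventitious root from filtered radii
#'
#' Rebuilds the adventitious-root mask as the union, over path positions,
#' of the perpendicular cross-section segments of length
#' `r_left_f + 1 + r_right_f`, and reports the local diameter profile
#' `d = r_left_f + r_right_f + 1` in px and mm. The result represents the
#' adventitious root without lateral information, at its original diameter.
#'
#' @param mask source `binary_mask` (for dimensions and calibration).
#' @param path the traced `adventitious_path`.
#' @param profile a `radius_profile` after [suppress_peaks()].
#' @return List with `mask` (logical `binary_mask`, adventitious root only)
#'   and `diameter` (data.frame: position, row, col, d_px, d_mm).
#' @export
reconstruct_root <- function(mask, path, profile) {
  stopifnot(!is.null(profile$r_left_f), nrow(profile) == nrow(path))
  g <- as_grid(mask)
  nr <- nrow(g); nc <- ncol(g)
  adv <- matrix(FALSE, nr, nc)
  for (i in seq_len(nrow(profile))) {
    d <- c(profile$dr_right[i], profile$dc_right[i])
    for (k in -profile$r_left_f[i]:profile$r_right_f[i]) {
      rr <- profile$row[i] + k * d[1]
      cc <- profile$col[i] + k * d[2]
      if (rr >= 1L && rr <= nr && cc >= 1L && cc <= nc) adv[rr, cc] <- TRUE
    }
  }
  mmpp <- attr(profile, "mm_per_px")
  d_px <- profile$r_left_f + profile$r_right_f + 1L
  list(mask = binary_mask(adv, mm_per_px = mmpp,
                          polarity = if (inherits(mask, "binary_mask"))
                            attr(mask, "polarity") else "bright"),
       diameter = data.frame(position = profile$position, row = profile$row,
                             col = profile$col, d_px = d_px,
                             d_mm = d_px * mmpp))
}
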