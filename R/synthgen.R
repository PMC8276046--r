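#' Specification of a synthetic root image
#'
#' Describes a dark-background image holding one (optionally two) bright
#' main root(s) running top to bottom, with lateral roots branching off and
#' optional nodule-like blobs — the geometry of a cutting's adventitious
#' root imaged in a rhizotron.
#'
#' @param image_size `c(rows, cols)` in px.
#' @param trunk data.frame with columns `row`, `col`: control points of the
#'   main (adventitious) root, ordered from its top anchor down to its tip.
#' @param width `c(top_px, tip_px)`: root width tapers linearly in arc
#'   length between these values (realized widths are odd, discs are
#'   stamped along the centreline).
#' @param laterals data.frame with columns `s` (branch position along the
#'   trunk, in (0, 1)), `side` (-1 left, +1 right), `angle` (degrees from
#'   the downward vertical: 0 points down, 90 horizontal, > 90 ascending),
#'   `length` (px), `width` (px, odd). `NULL` for none.
#' @param nodules data.frame with columns `s`, `a` (horizontal semi-axis,
#'   px), `b` (vertical semi-axis, px). `NULL` for none.
#' @param second_trunk optional list with `trunk` and `width` as above: a
#'   second, lateral-free adventitious root (for multi-root images).
#' @param bg_level,root_level 8-bit background/root intensities.
#' @param noise_sd Gaussian noise standard deviation (gray levels; 0 =
#'   noiseless).
#' @param blur_sigma Gaussian optical blur in px (0 = none).
#' @param mm_per_px calibration (default 300-dpi scan).
#' @param seed integer; fixes all randomness of the rendering.
#' @return A `root_spec` list.
#' @export
root_spec <- function(image_size = c(400L, 300L),
                      trunk = data.frame(row = c(20, 120, 240, 380),
                                         col = c(150, 140, 160, 150)),
                      width = c(9, 3),
                      laterals = NULL, nodules = NULL, second_trunk = NULL,
                      bg_level = 30, root_level = 200,
                      noise_sd = 0, blur_sigma = 0,
                      mm_per_px = 25.4 / 300, seed = 1L) {
  stopifnot(length(image_size) == 2L, all(image_size >= 32L),
            is.data.frame(trunk), nrow(trunk) >= 2L,
            all(diff(trunk$row) > 0), all(width >= 1),
            bg_level < root_level, mm_per_px > 0)
  if (!is.null(laterals))
    stopifnot(all(laterals$s > 0), all(laterals$s < 1),
              all(laterals$side %in% c(-1, 1)), all(laterals$width >= 1))
  if (!is.null(nodules)) stopifnot(all(nodules$s > 0), all(nodules$s < 1))
  structure(list(image_size = as.integer(image_size), trunk = trunk,
                 width = width, laterals = laterals, nodules = nodules,
                 second_trunk = second_trunk, bg_level = bg_level,
                 root_level = root_level, noise_sd = noise_sd,
                 blur_sigma = blur_sigma, mm_per_px = mm_per_px,
                 seed = as.integer(seed)),
            class = "root_spec")
}

# Sample a smooth polyline through control points at ~0.5 px arc steps.
# Returns data.frame(row, col, s) with s = normalized arc length in [0, 1].
sample_polyline <- function(ctrl, step = 0.5) {
  d <- sqrt(diff(ctrl$row)^2 + diff(ctrl$col)^2)
  t <- c(0, cumsum(d))
  n <- max(16L, ceiling(sum(d) / step))
  tt <- seq(0, t[length(t)], length.out = n)
  if (nrow(ctrl) > 2L) {
    r <- spline(t, ctrl$row, xout = tt)$y
    c_ <- spline(t, ctrl$col, xout = tt)$y
  } else {
    r <- approx(t, ctrl$row, xout = tt)$y
    c_ <- approx(t, ctrl$col, xout = tt)$y
  }
  arc <- c(0, cumsum(sqrt(diff(r)^2 + diff(c_)^2)))
  data.frame(row = r, col = c_, s = arc / arc[length(arc)],
             arc_px = arc)
}

# Rasterize sampled polyline to a deduplicated 8-connected pixel chain
rasterize_chain <- function(pl) {
  r <- round(pl$row); c_ <- round(pl$col)
  keep <- c(TRUE, diff(r) != 0 | diff(c_) != 0)
  data.frame(row = as.integer(r[keep]), col = as.integer(c_[keep]),
             s = pl$s[keep])
}

#' Render a synthetic root image with exact ground truth
#'
#' Strokes the main root's centreline with discs of linearly tapering
#' radius, then the laterals, then the nodule ellipses; composes the 8-bit
#' intensity image (optionally blurred and noised) and emits the ground
#' truth every pipeline stage can be scored against. Output is
#' deterministic for identical spec (including seed).
#'
#' @param spec a [root_spec()].
#' @return List with `image` (a `root_image`) and `truth`, a list holding:
#'   `mask` (exact `binary_mask`), `trunk_mask`, `lateral_only_mask`,
#'   `nodule_only_mask`, `main_skeleton` (data.frame row, col, s),
#'   `width_profile` (data.frame row, col, s, w_true: realized horizontal
#'   trunk width at each centreline pixel), `branch_points` (data.frame of
#'   lateral attachment pixels), `laterals` (data.frame incl. true
#'   `length_px`), `arl_px`, `arl_mm`, `lrn`, `llrl_mm`, `tnn`,
#'   `projected_area_mm2`, `arn`, `mm_per_px`.
#' @export
render_root <- function(spec) {
  nr <- spec$image_size[1]; nc <- spec$image_size[2]
  empty <- matrix(FALSE, nr, nc)

  draw_trunk <- function(ctrl, width) {
    pl <- sample_polyline(ctrl)
    rad <- (width[1] + (width[2] - width[1]) * pl$s - 1) / 2
    rad <- pmax(rad, 0)
    if (any(pl$row - rad < 1 | pl$row + rad > nr |
            pl$col - rad < 1 | pl$col + rad > nc))
      stop("root exits canvas")
    list(pl = pl,
         mask = stamp_discs_cpp(empty, pl$row - 1, pl$col - 1, rad),
         skeleton = rasterize_chain(pl))
  }

  tr <- draw_trunk(spec$trunk, spec$width)
  trunk_mask <- tr$mask
  skel <- tr$skeleton
  arl_px <- tail(tr$pl$arc_px, 1)
  arn <- 1L
  skel2 <- NULL
  if (!is.null(spec$second_trunk)) {
    tr2 <- draw_trunk(spec$second_trunk$trunk, spec$second_trunk$width)
    trunk_mask <- trunk_mask | tr2$mask
    skel2 <- tr2$skeleton
    arn <- 2L
  }

  # trunk point (row, col) and local radius at normalized position s
  trunk_at <- function(s) {
    i <- which.min(abs(tr$pl$s - s))
    list(row = tr$pl$row[i], col = tr$pl$col[i],
         rad = (spec$width[1] + diff(spec$width) * s - 1) / 2)
  }

  lateral_only <- empty
  branch_points <- NULL
  lat_tab <- spec$laterals
  if (!is.null(lat_tab) && nrow(lat_tab)) {
    lat_tab$length_px <- lat_tab$length
    for (j in seq_len(nrow(lat_tab))) {
      at <- trunk_at(lat_tab$s[j])
      th <- lat_tab$angle[j] * pi / 180
      dir <- c(cos(th), lat_tab$side[j] * sin(th))   # (drow, dcol), row down
      steps <- seq(0, lat_tab$length[j], by = 0.5)
      pr <- at$row + dir[1] * steps
      pc <- at$col + dir[2] * steps
      rad <- rep((lat_tab$width[j] - 1) / 2, length(steps))
      if (any(pr - rad[1] < 1 | pr + rad[1] > nr |
              pc - rad[1] < 1 | pc + rad[1] > nc))
        stop("root exits canvas")
      lateral_only <- stamp_discs_cpp(lateral_only, pr - 1, pc - 1, rad)
      branch_points <- rbind(branch_points,
                             data.frame(lateral = j,
                                        row = as.integer(round(at$row)),
                                        col = as.integer(round(at$col)),
                                        s = lat_tab$s[j]))
    }
  }

  nodule_only <- empty
  if (!is.null(spec$nodules) && nrow(spec$nodules)) {
    for (j in seq_len(nrow(spec$nodules))) {
      at <- trunk_at(spec$nodules$s[j])
      a <- spec$nodules$a[j]; b <- spec$nodules$b[j]
      rs <- round(at$row) + (-ceiling(b)):ceiling(b)
      cs <- round(at$col) + (-ceiling(a)):ceiling(a)
      rs <- rs[rs >= 1 & rs <= nr]; cs <- cs[cs >= 1 & cs <= nc]
      for (r in rs) for (c_ in cs) {
        if (((r - at$row) / b)^2 + ((c_ - at$col) / a)^2 <= 1)
          nodule_only[r, c_] <- TRUE
      }
    }
  }

  lateral_only <- lateral_only & !trunk_mask
  nodule_only <- nodule_only & !trunk_mask & !lateral_only
  mask <- trunk_mask | lateral_only | nodule_only

  # realized horizontal trunk width at each centreline pixel (trunk only)
  wp <- skel
  wp$w_true <- vapply(seq_len(nrow(skel)), function(i) {
    r <- skel$row[i]; c_ <- skel$col[i]
    if (!trunk_mask[r, c_]) return(NA_real_)
    l <- c_; while (l > 1 && trunk_mask[r, l - 1L]) l <- l - 1L
    h <- c_; while (h < nc && trunk_mask[r, h + 1L]) h <- h + 1L
    h - l + 1
  }, 0)

  set.seed(spec$seed)
  img <- matrix(spec$bg_level, nr, nc) +
    (spec$root_level - spec$bg_level) * mask
  if (spec$blur_sigma > 0) img <- gaussian_blur(img, spec$blur_sigma)
  if (spec$noise_sd > 0) img <- img + rnorm(length(img), 0, spec$noise_sd)
  img <- round(clamp(img, 0, 255))

  lrn <- if (is.null(lat_tab)) 0L else nrow(lat_tab)
  llrl_mm <- if (lrn > 0L) max(lat_tab$length_px) * spec$mm_per_px else 0
  truth <- list(
    mask = binary_mask(mask, mm_per_px = spec$mm_per_px),
    trunk_mask = trunk_mask, lateral_only_mask = lateral_only,
    nodule_only_mask = nodule_only,
    main_skeleton = skel, main_skeleton2 = skel2,
    width_profile = wp, branch_points = branch_points,
    laterals = lat_tab,
    arl_px = arl_px, arl_mm = arl_px * spec$mm_per_px,
    lrn = lrn, llrl_mm = llrl_mm,
    tnn = if (is.null(spec$nodules)) 0L else nrow(spec$nodules),
    projected_area_mm2 = sum(mask) * spec$mm_per_px^2,
    arn = arn, mm_per_px = spec$mm_per_px)
  list(image = root_image(img, mm_per_px = spec$mm_per_px), truth = truth)
}

#' Split an image into two overlapping halves for stitching tests
#'
#' Crops a top and a bottom half sharing an `overlap_px`-high common band,
#' optionally warping the bottom half by a small random perspective
#' transform, and returns the true homography mapping bottom-half
#' coordinates into the top-half frame.
#'
#' @param image `root_image` or matrix.
#' @param overlap_px height of the common band (>= 16).
#' @param max_warp_px bottom-half corners are displaced uniformly within
#'   +/- this many px (0 = pure translation).
#' @param seed seed for the corner displacements.
#' @return List with `pair` (list: `top`, `bottom`, `nominal_overlap_px`)
#'   and `h_true` (3x3 matrix acting on homogeneous `(col, row, 1)`).
#' @export
split_for_stitching <- function(image, overlap_px = 100L, max_warp_px = 0,
                                seed = 1L) {
  if (overlap_px < 16L) stop("overlap too small: need at least 16 px")
  px <- if (inherits(image, "root_image")) luminance(image) else image
  H <- nrow(px); W <- ncol(px)
  if (overlap_px >= H) stop("overlap too small: exceeds image height")
  h_t <- ceiling((H + overlap_px) / 2)
  top <- px[1:h_t, , drop = FALSE]
  bottom <- px[(h_t - overlap_px + 1L):H, , drop = FALSE]
  shift <- h_t - overlap_px               # bottom row r maps to top row r+shift
  t_mat <- matrix(c(1, 0, 0, 0, 1, shift, 0, 0, 1), 3, 3, byrow = TRUE)
  if (max_warp_px > 0) {
    set.seed(seed)
    hb <- nrow(bottom)
    src <- cbind(x = c(1, W, 1, W), y = c(1, 1, hb, hb))
    dst <- src + matrix(runif(8, -max_warp_px, max_warp_px), 4, 2)
    # q maps warped-bottom coords -> original bottom coords
    q <- fit_homography(src, dst)
    bottom_w <- warp_bilinear(bottom, q, nrow_out = hb, ncol_out = W)
    bottom_w[is.na(bottom_w)] <- 0
    h_true <- t_mat %*% q
    list(pair = list(top = top, bottom = bottom_w,
                     nominal_overlap_px = as.integer(overlap_px)),
         h_true = h_true / h_true[3, 3])
  } else {
    list(pair = list(top = top, bottom = bottom,
                     nominal_overlap_px = as.integer(overlap_px)),
         h_true = t_mat)
  }
}

#' Render a synthetic transmission tomography stack
#'
#' Emulates a reconstructed neutron tomography stack of a sand-filled
#' sample holder: sand background transmission near 0.8 and root "tubes"
#' (slanted cylinders) with voxel transmissions drawn uniformly in a lower
#' band (default \[0.2, 0.4\]), optionally with Gaussian noise.
#'
#' @param dim `c(rows, cols, slices)` voxel dimensions.
#' @param tubes data.frame with columns `r0, c0, s0, r1, c1, s1, radius`
#'   (voxel coordinates of the axis endpoints and tube radius).
#' @param sand_level background transmission.
#' @param root_range transmission band for root voxels.
#' @param noise_sd Gaussian noise sd (0 = none).
#' @param voxel_mm voxel edge length in mm.
#' @param seed seed for root-voxel values and noise.
#' @return List with `stack` (a `tomo_stack`) and `truth` (list: `root`
#'   logical array, `count`, `fraction`, `rsv_cm3`).
#' @export
render_tomo_stack <- function(dim = c(64L, 64L, 64L),
                              tubes = data.frame(r0 = 32, c0 = 32, s0 = 1,
                                                 r1 = 40, c1 = 28, s1 = 64,
                                                 radius = 4),
                              sand_level = 0.8, root_range = c(0.2, 0.4),
                              noise_sd = 0, voxel_mm = 0.0152, seed = 1L) {
  stopifnot(length(dim) == 3L, all(dim >= 4L))
  root <- array(FALSE, dim)
  if (!is.null(tubes) && nrow(tubes)) {
    grid_r <- seq_len(dim[1]); grid_c <- seq_len(dim[2])
    for (j in seq_len(nrow(tubes))) {
      p0 <- c(tubes$r0[j], tubes$c0[j], tubes$s0[j])
      p1 <- c(tubes$r1[j], tubes$c1[j], tubes$s1[j])
      rad <- tubes$radius[j]
      n <- max(2L, ceiling(2 * sqrt(sum((p1 - p0)^2))))
      for (t in seq(0, 1, length.out = n)) {
        p <- p0 + t * (p1 - p0)
        sl <- round(p[3])
        if (sl < 1 || sl > dim[3]) next
        rr <- grid_r[abs(grid_r - p[1]) <= rad]
        cc <- grid_c[abs(grid_c - p[2]) <= rad]
        for (r in rr) for (c_ in cc) {
          if ((r - p[1])^2 + (c_ - p[2])^2 <= rad^2) root[r, c_, sl] <- TRUE
        }
      }
    }
  }
  set.seed(seed)
  vox <- array(sand_level, dim)
  nroot <- sum(root)
  if (nroot > 0)
    vox[root] <- runif(nroot, root_range[1], root_range[2])
  if (noise_sd > 0) vox <- vox + rnorm(length(vox), 0, noise_sd)
  st <- tomo_stack(vox, voxel_mm = voxel_mm)
  list(stack = st,
       truth = list(root = root, count = nroot,
                    fraction = nroot / prod(dim),
                    rsv_cm3 = nroot * voxel_mm^3 / 1000))
}

#' Named fixture suite of synthetic root specs
#'
#' Twelve specs spanning the situations the pipeline must handle:
#' lateral-free straight and curved trunks, sparse/dense/steep laterals,
#' nodules, noisy and blurred images, a two-root image and a strong taper.
#' Definitions are stored as JSON under `inst/extdata/fixture_specs.json`.
#'
#' @param names optional character vector to subset by name.
#' @return Named list of `root_spec` objects.
#' @export
fixture_specs <- function(names = NULL) {
  path <- system.file("extdata", "fixture_specs.json", package = "rootascent")
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  specs <- lapply(raw, function(s) {
    root_spec(image_size = s$image_size,
              trunk = as.data.frame(s$trunk),
              width = s$width,
              laterals = if (!is.null(s$laterals)) as.data.frame(s$laterals),
              nodules = if (!is.null(s$nodules)) as.data.frame(s$nodules),
              second_trunk = if (!is.null(s$second_trunk))
                list(trunk = as.data.frame(s$second_trunk$trunk),
                     width = s$second_trunk$width),
              bg_level = s$bg_level, root_level = s$root_level,
              noise_sd = s$noise_sd, blur_sigma = s$blur_sigma,
              mm_per_px = s$mm_per_px, seed = s$seed)
  })
  if (!is.null(names)) specs <- specs[names]
  specs
}

#' Construct a tomography stack object
#'
#' @param voxels 3D numeric array `[row, col, slice]`.
#' @param voxel_mm voxel edge in mm.
#' @param transmission_scale whether values are normalized transmission.
#' @return A `tomo_stack`.
#' @export
tomo_stack <- function(voxels, voxel_mm, transmission_scale = TRUE) {
  stopifnot(length(dim(voxels)) == 3L, voxel_mm > 0)
  structure(list(voxels = voxels, voxel_mm = voxel_mm,
                 transmission_scale = transmission_scale),
            class = "tomo_stack")
}

#' @export
print.tomo_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("tomo_stack: %d x %d x %d voxels, %.4f mm/voxel\n",
              d[1], d[2], d[3], x$voxel_mm))
  invisible(x)
}
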