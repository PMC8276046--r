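# Homographies act on homogeneous (x = col, y = row, 1) column vectors.

# Apply a homography to an n x 2 matrix of (x, y) points
apply_homography <- function(h, xy) {
  p <- h %*% rbind(t(xy), 1)
  cbind(p[1, ] / p[3, ], p[2, ] / p[3, ])
}

# Direct linear transform with Hartley normalization: returns h such that
# to ~ h(from); both point sets n x 2 (x, y), n >= 4
fit_homography <- function(to, from) {
  src <- from; dst <- to
  stopifnot(nrow(src) >= 4L, nrow(src) == nrow(dst))
  norm_t <- function(p) {
    m <- colMeans(p)
    s <- sqrt(2) / mean(sqrt(rowSums(sweep(p, 2, m)^2)) + 1e-12)
    matrix(c(s, 0, -s * m[1], 0, s, -s * m[2], 0, 0, 1), 3, 3, byrow = TRUE)
  }
  t1 <- norm_t(src); t2 <- norm_t(dst)
  a <- apply_homography(t1, src)
  b <- apply_homography(t2, dst)
  n <- nrow(src)
  A <- matrix(0, 2 * n, 9)
  for (i in seq_len(n)) {
    x <- a[i, 1]; y <- a[i, 2]; u <- b[i, 1]; v <- b[i, 2]
    A[2 * i - 1, ] <- c(-x, -y, -1, 0, 0, 0, u * x, u * y, u)
    A[2 * i, ] <- c(0, 0, 0, -x, -y, -1, v * x, v * y, v)
  }
  h <- matrix(svd(A, nu = 0, nv = 9)$v[, 9], 3, 3, byrow = TRUE)
  h <- solve(t2) %*% h %*% t1
  h / h[3, 3]
}

# Harris corner detection on a [0, 1] luminance matrix; returns data.frame
# (row, col, response) sorted by decreasing response
harris_keypoints <- function(x, max_points = 400L, sigma_d = 1, sigma_i = 2,
                             k = 0.04, margin = 9L) {
  xs <- gaussian_blur(x, sigma_d)
  nr <- nrow(xs); nc <- ncol(xs)
  gx <- (xs[, c(2:nc, nc)] - xs[, c(1, 1:(nc - 1))]) / 2
  gy <- (xs[c(2:nr, nr), ] - xs[c(1, 1:(nr - 1)), ]) / 2
  sxx <- gaussian_blur(gx * gx, sigma_i)
  syy <- gaussian_blur(gy * gy, sigma_i)
  sxy <- gaussian_blur(gx * gy, sigma_i)
  resp <- sxx * syy - sxy^2 - k * (sxx + syy)^2
  # 3x3 non-maximum suppression (strict against earlier neighbours)
  shift <- function(m, dr, dc) {
    out <- matrix(-Inf, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  is_max <- resp > 0
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- shift(resp, dr, dc)
    is_max <- is_max & (resp > nb | (resp == nb & (dr > 0 | (dr == 0 & dc > 0))))
  }
  is_max[c(1:margin, (nr - margin + 1):nr), ] <- FALSE
  is_max[, c(1:margin, (nc - margin + 1):nc)] <- FALSE
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(data.frame(row = integer(), col = integer(), response = numeric()))
  r <- resp[idx]
  ord <- order(-r, idx[, 1], idx[, 2])
  ord <- head(ord, max_points)
  data.frame(row = idx[ord, 1], col = idx[ord, 2], response = r[ord])
}

# Normalized patch descriptors (patch_r*2+1 square, zero mean, unit norm);
# keypoints too close to the border or with flat patches are dropped
patch_descriptors <- function(x, kp, patch_r = 7L) {
  keep <- kp$row > patch_r & kp$row <= nrow(x) - patch_r &
    kp$col > patch_r & kp$col <= ncol(x) - patch_r
  kp <- kp[keep, , drop = FALSE]
  if (nrow(kp) == 0L) return(list(kp = kp, desc = NULL))
  d <- matrix(0, (2 * patch_r + 1)^2, nrow(kp))
  ok <- logical(nrow(kp))
  for (i in seq_len(nrow(kp))) {
    p <- x[(kp$row[i] - patch_r):(kp$row[i] + patch_r),
           (kp$col[i] - patch_r):(kp$col[i] + patch_r)]
    v <- as.numeric(p) - mean(p)
    nv <- sqrt(sum(v^2))
    if (nv > 1e-8) { d[, i] <- v / nv; ok[i] <- TRUE }
  }
  list(kp = kp[ok, , drop = FALSE], desc = d[, ok, drop = FALSE])
}

# Mutual-best normalized-correlation matching; returns index pairs
match_descriptors <- function(d1, d2, min_score = 0.6) {
  s <- crossprod(d1, d2)                     # n1 x n2 correlation
  b1 <- max.col(s)                           # best in 2 for each of 1
  b2 <- max.col(t(s))                        # best in 1 for each of 2
  i <- seq_len(nrow(s))
  mutual <- b2[b1] == i & s[cbind(i, b1)] >= min_score
  cbind(i1 = i[mutual], i2 = b1[mutual])
}

# RANSAC homography from matched (x, y) point sets; maps p_src -> p_dst
ransac_homography <- function(p_src, p_dst, tol = 2, iters = 1000L,
                              seed = 42L) {
  n <- nrow(p_src)
  stopifnot(n >= 4L)
  set.seed(seed)
  collinear <- function(p) {
    for (tri in list(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))) {
      v1 <- p[tri[2], ] - p[tri[1], ]; v2 <- p[tri[3], ] - p[tri[1], ]
      if (abs(v1[1] * v2[2] - v1[2] * v2[1]) < 1e-6) return(TRUE)
    }
    FALSE
  }
  best_inl <- logical(n); best_count <- -1L
  for (it in seq_len(iters)) {
    s <- sample.int(n, 4L)
    if (collinear(p_src[s, , drop = FALSE]) ||
        collinear(p_dst[s, , drop = FALSE])) next
    h <- tryCatch(fit_homography(p_dst[s, , drop = FALSE],
                                 p_src[s, , drop = FALSE]),
                  error = function(e) NULL)
    if (is.null(h)) next
    proj <- apply_homography(h, p_src)
    err <- sqrt(rowSums((proj - p_dst)^2))
    inl <- err < tol
    if (sum(inl) > best_count) { best_count <- sum(inl); best_inl <- inl }
  }
  if (best_count < 4L) stop("degenerate geometry: no homography consensus")
  # refit on the consensus set, twice
  inl <- best_inl
  for (pass in 1:2) {
    if (sum(inl) < 4L) break
    h <- fit_homography(p_dst[inl, , drop = FALSE], p_src[inl, , drop = FALSE])
    err <- sqrt(rowSums((apply_homography(h, p_src) - p_dst)^2))
    inl <- err < tol
  }
  if (sum(inl) < 4L || collinear_spread(p_src[inl, , drop = FALSE]))
    stop("degenerate geometry: inlier set is (near) collinear")
  list(h = h / h[3, 3], inliers = inl,
       mean_err = mean(err[inl]))
}

# TRUE when points have no 2D spread (all within a thin line)
collinear_spread <- function(p) {
  if (nrow(p) < 3L) return(TRUE)
  e <- eigen(stats::cov(p), symmetric = TRUE, only.values = TRUE)$values
  e[2] < 1e-6 * max(e[1], 1)
}

#' Estimate the alignment between two overlapping scan halves
#'
#' Detects corner keypoints on the luminance of both halves, matches
#' normalized intensity-patch descriptors, and estimates the homography
#' mapping bottom-half coordinates into the top-half frame by RANSAC with
#' a reprojection tolerance, followed by a least-squares refit on the
#' consensus set. Deterministic for a fixed `seed`.
#'
#' @param pair list with `top`, `bottom` (matrices or `root_image`s, RGB
#'   accepted) and optionally `nominal_overlap_px`.
#' @param min_keypoints minimum matched keypoints required (default 12).
#' @param tol RANSAC reprojection tolerance in px (default 2).
#' @param seed RANSAC seed (default 42).
#' @param max_points keypoints retained per half.
#' @return An `alignment`: list with `homography` (3x3, acts on
#'   `(col, row, 1)`), `inliers` (data.frame `col_bottom, row_bottom,
#'   col_top, row_top`), `mean_reproj_error_px`, `n_matches`.
#' @export
estimate_alignment <- function(pair, min_keypoints = 12L, tol = 2,
                               seed = 42L, max_points = 400L) {
  top <- luminance(pair$top) / 255
  bot <- luminance(pair$bottom) / 255
  kp_t <- harris_keypoints(top, max_points = max_points)
  kp_b <- harris_keypoints(bot, max_points = max_points)
  dt <- patch_descriptors(gaussian_blur(top, 1), kp_t)
  db <- patch_descriptors(gaussian_blur(bot, 1), kp_b)
  if (is.null(dt$desc) || is.null(db$desc))
    stop("insufficient keypoints: no textured patches found")
  m <- match_descriptors(db$desc, dt$desc)
  if (nrow(m) < min_keypoints)
    stop(sprintf("insufficient keypoints: %d matches < %d required",
                 nrow(m), min_keypoints))
  p_b <- cbind(db$kp$col[m[, 1]], db$kp$row[m[, 1]])
  p_t <- cbind(dt$kp$col[m[, 2]], dt$kp$row[m[, 2]])
  fit <- ransac_homography(p_b, p_t, tol = tol, seed = seed)
  inl <- fit$inliers
  structure(list(homography = fit$h,
                 inliers = data.frame(col_bottom = p_b[inl, 1],
                                      row_bottom = p_b[inl, 2],
                                      col_top = p_t[inl, 1],
                                      row_top = p_t[inl, 2]),
                 mean_reproj_error_px = fit$mean_err,
                 n_matches = nrow(m)),
            class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf("alignment: %d inliers / %d matches, mean reprojection %.3f px\n",
              nrow(x$inliers), x$n_matches, x$mean_reproj_error_px))
  print(round(x$homography, 5))
  invisible(x)
}

# Inverse-map warp: sample `src` at h_inv(dst coords), bilinear, NA outside
warp_bilinear <- function(src, h_inv, nrow_out, ncol_out,
                          row_offset = 0, col_offset = 0) {
  grid <- cbind(rep(seq_len(ncol_out), each = nrow_out) + col_offset,
                rep(seq_len(nrow_out), ncol_out) + row_offset)
  p <- apply_homography(h_inv, grid)
  x <- p[, 1]; y <- p[, 2]
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  nr <- nrow(src); nc <- ncol(src)
  valid <- x0 >= 1 & x0 + 1 <= nc & y0 >= 1 & y0 + 1 <= nr
  out <- rep(NA_real_, nrow_out * ncol_out)
  if (any(valid)) {
    i00 <- cbind(y0[valid], x0[valid])
    v <- (1 - fx[valid]) * (1 - fy[valid]) * src[i00] +
      fx[valid] * (1 - fy[valid]) * src[cbind(y0[valid], x0[valid] + 1)] +
      (1 - fx[valid]) * fy[valid] * src[cbind(y0[valid] + 1, x0[valid])] +
      fx[valid] * fy[valid] * src[cbind(y0[valid] + 1, x0[valid] + 1)]
    out[valid] <- v
  }
  matrix(out, nrow_out, ncol_out)
}

#' Merge two aligned scan halves into one image
#'
#' Warps the bottom half into the top half's frame with the alignment
#' homography and composes both on the union bounding-box canvas. Pixels
#' covered by both halves (the common band) are blended by per-pixel
#' averaging; elsewhere the available half is copied.
#'
#' @param pair as in [estimate_alignment()].
#' @param alignment an `alignment` (or 3x3 homography matrix).
#' @param mm_per_px calibration propagated to the output.
#' @return A `root_image` of the merged scan.
#' @export
merge_halves <- function(pair, alignment, mm_per_px = 25.4 / 300) {
  top <- luminance(pair$top)
  bot <- luminance(pair$bottom)
  h <- if (inherits(alignment, "alignment")) alignment$homography else alignment
  corners <- cbind(c(1, ncol(bot), 1, ncol(bot)),
                   c(1, 1, nrow(bot), nrow(bot)))
  warped <- round(apply_homography(h, corners), 6)  # absorb numeric jitter
  row_min <- floor(min(1, warped[, 2])); row_max <- ceiling(max(nrow(top), warped[, 2]))
  col_min <- floor(min(1, warped[, 1])); col_max <- ceiling(max(ncol(top), warped[, 1]))
  if (min(warped[, 2]) > nrow(top) + 1 || max(warped[, 2]) < 0)
    stop("empty overlap: warped halves do not intersect")
  nr_out <- row_max - row_min + 1L; nc_out <- col_max - col_min + 1L
  bot_w <- warp_bilinear(bot, solve(h), nr_out, nc_out,
                         row_offset = row_min - 1, col_offset = col_min - 1)
  canvas <- matrix(NA_real_, nr_out, nc_out)
  canvas[(1 - row_min + 1):(nrow(top) - row_min + 1),
         (1 - col_min + 1):(ncol(top) - col_min + 1)] <- top
  both <- !is.na(canvas) & !is.na(bot_w)
  only_b <- is.na(canvas) & !is.na(bot_w)
  canvas[both] <- (canvas[both] + bot_w[both]) / 2
  canvas[only_b] <- bot_w[only_b]
  canvas[is.na(canvas)] <- 0
  root_image(canvas, mm_per_px = mm_per_px)
}
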