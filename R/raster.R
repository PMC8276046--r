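#' Calibrated root image
#'
#' Wraps a 2D numeric matrix (grayscale, values in \[0, 255\]) or a
#' rows x cols x 3 array (RGB) together with its spatial calibration.
#'
#' @param pixels numeric matrix `[row, col]` or 3D array `[row, col, channel]`.
#' @param mm_per_px millimetres per pixel edge (default 25.4/300, a 300-dpi
#'   scan).
#' @return A `root_image` object.
#' @export
root_image <- function(pixels, mm_per_px = 25.4 / 300) {
  stopifnot(is.numeric(pixels), length(dim(pixels)) %in% c(2L, 3L),
            is.numeric(mm_per_px), mm_per_px > 0)
  structure(list(pixels = pixels, mm_per_px = mm_per_px),
            class = "root_image")
}

#' @export
print.root_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("root_image: %d x %d px%s, %.4f mm/px\n", d[1], d[2],
              if (length(d) == 3) " (RGB)" else "", x$mm_per_px))
  invisible(x)
}

#' Luminance of an image
#'
#' RGB images are converted with Rec. 601 weights (0.299, 0.587, 0.114);
#' grayscale input passes through.
#'
#' @param img a `root_image`, matrix, or 3D array.
#' @return Numeric matrix `[row, col]`.
#' @export
luminance <- function(img) {
  px <- if (inherits(img, "root_image")) img$pixels else img
  if (length(dim(px)) == 2L) return(px)
  0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
}

#' Read an image file as a calibrated root image
#'
#' PNG and TIFF (8/16-bit) are supported through EBImage. Intensities are
#' rescaled to \[0, 255\]; the image is transposed so rows run top to bottom.
#'
#' @param path file path.
#' @inheritParams root_image
#' @return A `root_image`.
#' @export
read_root_image <- function(path, mm_per_px = 25.4 / 300) {
  im <- EBImage::readImage(path)
  a <- EBImage::imageData(im)
  if (length(dim(a)) == 3L && dim(a)[3] >= 3L) {
    a <- aperm(a[, , 1:3], c(2, 1, 3))
  } else {
    if (length(dim(a)) == 3L) a <- a[, , 1]
    a <- t(a)
  }
  root_image(a * 255, mm_per_px = mm_per_px)
}

#' Write a grayscale raster or mask to PNG/TIFF
#'
#' @param x matrix in \[0, 255\], logical matrix, or `root_image`.
#' @param path output path; format chosen by extension (.png or .tif/.tiff).
#' @return `path`, invisibly.
#' @export
write_root_image <- function(x, path) {
  px <- if (inherits(x, "root_image")) x$pixels else x
  stopifnot(length(dim(px)) %in% c(2L, 3L))
  if (is.logical(px)) px <- px * 255
  px <- pmin(pmax(px / 255, 0), 1)
  im <- EBImage::Image(if (length(dim(px)) == 3L) aperm(px, c(2, 1, 3)) else t(px),
                       colormode = if (length(dim(px)) == 3L) "Color" else "Grayscale")
  EBImage::writeImage(im, path)
  invisible(path)
}

#' @rdname label_mask
#' @name label_mask
#' @title Connected components and hole count of a binary raster
#' @description `label_mask()` labels foreground components (labels follow
#'   raster discovery order); `count_holes()` counts background regions not
#'   connected to the image border. The pairing (8-connected foreground,
#'   4-connected background) is the digital-topology convention used
#'   throughout the package.
#' @param mask logical matrix.
#' @param conn 4 or 8 connectivity.
#' @return `label_mask()`: integer matrix of labels (0 = background);
#'   `count_holes()`: integer count.
#' @export
label_mask <- function(mask, conn = 8L) {
  stopifnot(is.logical(mask), conn %in% c(4L, 8L))
  label_components_cpp(mask, as.integer(conn))
}

#' @rdname label_mask
#' @export
count_holes <- function(mask) {
  bg <- !mask
  lab <- label_components_cpp(bg, 4L)
  if (max(lab) == 0L) return(0L)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  length(setdiff(seq_len(max(lab)), border))
}

# Clamp a numeric raster into [lo, hi]
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Gaussian blur on a [row, col] matrix via EBImage (sigma in px; 0 = no-op)
gaussian_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  t(EBImage::imageData(EBImage::gblur(EBImage::Image(t(x)), sigma = sigma)))
}
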