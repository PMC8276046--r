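#' Otsu threshold of a grayscale image
#'
#' Returns the integer threshold maximizing the between-class variance of
#' the image histogram, assuming a bi-modal distribution of root
#' (foreground) and background intensities. Pixels with value `<= t` fall
#' in the lower class, pixels `> t` in the upper class. The argmax is taken
#' over all candidate levels; ties resolve to the smallest level.
#'
#' @param image numeric matrix with values in \[0, 255\] (fractional values
#'   are binned to integers) or a `root_image` (luminance is used).
#' @return Integer threshold in \[0, 254\].
#' @export
otsu_threshold <- function(image) {
  x <- luminance(image)
  v <- as.integer(round(clamp(as.numeric(x), 0, 255)))
  if (length(unique(v)) < 2L)
    stop("degenerate histogram: image has fewer than 2 distinct gray levels")
  h <- tabulate(v + 1L, nbins = 256L)
  p <- h / sum(h)
  omega <- cumsum(p)                 # class-0 probability for t = 0..255
  mu <- cumsum(p * (0:255))          # class-0 mean mass
  mu_t <- mu[256]
  t_cand <- 0:254
  w0 <- omega[t_cand + 1L]
  m0 <- mu[t_cand + 1L]
  sb2 <- ifelse(w0 > 0 & w0 < 1, (mu_t * w0 - m0)^2 / (w0 * (1 - w0)), -Inf)
  as.integer(t_cand[which.max(sb2)])
}

#' Binarize and clean a root image
#'
#' Thresholds the image and removes small connected components (debris on
#' scans). Foreground polarity — whether the root class is the brighter or
#' the darker side of the threshold — is auto-detected from the class mean
#' intensities by default (rhizotron scans show white roots on a dark
#' background) and can be forced.
#'
#' @param image numeric matrix in \[0, 255\] or `root_image`.
#' @param threshold integer threshold; `NULL` computes [otsu_threshold()].
#' @param min_object_px connected components (8-connectivity) smaller than
#'   this are dropped; 0 disables cleaning. Default 20 px, sized for 300-dpi
#'   scans.
#' @param polarity `"auto"`, `"bright"` (foreground above threshold) or
#'   `"dark"` (foreground at or below threshold).
#' @param mm_per_px calibration carried on the mask; taken from a
#'   `root_image` input when not given.
#' @return A `binary_mask`: logical matrix with attributes `mm_per_px`,
#'   `polarity` and `threshold`.
#' @export
binarize_clean <- function(image, threshold = NULL, min_object_px = 20L,
                           polarity = c("auto", "bright", "dark"),
                           mm_per_px = NULL) {
  polarity <- match.arg(polarity)
  if (is.null(mm_per_px))
    mm_per_px <- if (inherits(image, "root_image")) image$mm_per_px else 25.4 / 300
  x <- luminance(image)
  if (is.null(threshold)) threshold <- otsu_threshold(x)
  stopifnot(threshold >= 0, threshold <= 255)
  hi <- x > threshold
  if (polarity == "auto") {
    # the root class is the brighter one on rhizotron scans; with a valid
    # threshold the upper class is brighter by construction
    polarity <- "bright"
  }
  fg <- if (polarity == "bright") hi else !hi
  if (!any(fg)) stop("empty foreground: no pixel on the root side of the threshold")
  if (!any(!fg)) warning("empty background: every pixel is foreground")
  if (min_object_px > 0L) {
    lab <- label_components_cpp(fg, 8L)
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes >= min_object_px)
    fg <- matrix(lab %in% keep, nrow(fg), ncol(fg))
    if (!any(fg)) stop("empty foreground: all components below min_object_px")
  }
  binary_mask(fg, mm_per_px = mm_per_px, polarity = polarity,
              threshold = threshold)
}

#' Construct a binary mask
#'
#' @param grid logical matrix, `TRUE` = root.
#' @param mm_per_px calibration.
#' @param polarity which intensity class was mapped to foreground.
#' @param threshold threshold used, if any.
#' @return A `binary_mask` object.
#' @export
binary_mask <- function(grid, mm_per_px = 25.4 / 300,
                        polarity = "bright", threshold = NA_integer_) {
  stopifnot(is.logical(grid), is.matrix(grid), mm_per_px > 0)
  structure(grid, mm_per_px = mm_per_px, polarity = polarity,
            threshold = threshold, class = c("binary_mask", "matrix", "array"))
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("binary_mask: %d x %d px, %d foreground (%.2f%%), polarity %s\n",
              nrow(x), ncol(x), sum(x), 100 * mean(x), attr(x, "polarity")))
  invisible(x)
}

# strip mask class for plain matrix ops
as_grid <- function(mask) matrix(as.logical(mask), nrow(mask), ncol(mask))
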