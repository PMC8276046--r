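# Shared fixtures and independent oracles. Rendered fixtures and pipeline
# results are cached per session: several test files (and the acceptance
# suite) score the same twelve specs.

.fixture_cache <- new.env(parent = emptyenv())

get_fixture <- function(name) {
  if (is.null(.fixture_cache[[name]]))
    .fixture_cache[[name]] <- render_root(fixture_specs(name)[[1]])
  .fixture_cache[[name]]
}

get_pipeline <- function(name) {
  key <- paste0("pipe_", name)
  if (is.null(.fixture_cache[[key]])) {
    fx <- get_fixture(name)
    .fixture_cache[[key]] <- run_pipeline(fx$image, pipeline_config())
  }
  .fixture_cache[[key]]
}

# fixtures whose laterals are well separated along the trunk
WELL_SEPARATED <- c("sparse_lateral", "dense_lateral", "curved_trunk",
                    "steep_lateral", "nodule_multi", "noisy_mild",
                    "wide_taper")

NOISELESS <- c("no_lateral_straight", "no_lateral_curved", "sparse_lateral",
               "dense_lateral", "curved_trunk", "steep_lateral",
               "nodule_single", "nodule_multi", "two_root", "wide_taper")

# 1-px dilation of a pixel set given as a data.frame/matrix of (row, col)
dilate_points <- function(pts, nr, nc) {
  m <- matrix(FALSE, nr, nc)
  for (dr in -1:1) for (dc in -1:1)
    m[cbind(pmin(pmax(pts[[1]] + dr, 1), nr),
            pmin(pmax(pts[[2]] + dc, 1), nc))] <- TRUE
  m
}

dilate_mask <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  dilate_points(list(idx[, 1], idx[, 2]), nrow(mask), ncol(mask))
}

# Independent Otsu oracle: exhaustive search of the between-class variance
# over all 255 split points, computed directly from the pixel values
otsu_bruteforce <- function(values) {
  v <- as.integer(round(values))
  best_t <- NA_integer_; best_v <- -Inf
  for (t in 0:254) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(v)
    sb2 <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (sb2 > best_v + 1e-12) { best_v <- sb2; best_t <- t }
  }
  best_t
}

# Independent change-count oracle: count maximal cyclic runs of active
# neighbours by direct enumeration; C = 2 * runs
run_count_oracle <- function(p) {
  p <- as.logical(p)
  if (!any(p)) return(0L)
  if (all(p)) return(0L)
  # rotate so position 1 is inactive, then count rising edges
  k <- which(!p)[1]
  q <- p[c(k:8, seq_len(k - 1))]
  runs <- sum(diff(c(FALSE, q)) == 1)
  2L * runs
}

# Random blob mask used by the skeleton topology tests
random_blob_mask <- function(seed, nr = 64L, nc = 64L) {
  set.seed(seed)
  m <- matrix(FALSE, nr, nc)
  n_disc <- sample(3:8, 1)
  m <- rootascent:::stamp_discs_cpp(m, runif(n_disc, 8, nr - 9), runif(n_disc, 8, nc - 9),
                       runif(n_disc, 2, 7))
  # occasionally punch a hole to exercise hole preservation
  if (runif(1) < 0.5) {
    idx <- which(m, arr.ind = TRUE)
    if (nrow(idx) > 30) {
      c0 <- idx[sample(nrow(idx), 1), ]
      hole <- (row(m) - c0[1])^2 + (col(m) - c0[2])^2 <= 4
      m[hole] <- FALSE
    }
  }
  m
}

# Draw an 8-connected digital line between two points (for hand-built
# skeletons in tracing tests)
digital_line <- function(r0, c0, r1, c1) {
  n <- max(abs(r1 - r0), abs(c1 - c0)) + 1L
  cbind(row = round(seq(r0, r1, length.out = n)),
        col = round(seq(c0, c1, length.out = n)))
}
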