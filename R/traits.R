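# Geodesic length of an ordered pixel chain: 1 per direct step, sqrt(2)
# per diagonal step
geodesic_length <- function(rows, cols) {
  if (length(rows) < 2L) return(0)
  dr <- abs(diff(rows)); dc <- abs(diff(cols))
  sum(ifelse(dr == 1L & dc == 1L, sqrt(2), 1) * (dr | dc))
}

# Chord-subsampled length of an ordered pixel chain: Euclidean distance
# between every k-th pixel, plus the tail segment. Unbiased estimate of the
# underlying smooth curve's length (the raw (1, sqrt(2)) step sum
# overestimates slanted curves by up to ~8%); exact on straight and 45
# degree digital lines.
chord_length <- function(rows, cols, k = 4L) {
  n <- length(rows)
  if (n < 2L) return(0)
  i <- unique(c(seq(1L, n, by = k), n))
  sum(sqrt(diff(rows[i])^2 + diff(cols[i])^2))
}

#' Primary traits of one adventitious root
#'
#' ARL (adventitious root length), the DIA (local diameter) summaries, the
#' projected root area and the unbranched apical zone length. Path lengths
#' use a chord-subsampled estimator (Euclidean distance between every 4th
#' path pixel), which is free of the slant bias of raw per-step counting;
#' the `pixel_count` flag reproduces plain pixel counting instead.
#'
#' @param path an `adventitious_path`.
#' @param diameter diameter profile from [reconstruct_root()] (data.frame
#'   with `d_px`, `d_mm` ordered from the root tip upwards).
#' @param mask the full `binary_mask` of the image (projected area).
#' @param profile the `radius_profile` carrying detected peaks (for the
#'   unbranched apical zone); optional.
#' @param mm_per_px calibration; defaults to the mask's.
#' @param apical_k number of tip-side positions averaged for the apical
#'   diameter (default 20).
#' @param pixel_count if `TRUE`, ARL is the raw pixel count of the path.
#' @return One-row data.frame: `arl_mm`, `dia_mean_mm`, `dia_apical_mm`,
#'   `projected_area_mm2`, `unbranched_apical_mm`.
#' @export
main_traits <- function(path, diameter, mask, profile = NULL,
                        mm_per_px = NULL, apical_k = 20L,
                        pixel_count = FALSE) {
  if (is.null(mm_per_px))
    mm_per_px <- if (inherits(mask, "binary_mask"))
      attr(mask, "mm_per_px") else 25.4 / 300
  arl_px <- if (pixel_count) nrow(path)
  else chord_length(path$row, path$col)
  k <- min(apical_k, nrow(diameter))
  apical <- mean(diameter$d_px[seq_len(k)])   # path starts at the tip
  unbranched_px <- arl_px
  if (!is.null(profile) && !is.null(attr(profile, "peaks"))) {
    pk <- attr(profile, "peaks")
    lat <- pk[pk$klass == "lateral", , drop = FALSE]
    if (nrow(lat)) {
      first <- min(lat$start)
      unbranched_px <- chord_length(path$row[seq_len(first)],
                                    path$col[seq_len(first)])
    }
  }
  data.frame(arl_mm = arl_px * mm_per_px,
             dia_mean_mm = mean(diameter$d_px) * mm_per_px,
             dia_apical_mm = apical * mm_per_px,
             projected_area_mm2 = sum(as_grid(mask)) * mm_per_px^2,
             unbranched_apical_mm = unbranched_px * mm_per_px)
}

#' Lateral-root and nodule traits
#'
#' Lateral skeletons are the 8-connected components of (skeleton minus path
#' pixels) that touch the path; their lengths are tip-to-attachment
#' geodesics. LRN is the number of such components at least `min_lateral_px`
#' long (short spurs left by thinning are not laterals); LLRL the longest
#' lateral root length. Nodule counts (TNN, and PNN on the primary root)
#' come from nodule-class radius peaks, with peaks facing each other on
#' opposite sides merged into one nodule.
#'
#' @param graph `skeleton_graph` of the full root system.
#' @param path the traced `adventitious_path`.
#' @param profile `radius_profile` after [detect_classify_peaks()].
#' @param mm_per_px calibration.
#' @param min_lateral_px minimum lateral skeleton length (default 10 px).
#' @return List with `lrn`, `llrl_mm`, `tnn`, `pnn`, and `laterals`
#'   (data.frame: component id, attach position, length_mm, matched peak
#'   side if any).
#' @export
lateral_traits <- function(graph, path, profile = NULL,
                           mm_per_px = 25.4 / 300, min_lateral_px = 10) {
  g <- graph$raster
  resid <- g
  resid[cbind(path$row, path$col)] <- FALSE
  lab <- label_components_cpp(resid, 8L)
  n <- max(lab)
  path_key <- (path$col - 1L) * nrow(g) + path$row
  lats <- NULL
  if (n > 0L) {
    for (id in seq_len(n)) {
      px <- which(lab == id, arr.ind = TRUE)
      # attachment: component pixel 8-adjacent to a path pixel
      attach_pos <- NA_integer_
      for (i in seq_len(nrow(px))) {
        nb_r <- px[i, 1] + P_OFFSETS[, 1]; nb_c <- px[i, 2] + P_OFFSETS[, 2]
        k <- (nb_c - 1L) * nrow(g) + nb_r
        hit <- match(k, path_key)
        hit <- hit[!is.na(hit)]
        if (length(hit)) { attach_pos <- min(hit); break }
      }
      if (is.na(attach_pos)) next
      len_px <- component_length(px)
      if (len_px < min_lateral_px) next
      lats <- rbind(lats, data.frame(component = id,
                                     attach_position = attach_pos,
                                     length_px = len_px,
                                     length_mm = len_px * mm_per_px))
    }
  }
  lrn <- if (is.null(lats)) 0L else nrow(lats)
  llrl_mm <- if (lrn > 0L) max(lats$length_mm) else 0
  tnn <- 0L
  if (!is.null(profile) && !is.null(attr(profile, "peaks"))) {
    pk <- attr(profile, "peaks")
    nod <- pk[pk$klass == "nodule", , drop = FALSE]
    if (nrow(nod)) {
      # merge left/right peaks whose spans overlap: one physical nodule
      nod <- nod[order(nod$start), , drop = FALSE]
      groups <- 1L
      if (nrow(nod) > 1L)
        groups <- cumsum(c(1L, nod$start[-1] > cummax(nod$end)[-nrow(nod)]))
      tnn <- length(unique(groups))
    }
    if (lrn > 0L) {
      lat_pk <- pk[pk$klass == "lateral", , drop = FALSE]
      lats$matched_peak <- vapply(lats$attach_position, function(p) {
        if (!nrow(lat_pk)) return(NA_character_)
        j <- which(lat_pk$start - 15 <= p & lat_pk$end + 15 >= p)
        if (length(j)) lat_pk$side[j[1]] else NA_character_
      }, "")
    }
  }
  list(lrn = lrn, llrl_mm = llrl_mm, tnn = tnn, pnn = tnn, laterals = lats)
}

# Length of a (possibly branched) skeleton component: longest geodesic
# between any two of its pixels (double BFS over the pixel adjacency graph).
# Default weights are Kulpa's bias-corrected step lengths (0.948 direct,
# 1.343 diagonal), near-unbiased for digital straight lines at any angle;
# pass c(1, sqrt(2)) for the raw step geodesic.
component_length <- function(px, weights = c(0.948, 1.343)) {
  n <- nrow(px)
  if (n < 2L) return(0)
  key <- paste(px[, 1], px[, 2])
  idx <- seq_len(n)
  names(idx) <- key
  adj <- vector("list", n)
  for (i in idx) {
    nb <- cbind(px[i, 1] + P_OFFSETS[, 1], px[i, 2] + P_OFFSETS[, 2])
    j <- idx[paste(nb[, 1], nb[, 2])]
    j <- j[!is.na(j)]
    adj[[i]] <- j
  }
  bfs_far <- function(s) {
    dist <- rep(Inf, n); dist[s] <- 0
    frontier <- s
    while (length(frontier)) {
      nxt <- integer()
      for (u in frontier) {
        for (v in adj[[u]]) {
          w <- if (abs(px[u, 1] - px[v, 1]) + abs(px[u, 2] - px[v, 2]) == 2L)
            weights[2] else weights[1]
          if (dist[u] + w < dist[v] - 1e-9) { dist[v] <- dist[u] + w
            nxt <- c(nxt, v) }
        }
      }
      frontier <- unique(nxt)
    }
    list(far = which.max(ifelse(is.finite(dist), dist, -1)),
         d = max(dist[is.finite(dist)]))
  }
  a <- bfs_far(1L)
  bfs_far(a$far)$d
}

#' Trait time series across acquisitions
#'
#' Orders per-image trait records by timestamp, computes inter-timepoint
#' ratios of the projected area (growth factors), and flags timepoints
#' missing from the regular acquisition grid. Missing values are never
#' interpolated; ratios skip flagged rows.
#'
#' @param records data.frame with a `timestamp` column (numeric or
#'   orderable) and trait columns, one row per acquisition, or a list of
#'   such rows.
#' @return Data.frame ordered by timestamp with `missing` flag and
#'   `area_ratio` (projected area relative to the previous present
#'   timepoint; NA for the first).
#' @export
growth_series <- function(records) {
  if (is.list(records) && !is.data.frame(records))
    records <- do.call(rbind, lapply(records, as.data.frame))
  stopifnot(nrow(records) >= 1L, "timestamp" %in% names(records))
  ts <- records$timestamp
  if (anyNA(ts) || (!is.numeric(ts) && anyNA(suppressWarnings(as.numeric(ts)))))
    stop("unsorted timestamps: labels are not orderable")
  ts <- as.numeric(ts)
  records <- records[order(ts), , drop = FALSE]
  ts <- sort(ts)
  out <- records
  out$missing <- FALSE
  if (length(ts) > 2L) {
    step <- min(diff(ts))
    grid <- seq(ts[1], ts[length(ts)], by = step)
    absent <- grid[!vapply(grid, function(g) any(abs(ts - g) < step / 2), TRUE)]
    if (length(absent)) {
      pad <- out[rep(1L, length(absent)), , drop = FALSE]
      pad[] <- NA
      pad$timestamp <- absent
      pad$missing <- TRUE
      out <- rbind(out, pad)
      out <- out[order(out$timestamp), , drop = FALSE]
    }
  }
  out$area_ratio <- NA_real_
  if ("projected_area_mm2" %in% names(out)) {
    present <- which(!out$missing)
    if (length(present) > 1L)
      out$area_ratio[present[-1]] <-
        out$projected_area_mm2[present[-1]] /
        out$projected_area_mm2[present[-length(present)]]
  }
  rownames(out) <- NULL
  out
}
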