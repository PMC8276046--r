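# Neighbour ordering used by the change-count rule: P1..P8 walk the
# 8-neighbourhood clockwise starting at the upper-left diagonal, so the
# direct neighbours are P2 (N), P4 (E), P6 (S), P8 (W) and the diagonals
# P1 (NW), P3 (NE), P5 (SE), P7 (SW). Offsets as (dr, dc), row 1 at top.
P_OFFSETS <- matrix(c(-1, -1,   # P1 NW
                      -1,  0,   # P2 N
                      -1,  1,   # P3 NE
                       0,  1,   # P4 E
                       1,  1,   # P5 SE
                       1,  0,   # P6 S
                       1, -1,   # P7 SW
                       0, -1),  # P8 W
                    ncol = 2, byrow = TRUE)

#' Skeletonize a binary mask by homotopic thinning
#'
#' Iteratively erodes the boundary of the foreground, at each step deleting
#' only pixels whose removal leaves the topology unchanged (simple points),
#' until the object is one pixel wide. Deletion runs in four directional
#' sub-iterations (north-, south-, east-, then west-border pixels) in a
#' fixed raster order, so the result is deterministic and stays centred.
#' Endpoints (single-neighbour pixels) are never deleted, so branch lengths
#' are preserved; the numbers of 8-connected foreground components and of
#' 4-connected holes are invariant.
#'
#' Boundary bumps can freeze into 1-2 px branch stubs during erosion (the
#' endpoint protection keeps them); stubs of at most `prune_px` pixels
#' ending at a junction are removed afterwards. This is an artifact
#' cleanup, far below any lateral-root length, and also a sequence of
#' simple-point deletions, so topology is still preserved.
#'
#' @param mask logical matrix or `binary_mask`.
#' @param prune_px maximum artifact stub length removed (default 2; 0
#'   disables pruning).
#' @return Logical skeleton matrix (a `binary_mask` if the input was one,
#'   calibration preserved).
#' @export
skeletonize <- function(mask, prune_px = 2L) {
  g <- as_grid(mask)
  sk <- thin_homotopic_cpp(g)
  sk <- prune_stubs(sk, prune_px)
  # stub removal can expose a newly simple corner at the old junction;
  # a second thinning pass (idempotent) restores convergence
  if (prune_px > 0L) sk <- thin_homotopic_cpp(sk)
  if (inherits(mask, "binary_mask"))
    sk <- binary_mask(sk, mm_per_px = attr(mask, "mm_per_px"),
                      polarity = attr(mask, "polarity"),
                      threshold = attr(mask, "threshold"))
  sk
}

#' Cyclic change count of an 8-neighbourhood
#'
#' Counts the 0/1 transitions Ch1..Ch8 around the cyclic neighbour sequence
#' P1 -> P2 -> ... -> P8 -> P1 (clockwise). `C` is always even and equals
#' twice the number of maximal runs of active neighbours, i.e. twice the
#' number of branches meeting at the centre pixel.
#'
#' @param neighbors logical (or 0/1) vector of length 8, ordered P1..P8 as
#'   in [classify_points()] (P1 = upper-left diagonal, clockwise).
#' @return Integer change count C in \{0, 2, 4, 6, 8\}.
#' @export
change_count <- function(neighbors) {
  p <- as.logical(neighbors)
  stopifnot(length(p) == 8L, !anyNA(p))
  sum(p != p[c(2:8, 1)])
}

#' Classify every skeleton pixel as endpoint, junction or normal point
#'
#' Applies the change-count rule to each active pixel of a 1-px skeleton:
#' `C = 0` isolated, `C = 2` endpoint (one branch; this admits tips whose
#' two active neighbours are mutually adjacent), `C = 4` normal point (a
#' line passes through), `C >= 6` junction (at least 3 branches of
#' different directions). Out-of-image neighbours count as inactive.
#'
#' @param skeleton logical matrix, 1-px-wide skeleton.
#' @return A `skeleton_graph`: list with `raster` (the input), `points`
#'   (data.frame: row, col, C, class), `class_raster` (integer matrix,
#'   0 = background, 1 = endpoint, 2 = junction, 3 = normal, 4 = isolated)
#'   and `components` (integer matrix of 8-connected component labels).
#' @export
classify_points <- function(skeleton) {
  g <- as_grid(skeleton)
  if (interior_block(g))
    stop("not a skeleton: interior 2x2 foreground block present")
  idx <- which(g, arr.ind = TRUE)
  C <- integer(nrow(idx))
  nbr_count <- integer(nrow(idx))
  pad <- matrix(FALSE, nrow(g) + 2L, ncol(g) + 2L)
  pad[2:(nrow(g) + 1L), 2:(ncol(g) + 1L)] <- g
  if (nrow(idx)) {
    nb <- matrix(FALSE, nrow(idx), 8L)
    for (k in 1:8) {
      nb[, k] <- pad[cbind(idx[, 1] + 1L + P_OFFSETS[k, 1],
                           idx[, 2] + 1L + P_OFFSETS[k, 2])]
    }
    C <- rowSums(nb != nb[, c(2:8, 1), drop = FALSE])
    nbr_count <- rowSums(nb)
  }
  cls <- ifelse(C == 0L, "isolated",
         ifelse(C == 2L, "endpoint",
         ifelse(C == 4L, "normal", "junction")))
  pts <- data.frame(row = as.integer(idx[, 1]), col = as.integer(idx[, 2]),
                    C = as.integer(C), n_neighbors = as.integer(nbr_count),
                    class = cls, stringsAsFactors = FALSE)
  cr <- matrix(0L, nrow(g), ncol(g))
  code <- c(endpoint = 1L, junction = 2L, normal = 3L, isolated = 4L)
  if (nrow(pts)) cr[cbind(pts$row, pts$col)] <- code[pts$class]
  structure(list(raster = g, points = pts, class_raster = cr,
                 components = label_components_cpp(g, 8L)),
            class = "skeleton_graph")
}

#' @export
print.skeleton_graph <- function(x, ...) {
  tab <- table(x$points$class)
  cat(sprintf("skeleton_graph: %d px, %d component(s) [%s]\n",
              nrow(x$points), max(x$components),
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  invisible(x)
}

# Remove endpoint stubs of <= prune_px pixels that terminate at a junction
# (>= 3 neighbours); longer branches and free line ends are kept
prune_stubs <- function(sk, prune_px) {
  if (prune_px <= 0L) return(sk)
  nr <- nrow(sk); nc <- ncol(sk)
  nbrs <- function(r, c) {
    rr <- r + P_OFFSETS[, 1]; cc <- c + P_OFFSETS[, 2]
    ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
    ok[ok] <- sk[cbind(rr[ok], cc[ok])]
    cbind(rr[ok], cc[ok])
  }
  idx <- which(sk, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(sk)
  ncount <- vapply(seq_len(nrow(idx)), function(i)
    nrow(nbrs(idx[i, 1], idx[i, 2])), 0L)
  for (i in which(ncount == 1L)) {
    chain <- idx[i, , drop = FALSE]
    cur <- idx[i, ]
    spur <- FALSE
    for (step in seq_len(prune_px)) {
      nb <- nbrs(cur[1], cur[2])
      nb <- nb[!(paste(nb[, 1], nb[, 2]) %in% paste(chain[, 1], chain[, 2])), ,
               drop = FALSE]
      if (nrow(nb) != 1L) break
      nxt <- nb[1, ]
      if (nrow(nbrs(nxt[1], nxt[2])) >= 3L) { spur <- TRUE; break }
      cur <- nxt
      chain <- rbind(chain, nxt)
    }
    if (spur) sk[chain] <- FALSE
  }
  sk
}

# TRUE if the raster contains a fully-foreground 2x2 block (not 1-px wide)
interior_block <- function(g) {
  if (nrow(g) < 2L || ncol(g) < 2L) return(FALSE)
  a <- g[-nrow(g), -ncol(g)] & g[-1, -ncol(g)] & g[-nrow(g), -1] & g[-1, -1]
  any(a)
}
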