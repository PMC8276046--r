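#' Anchor points of a skeleton component
#'
#' The starting point of the ascending traversal is the lowest active pixel
#' of the component (maximum row; roots grow downwards, so this is the root
#' tip) and the breakpoint is the highest (minimum row; the stem base).
#' Ties resolve to the smallest column.
#'
#' @param graph a `skeleton_graph` from [classify_points()].
#' @param component_id component label (see `graph$components`); default 1.
#' @return List with `start` and `breakpoint`, each an integer `c(row, col)`.
#' @export
find_anchors <- function(graph, component_id = 1L) {
  idx <- which(graph$components == component_id, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty component: no pixel with this label")
  lo <- idx[idx[, 1] == max(idx[, 1]), , drop = FALSE]
  hi <- idx[idx[, 1] == min(idx[, 1]), , drop = FALSE]
  list(start = as.integer(lo[which.min(lo[, 2]), ]),       # lowest, then leftmost
       breakpoint = as.integer(hi[which.min(hi[, 2]), ]))  # highest, then leftmost
}

#' Trace the ascending path through a skeleton
#'
#' Walks the skeleton from the lowest point upwards. At a normal point the
#' walk continues to the unvisited neighbour; at a junction (change count of
#' 6 or more, i.e. at least three branches) each unvisited outgoing branch is
#' probed by a lookahead of `lookahead` pixels and the branch whose probe
#' ends highest (smallest row) is taken — the "ascending" choice. Branches
#' that dead-end at an endpoint other than the breakpoint are undone by
#' depth-first backtracking to the last junction, so on tree-shaped
#' skeletons the traversal always terminates at the breakpoint and returns
#' the unique tip-to-top path: the adventitious-root skeleton, laterals
#' excluded.
#'
#' @param graph a `skeleton_graph`.
#' @param start,breakpoint integer `c(row, col)` anchors, e.g. from
#'   [find_anchors()]; both must lie in the same component.
#' @param lookahead branch-probe depth in pixels (default 15); a one-pixel
#'   decision would be sensitive to skeleton jitter.
#' @return An `adventitious_path`: data.frame with columns `order`, `row`,
#'   `col`; attributes `start`, `breakpoint`, `component_id`.
#' @export
trace_ascending <- function(graph, start, breakpoint, lookahead = 15L) {
  g <- graph$raster
  comp <- graph$components
  if (!g[start[1], start[2]] || !g[breakpoint[1], breakpoint[2]])
    stop("anchor is not an active skeleton pixel")
  if (comp[start[1], start[2]] != comp[breakpoint[1], breakpoint[2]])
    stop("start and breakpoint lie in different skeleton components")
  nr <- nrow(g); nc <- ncol(g)
  key <- function(r, c) (c - 1L) * nr + r
  neighbors <- function(r, c) {
    rr <- r + P_OFFSETS[, 1]; cc <- c + P_OFFSETS[, 2]
    ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
    ok[ok] <- g[cbind(rr[ok], cc[ok])]
    cbind(rr[ok], cc[ok])
  }
  # greedy lookahead probe: walk up to L steps without revisiting, prefer
  # ascending neighbours locally; returns the probe endpoint row/col
  probe <- function(r0, c0, banned) {
    seen <- c(banned, key(r0, c0))
    r <- r0; c <- c0
    for (i in seq_len(lookahead - 1L)) {
      nb <- neighbors(r, c)
      if (nrow(nb) == 0L) break
      k <- key(nb[, 1], nb[, 2])
      free <- !(k %in% seen)
      if (!any(free)) break
      nb <- nb[free, , drop = FALSE]
      j <- order(nb[, 1], abs(nb[, 2] - c), nb[, 2])[1]
      r <- nb[j, 1]; c <- nb[j, 2]
      seen <- c(seen, key(r, c))
    }
    c(r, c)
  }
  bp_key <- key(breakpoint[1], breakpoint[2])
  path <- matrix(c(start[1], start[2]), ncol = 2)
  visited <- key(start[1], start[2])
  # per-depth list of branch options not yet tried (for backtracking)
  pending <- list()
  repeat {
    cur <- path[nrow(path), ]
    if (key(cur[1], cur[2]) == bp_key) break
    nb <- neighbors(cur[1], cur[2])
    k <- key(nb[, 1], nb[, 2])
    free <- !(k %in% visited)
    options <- nb[free, , drop = FALSE]
    if (nrow(options) > 1L) {
      # junction: rank branches by how high their lookahead probe reaches;
      # tie-break by column deviation from the current heading, then column
      ends <- t(apply(options, 1, function(p) probe(p[1], p[2], visited)))
      heading <- cur[2]
      ord <- order(ends[, 1], abs(options[, 2] - heading), options[, 2])
      options <- options[ord, , drop = FALSE]
    }
    if (nrow(options) == 0L) {
      # dead end: backtrack to the last junction with untried branches
      repeat {
        if (length(pending) == 0L)
          stop("no ascending route: all branches exhausted before the breakpoint")
        d <- length(pending)
        alt <- pending[[d]]
        pending[[d]] <- NULL
        if (nrow(path) < 2L)
          stop("no ascending route: all branches exhausted before the breakpoint")
        path <- path[seq_len(alt$depth), , drop = FALSE]
        if (nrow(alt$options) > 0L) {
          nxt <- alt$options[1, ]
          if (nrow(alt$options) > 1L)
            pending[[length(pending) + 1L]] <-
              list(depth = alt$depth, options = alt$options[-1, , drop = FALSE])
          path <- rbind(path, nxt)
          visited <- c(visited, key(nxt[1], nxt[2]))
          break
        }
      }
    } else {
      nxt <- options[1, ]
      if (nrow(options) > 1L)
        pending[[length(pending) + 1L]] <-
          list(depth = nrow(path), options = options[-1, , drop = FALSE])
      path <- rbind(path, nxt)
      visited <- c(visited, key(nxt[1], nxt[2]))
    }
  }
  out <- data.frame(order = seq_len(nrow(path)),
                    row = as.integer(path[, 1]), col = as.integer(path[, 2]))
  structure(out, start = as.integer(start),
            breakpoint = as.integer(breakpoint),
            component_id = comp[start[1], start[2]],
            class = c("adventitious_path", "data.frame"))
}

#' Trace every adventitious root in a skeleton
#'
#' Runs [find_anchors()] + [trace_ascending()] once per 8-connected skeleton
#' component with at least `min_component_px` pixels. One adventitious root
#' per component is the operating assumption for cuttings imaged in
#' rhizotrons.
#'
#' @inheritParams trace_ascending
#' @param min_component_px components smaller than this are skipped
#'   (default 30 px; fragments and debris).
#' @return List of `adventitious_path` objects.
#' @export
trace_all_components <- function(graph, lookahead = 15L,
                                 min_component_px = 30L) {
  ncomp <- max(graph$components)
  if (ncomp == 0L) return(list())
  sizes <- tabulate(graph$components[graph$components > 0L], nbins = ncomp)
  out <- list()
  for (id in seq_len(ncomp)) {
    if (sizes[id] < min_component_px) next
    a <- find_anchors(graph, id)
    out[[length(out) + 1L]] <-
      trace_ascending(graph, a$start, a$breakpoint, lookahead = lookahead)
  }
  out
}
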