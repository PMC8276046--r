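test_that("anchors are the lowest and highest skeleton pixels", {
  m <- matrix(FALSE, 100, 20)
  m[10:90, 7] <- TRUE
  a <- find_anchors(classify_points(m))
  expect_identical(a$start, c(90L, 7L))
  expect_identical(a$breakpoint, c(10L, 7L))
  # single-pixel component degenerates to start == breakpoint
  p1 <- matrix(FALSE, 5, 5); p1[3, 3] <- TRUE
  a1 <- find_anchors(classify_points(p1))
  expect_identical(a1$start, a1$breakpoint)
  # two equally-low tips: leftmost wins
  v <- matrix(FALSE, 30, 30)
  v[cbind(20:10, 10:20)] <- TRUE   # descending to the left... tip at (20,10)
  v[cbind(10:20, 20:30)] <- TRUE   # second tip at (20,30)
  av <- find_anchors(classify_points(v))
  expect_identical(av$start, c(20L, 10L))
})

test_that("a straight vertical skeleton is traced bottom-to-top in full", {
  m <- matrix(FALSE, 60, 11)
  m[5:55, 6] <- TRUE
  g <- classify_points(m)
  a <- find_anchors(g)
  p <- trace_ascending(g, a$start, a$breakpoint)
  expect_identical(nrow(p), 51L)
  expect_identical(p$row, 55:5)
  expect_true(all(p$col == 6L))
})

test_that("a downward lateral on a Y-shaped skeleton is excluded", {
  m <- matrix(FALSE, 80, 40)
  m[10:70, 20] <- TRUE                       # trunk
  lat <- digital_line(40, 19, 60, 5)         # lateral going down-left
  lat <- lat[lat[, 2] < 20, ]
  m[lat] <- TRUE
  g <- classify_points(m)
  a <- find_anchors(g)
  p <- trace_ascending(g, a$start, a$breakpoint)
  expect_true(all(p$col == 20L))             # trunk pixels only
  expect_identical(nrow(p), 61L)
})

test_that("the path is simple and 8-connected end to end", {
  for (nm in c("dense_lateral", "curved_trunk", "nodule_multi")) {
    res <- get_pipeline(nm)
    for (p in res$paths) {
      expect_false(any(duplicated(p[, c("row", "col")])))
      steps <- cbind(abs(diff(p$row)), abs(diff(p$col)))
      expect_true(all(steps <= 1), info = nm)
      expect_true(all(rowSums(steps) >= 1), info = nm)
      expect_identical(c(p$row[1], p$col[1]), as.integer(attr(p, "start")))
      expect_identical(c(p$row[nrow(p)], p$col[nrow(p)]),
                       as.integer(attr(p, "breakpoint")))
    }
  }
})

test_that("traced paths follow the true main-root skeleton on fixtures", {
  for (nm in c("sparse_lateral", "steep_lateral", "curved_trunk")) {
    fx <- get_fixture(nm)
    res <- get_pipeline(nm)
    ts <- fx$truth$main_skeleton
    dil <- dilate_points(list(ts$row, ts$col), 400, 300)
    p <- res$paths[[1]]
    expect_gte(mean(dil[cbind(p$row, p$col)]), 0.95)
  }
})

test_that("tracing equals the shortest-path oracle on a small tree", {
  # trunk with two laterals that stay below the trunk top
  m <- matrix(FALSE, 50, 30)
  m[5:45, 15] <- TRUE
  m[digital_line(30, 16, 40, 25)] <- TRUE
  m[digital_line(20, 14, 28, 6)] <- TRUE
  g <- classify_points(m)
  a <- find_anchors(g)
  p <- trace_ascending(g, a$start, a$breakpoint)
  # oracle: BFS shortest path start -> breakpoint on the skeleton graph
  idx <- which(m, arr.ind = TRUE)
  key <- paste(idx[, 1], idx[, 2])
  prev <- setNames(rep(NA_character_, nrow(idx)), key)
  q <- paste(a$start[1], a$start[2])
  prev[q] <- q
  while (length(q)) {
    nq <- character()
    for (u in q) {
      uc <- as.integer(strsplit(u, " ")[[1]])
      for (k in 1:8) {
        vkey <- paste(uc[1] + rootascent:::P_OFFSETS[k, 1],
                      uc[2] + rootascent:::P_OFFSETS[k, 2])
        if (!is.na(match(vkey, key)) && is.na(prev[vkey])) {
          prev[vkey] <- u
          nq <- c(nq, vkey)
        }
      }
    }
    q <- nq
  }
  node <- paste(a$breakpoint[1], a$breakpoint[2])
  oracle <- character()
  while (node != paste(a$start[1], a$start[2])) {
    oracle <- c(oracle, node)
    node <- prev[[node]]
  }
  oracle <- c(oracle, node)
  oracle <- rev(oracle)
  # the geodesic is unique up to corner cuts where a branch pixel is
  # diagonally adjacent to two consecutive trunk pixels: compare within a
  # 1-px tolerance and require matching endpoints and length
  omat <- do.call(rbind, lapply(strsplit(oracle, " "), as.integer))
  dil <- dilate_points(list(omat[, 1], omat[, 2]), nrow(m), ncol(m))
  expect_true(all(dil[cbind(p$row, p$col)]))
  expect_lte(abs(nrow(p) - length(oracle)), 2)
  expect_identical(paste(p$row, p$col)[1], oracle[1])
  expect_identical(paste(p$row, p$col)[nrow(p)], oracle[length(oracle)])
})

test_that("an ascending dead-end branch triggers backtracking", {
  m <- matrix(FALSE, 60, 40)
  m[30:50, 10] <- TRUE                     # lower trunk
  m[30, 10:16] <- TRUE                     # trunk jogs sideways...
  m[10:30, 16] <- TRUE                     # ...then resumes upwards
  m[digital_line(29, 9, 18, 4)] <- TRUE    # ascending decoy that dead-ends
  g <- classify_points(m)
  a <- find_anchors(g)
  expect_identical(a$breakpoint, c(10L, 16L))
  p <- trace_ascending(g, a$start, a$breakpoint)
  expect_identical(c(p$row[nrow(p)], p$col[nrow(p)]),
                   as.integer(a$breakpoint))
  expect_false(any(p$col < 9))             # decoy abandoned
})

test_that("per-component tracing finds both roots of a two-root image", {
  res <- get_pipeline("two_root")
  expect_identical(length(res$paths), 2L)
  cols <- vapply(res$paths, function(p) mean(p$col), 0)
  expect_identical(length(unique(round(cols, -1))), 2L)
})
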