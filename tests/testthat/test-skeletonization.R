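test_that("change count matches the cyclic run-count oracle on all 256 configs", {
  for (cfg in 0:255) {
    p <- as.logical(bitwAnd(cfg, 2^(0:7)))
    expect_identical(as.integer(change_count(p)),
                     as.integer(run_count_oracle(p)),
                     info = paste("config", cfg))
  }
})

test_that("change count on canonical neighbourhoods", {
  only_p2 <- c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE)
  expect_identical(change_count(only_p2), 2L)        # one neighbour: one run
  expect_identical(change_count(rep(FALSE, 8)), 0L)  # no transitions
  expect_identical(change_count(rep(TRUE, 8)), 0L)
  line_ns <- c(FALSE, TRUE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE)
  expect_identical(change_count(line_ns), 4L)        # two opposite branches
})

test_that("point classes follow the change-count rule", {
  # T-junction: vertical line with an east branch from the centre
  m <- matrix(FALSE, 9, 9)
  m[3:7, 5] <- TRUE
  m[5, 5:8] <- TRUE
  g <- classify_points(m)
  cls <- function(r, c) g$points$class[g$points$row == r & g$points$col == c]
  expect_identical(cls(5, 5), "junction")
  expect_identical(g$points$C[g$points$row == 5 & g$points$col == 5], 6L)
  expect_identical(cls(3, 5), "endpoint")
  expect_identical(cls(4, 5), "normal")
  # X-cross centre has C = 8
  x <- matrix(FALSE, 9, 9)
  for (k in -3:3) { x[5 + k, 5 + k] <- TRUE; x[5 + k, 5 - k] <- TRUE }
  gx <- classify_points(x)
  expect_identical(gx$points$C[gx$points$row == 5 & gx$points$col == 5], 8L)
  expect_identical(gx$points$class[gx$points$row == 5 & gx$points$col == 5],
                   "junction")
  # lone pixel
  iso <- matrix(FALSE, 3, 3); iso[2, 2] <- TRUE
  expect_identical(classify_points(iso)$points$class, "isolated")
})

test_that("classification rejects non-skeletons and is deterministic", {
  blob <- matrix(FALSE, 5, 5); blob[2:3, 2:3] <- TRUE
  expect_error(classify_points(blob), "not a skeleton")
  sk <- skeletonize(random_blob_mask(11))
  expect_identical(classify_points(sk)$points, classify_points(sk)$points)
})

test_that("a 1-px line is already thin and survives unchanged", {
  m <- matrix(FALSE, 30, 9)
  m[3:28, 5] <- TRUE
  expect_identical(skeletonize(m), m)
})

test_that("a filled rectangle thins to its central column", {
  m <- matrix(FALSE, 60, 15)
  m[5:55, 6:10] <- TRUE   # 51 x 5 vertical rectangle
  sk <- skeletonize(m)
  idx <- which(sk, arr.ind = TRUE)
  expect_true(all(abs(idx[, 2] - 8) <= 1))   # within 1 px of centre col
  expect_gte(nrow(idx), 47)                  # end effects only
})

test_that("thinning preserves components and holes on random masks", {
  for (seed in 1:50) {
    m <- random_blob_mask(seed)
    sk <- skeletonize(m)
    expect_true(all(m[sk]))                  # skeleton subset of mask
    expect_identical(max(label_mask(sk, 8L)), max(label_mask(m, 8L)),
                     info = paste("components, seed", seed))
    expect_identical(count_holes(sk), count_holes(m),
                     info = paste("holes, seed", seed))
    # converged: no deletable simple point remains
    expect_false(any(rootascent:::simple_points_cpp(sk)),
                 info = paste("simplicity, seed", seed))
  }
})

test_that("components have endpoints unless they are closed loops", {
  # tree-shaped skeleton: trunk plus two branches
  tree <- matrix(FALSE, 40, 40)
  tree[cbind(5:35, 20)] <- TRUE
  tree[cbind(15:20, 21:26)] <- TRUE
  tree[cbind(25:30, 19:14)] <- TRUE
  gt <- classify_points(tree)
  expect_gte(sum(gt$points$class == "endpoint"), 3L)
  # ring: annulus thinned to a loop has no endpoints
  ring <- (row(matrix(0, 41, 41)) - 21)^2 + (col(matrix(0, 41, 41)) - 21)^2
  ring <- ring <= 15^2 & ring >= 9^2
  gr <- classify_points(skeletonize(ring))
  expect_identical(sum(gr$points$class == "endpoint"), 0L)
  expect_true(all(gr$points$class %in% c("normal", "junction")))
})

test_that("sum of C/2 equals the total neighbour-run count on skeletons", {
  for (seed in c(3, 14, 27)) {
    g <- classify_points(skeletonize(random_blob_mask(seed)))
    runs <- vapply(seq_len(nrow(g$points)), function(i) {
      r <- g$points$row[i]; c <- g$points$col[i]
      pad <- matrix(FALSE, nrow(g$raster) + 2, ncol(g$raster) + 2)
      pad[2:(nrow(g$raster) + 1), 2:(ncol(g$raster) + 1)] <- g$raster
      nb <- pad[cbind(r + 1 + rootascent:::P_OFFSETS[, 1],
                      c + 1 + rootascent:::P_OFFSETS[, 2])]
      run_count_oracle(nb) / 2
    }, 0)
    expect_equal(sum(g$points$C) / 2, sum(runs))
  }
})
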