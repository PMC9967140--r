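checkerboard <- function(n, legend = c(a = 1L, b = 2L)) {
  land_raster(matrix(ifelse((row(diag(n)) + col(diag(n))) %% 2 == 0,
                            1L, 2L), n, n),
              legend = legend)
}

test_that("patch labeling follows the connectivity rule", {
  solid <- land_raster(matrix(1L, 5, 5), legend = c(a = 1L))
  expect_equal(nrow(label_patches(solid)$patches), 1L)

  cb <- checkerboard(4)
  expect_equal(nrow(label_patches(cb, connectivity = 4)$patches), 16L)
  expect_equal(nrow(label_patches(cb, connectivity = 8)$patches), 2L)
})

test_that("patch labeling agrees with the flood-fill oracle", {
  for (seed in 1:15) {
    set.seed(seed)
    nr <- sample(3:10, 1); nc <- sample(3:10, 1)
    r <- random_land(nr, nc, k = 3, seed = seed + 40)
    for (conn in c(4, 8)) {
      pl <- label_patches(r, conn)
      olab <- oracle_patches(r$codes, conn)
      # same partition: bijection between label sets
      expect_equal(length(unique(olab[!is.na(olab)])), nrow(pl$patches))
      expect_equal(length(unique(paste(pl$labels, olab))),
                   nrow(pl$patches))
    }
  }
})

test_that("class metrics hit their closed-form anchors", {
  solid <- land_raster(matrix(1L, 6, 6), legend = c(a = 1L, b = 2L))
  cm <- class_metrics(label_patches(solid))
  expect_equal(cm$np, 1L)
  expect_equal(cm$lpi, 100)
  expect_equal(cm$ai, 100)
  expect_equal(cm$lsi, 1)

  cb <- checkerboard(4)
  cmcb <- class_metrics(label_patches(cb, connectivity = 4))
  expect_equal(cmcb$ai, c(0, 0))

  strip <- land_raster(matrix(1L, 1, 9), legend = c(a = 1L))
  block <- land_raster(matrix(1L, 3, 3), legend = c(a = 1L))
  lsi_strip <- class_metrics(label_patches(strip))$lsi
  lsi_block <- class_metrics(label_patches(block))$lsi
  expect_equal(lsi_strip, 20 / 12)
  expect_equal(lsi_block, 1)
  expect_gt(lsi_strip, lsi_block)
})

test_that("landscape metrics hit their closed-form anchors", {
  solid <- land_raster(matrix(1L, 6, 6), legend = c(a = 1L, b = 2L))
  lm1 <- landscape_metrics(label_patches(solid))
  expect_equal(lm1$shdi, 0)
  expect_equal(lm1$split, 1)
  expect_true(is.na(lm1$contag))

  # two equal patches tiling the landscape
  half <- land_raster(rbind(matrix(1L, 3, 6), matrix(2L, 3, 6)),
                      legend = c(a = 1L, b = 2L))
  lm2 <- landscape_metrics(label_patches(half))
  expect_equal(lm2$split, 2)
  expect_equal(lm2$shdi, log(2))
})

test_that("SHDI is maximal iff proportions are equal, invariant to labels", {
  half <- land_raster(rbind(matrix(1L, 4, 8), matrix(2L, 4, 8)),
                      legend = c(a = 1L, b = 2L))
  skew <- land_raster(rbind(matrix(1L, 1, 8), matrix(2L, 7, 8)),
                      legend = c(a = 1L, b = 2L))
  expect_equal(landscape_metrics(label_patches(half))$shdi, log(2))
  expect_lt(landscape_metrics(label_patches(skew))$shdi, log(2))
  swap <- land_raster(3L - half$codes, legend = c(a = 1L, b = 2L))
  expect_equal(landscape_metrics(label_patches(swap))$shdi, log(2))
})

test_that("CONTAG decreases as like-adjacency is progressively broken up", {
  # two halves -> width-2 stripes -> width-1 stripes: the like/unlike
  # adjacency mix moves monotonically toward uniform, so CONTAG falls.
  # (A checkerboard is NOT the minimum: with all adjacencies unlike the
  # adjacency distribution is again far from uniform.)
  n <- 8
  leg <- c(a = 1L, b = 2L)
  halves <- land_raster(rbind(matrix(1L, n / 2, n), matrix(2L, n / 2, n)),
                        legend = leg)
  stripes2 <- land_raster(matrix(rep(rep(c(1L, 2L), each = 2 * n),
                                     length.out = n * n), n, n),
                          legend = leg)
  stripes1 <- land_raster(matrix(rep(c(1L, 2L), each = n,
                                     length.out = n * n), n, n),
                          legend = leg)
  c1 <- landscape_metrics(label_patches(halves))$contag
  c2 <- landscape_metrics(label_patches(stripes2))$contag
  c3 <- landscape_metrics(label_patches(stripes1))$contag
  expect_gt(c1, c2)
  expect_gt(c2, c3)
  # a dominant, fully self-adjacent class pushes CONTAG toward 100
  dom <- matrix(1L, 12, 12); dom[1, 1] <- 2L
  c_dom <- landscape_metrics(label_patches(land_raster(dom,
                                                       legend = leg)))$contag
  expect_gt(c_dom, 90)
})

test_that("a bridging cell cannot decrease AI or increase NP", {
  # count of rook neighbours of class `cl` for every cell
  rook_like <- function(codes, cl) {
    nr <- nrow(codes); nc <- ncol(codes)
    ind <- (codes == cl) * 1
    up <- rbind(ind[-1, , drop = FALSE], 0)
    dn <- rbind(0, ind[-nr, , drop = FALSE])
    lf <- cbind(0, ind[, -nc, drop = FALSE])
    rt <- cbind(ind[, -1, drop = FALSE], 0)
    up + dn + lf + rt
  }
  tested <- 0
  for (seed in 1:12) {
    r <- random_land(8, 8, k = 2, seed = seed + 300)
    cls1 <- class_metrics(label_patches(r))
    flip <- which(r$codes == 2L & rook_like(r$codes, 1L) >= 2)
    if (!length(flip)) next
    tested <- tested + 1
    r2codes <- r$codes
    r2codes[flip[1]] <- 1L
    r2 <- land_raster(r2codes, r$spec, r$legend)
    cls2 <- class_metrics(label_patches(r2))
    expect_lte(cls2$np[cls2$code == 1], cls1$np[cls1$code == 1])
    expect_gte(cls2$ai[cls2$code == 1], cls1$ai[cls1$code == 1])
  }
  expect_gt(tested, 5)
})

test_that("all metrics equal the definitional oracle on random grids", {
  for (seed in 1:25) {
    set.seed(seed)
    nr <- sample(4:10, 1); nc <- sample(4:10, 1)
    k <- sample(2:4, 1)
    r <- random_land(nr, nc, k = k, seed = seed + 900)
    pl <- label_patches(r)
    o <- oracle_metrics(r)
    cm <- class_metrics(pl)
    expect_equal(cm$np, o$class$np)
    expect_equal(cm$lpi, o$class$lpi, tolerance = 1e-12)
    expect_equal(cm$lsi, o$class$lsi, tolerance = 1e-12)
    expect_equal(cm$ai, o$class$ai, tolerance = 1e-12)
    lm <- landscape_metrics(pl)
    expect_equal(as.numeric(lm), as.numeric(o$landscape),
                 tolerance = 1e-12)
  }
})
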