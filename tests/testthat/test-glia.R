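test_that("percent stained area handles half-planes, blanks and constants", {
  plane <- matrix(900, 40, 40)
  plane[, 1:20] <- 4000
  st <- array(plane, dim = c(40, 40, 5))
  res <- stained_area_fraction(st, n_planes = 5)
  expect_equal(res$mean_percent, 50)
  expect_true(all(res$per_plane$percent == 50))
  # all-zero planes follow the explicit zero-foreground rule
  res0 <- stained_area_fraction(array(0, dim = c(10, 10, 5)))
  expect_equal(res0$mean_percent, 0)
  # nonzero constant plane is missing, with a warning
  stc <- array(c(rep(500, 100), rep(c(900, 4000), 50)), dim = c(10, 10, 2))
  expect_warning(resc <- stained_area_fraction(stc, planes = 1:2),
                 "constant")
  expect_true(is.na(resc$per_plane$percent[1]))
  expect_error(stained_area_fraction(array(1:8, c(2, 2, 2)), n_planes = 5),
               "fewer")
})

test_that("stained area recovers the designed cell area of the generator", {
  spec <- slice_spec(image_shape = c(400L, 400L), pixel_size = 1,
                     lesion_center = c(200, 200), cell_count = 40L,
                     n_z = 5L, seed = 77)
  sim <- simulate_cell_channel(spec)
  truth_pct <- 100 * sum(sim$binary_truth) / prod(dim(sim$binary_truth))
  res <- stained_area_fraction(sim$image, n_planes = 5)
  expect_lt(abs(res$mean_percent - truth_pct) / truth_pct, 0.10)
})

test_that("segmentation is 8-connected and matches a flood-fill oracle", {
  m <- matrix(FALSE, 20, 40)
  m[5:9, 5:9] <- TRUE
  m[5:9, 15:19] <- TRUE            # separated by background: 2 labels
  expect_equal(max(segment_cells(m)), 2)
  diag2 <- matrix(FALSE, 10, 10)
  diag2[2:4, 2:4] <- TRUE
  diag2[5:7, 5:7] <- TRUE          # touch only at the (4,4)-(5,5) diagonal
  expect_equal(max(segment_cells(diag2)), 1)
  set.seed(14)
  blobs <- matrix(runif(50 * 50) < 0.3, 50, 50)
  got <- segment_cells(blobs)
  oracle <- brute_flood_fill(blobs)
  # same partition: labels must be a relabeling of each other
  expect_equal(max(got), max(oracle))
  expect_true(all(tapply(oracle[blobs], got[blobs],
                         function(v) length(unique(v))) == 1))
})

test_that("size gate keeps components inside inclusive physical bounds", {
  m <- matrix(FALSE, 60, 200)
  m[10:12, 4:13] <- TRUE                      # 30 px
  m[20:29, 21:30] <- TRUE                     # 100 px
  m[35:58, 41:65] <- TRUE                     # 600 px
  labels <- segment_cells(m)
  expect_equal(length(size_gate(labels, 1, 40, 500)), 1)
  areas <- tabulate(labels[labels > 0])
  expect_equal(areas[size_gate(labels, 1, 40, 500)], 100)
  # exact bound is retained (inclusive)
  m2 <- matrix(FALSE, 20, 20); m2[3:10, 3:7] <- TRUE  # 40 px at ps 1
  expect_equal(size_gate(segment_cells(m2), 1, 40, 500), 1L)
  expect_equal(length(size_gate(matrix(0L, 5, 5), 1)), 0)
  expect_error(size_gate(labels, 1, 500, 40), "min_area")
})

test_that("shape descriptors match analytic fixtures", {
  lab <- segment_cells(disk_mask(20))
  disk <- shape_descriptors(lab, 0.31)
  expect_lt(abs(disk$area_um2 - pi * (20 * 0.31)^2) / (pi * (20 * 0.31)^2),
            0.03)
  expect_gte(disk$circularity, 0.9)
  # 1 x 100 px line: pixel-centre caliper
  line <- matrix(FALSE, 5, 110); line[3, 6:105] <- TRUE
  ln <- shape_descriptors(segment_cells(line), 0.31)
  expect_equal(ln$feret_um, 99 * 0.31)
  # n x n square: diagonal Feret, circularity below the disk's
  sq <- matrix(FALSE, 60, 60); sq[6:45, 6:45] <- TRUE
  s <- shape_descriptors(segment_cells(sq), 1)
  expect_equal(s$feret_um, 39 * sqrt(2))
  expect_lt(s$circularity, disk$circularity)
  # single-pixel degenerate values
  px <- matrix(FALSE, 5, 5); px[3, 3] <- TRUE
  p1 <- shape_descriptors(segment_cells(px), 0.5)
  expect_equal(p1$area_um2, 0.25)
  expect_equal(p1$feret_um, 0)
  expect_equal(p1$circularity, 1)
})

test_that("descriptors are invariant to rotation/mirror and stable to scale", {
  set.seed(6)
  base <- disk_mask(9)
  base[4:9, 12:19] <- TRUE   # asymmetric bump
  f0 <- shape_descriptors(segment_cells(base), 1)
  for (tr in list(t(base), base[nrow(base):1, ], base[, ncol(base):1])) {
    f <- shape_descriptors(segment_cells(tr), 1)
    expect_equal(f$area_um2, f0$area_um2)
    expect_equal(f$feret_um, f0$feret_um)
    expect_lt(abs(f$perimeter_um - f0$perimeter_um) / f0$perimeter_um, 0.02)
    expect_lt(abs(f$circularity - f0$circularity), 0.05)
  }
  # upscale x2 with halved pixel size: physical descriptors within 3%
  up <- base[rep(seq_len(nrow(base)), each = 2),
             rep(seq_len(ncol(base)), each = 2)]
  fu <- shape_descriptors(segment_cells(up), 0.5)
  expect_lt(abs(fu$area_um2 - f0$area_um2) / f0$area_um2, 0.03)
  expect_lt(abs(fu$feret_um - f0$feret_um) / f0$feret_um, 0.05)
  # chain-code perimeter estimators see finer staircases after upscaling;
  # the residual bias is bounded but larger than for area/Feret
  expect_lt(abs(fu$perimeter_um - f0$perimeter_um) / f0$perimeter_um, 0.15)
})

test_that("the digitized disk maximizes circularity at equal area", {
  target_px <- sum(disk_mask(15))
  disk_circ <- shape_descriptors(segment_cells(disk_mask(15)), 1)$circularity
  set.seed(10)
  for (rep in 1:8) {
    aspect <- runif(1, 1.4, 3)
    b <- sqrt(target_px / (pi * aspect)); a <- aspect * b
    th <- runif(1, 0, pi)
    n <- 2 * ceiling(a) + 7
    c0 <- (n - 1) / 2
    dr <- outer(seq_len(n) - 1 - c0, rep(1, n))
    dc <- t(dr)
    u <- dr * cos(th) + dc * sin(th)
    v <- -dr * sin(th) + dc * cos(th)
    ell <- (u / a)^2 + (v / b)^2 <= 1
    circ <- shape_descriptors(segment_cells(ell), 1)$circularity
    expect_lte(circ, disk_circ)
  }
})

test_that("cell summaries average retained cells and flag empty sets", {
  cells <- data.frame(area_um2 = c(100, 200), perimeter_um = c(40, 60),
                      feret_um = c(12, 20), circularity = c(0.8, 0.6))
  s <- summarize_cells(cells)
  expect_equal(s$mean_area_um2, 150)
  expect_equal(s$n_cells, 2)
  one <- summarize_cells(cells[1, ])
  expect_equal(one$mean_circularity, 0.8)
  empty <- summarize_cells(cells[0, ])
  expect_equal(empty$n_cells, 0)
  expect_true(is.na(empty$mean_area_um2))
})

test_that("core cells are rounder than peripheral cells across seeds", {
  wins <- 0
  for (s in 1:10) {
    spec <- slice_spec(image_shape = c(500L, 500L), pixel_size = 1,
                       lesion_center = c(250, 250), cell_count = 150L,
                       amoeboid_fraction_core = 0.8,
                       amoeboid_fraction_periphery = 0.2, seed = 400 + s)
    sim <- simulate_cell_channel(spec)
    cm <- cell_morphometry(sim$image, 1)
    d <- sqrt((cm$cells$centroid_row - 250)^2 +
              (cm$cells$centroid_col - 250)^2)
    core <- cm$cells$circularity[d < quantile(d, 0.3)]
    peri <- cm$cells$circularity[d > quantile(d, 0.7)]
    if (length(core) >= 3 && length(peri) >= 3 &&
        mean(core) > mean(peri)) wins <- wins + 1
  }
  expect_gte(wins, 9)
})
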