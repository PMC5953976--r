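test_that("fixed-threshold segmentation grows the seed's component only", {
  img <- toy_image(array(3.0, c(2, 2, 2)), c(10, 10, 10))
  m <- segment_fixed(img, c(1, 1, 1))
  expect_equal(sum(m), 8)
  expect_equal(mask_volume_cm3(m, img), 8)

  # two avid blobs separated by sub-threshold voxels
  vals <- array(0, c(7, 3, 3))
  vals[1:2, , ] <- 5; vals[6:7, , ] <- 4
  img2 <- toy_image(vals, c(10, 10, 10))
  mA <- segment_fixed(img2, c(1, 2, 2))
  expect_true(all(which(mA) == which(vals >= 2.5 &
                                       slice.index(vals, 1) <= 2)))
  expect_equal(sum(mA), 18)

  expect_error(segment_fixed(toy_image(array(0, c(3, 3, 3))), c(2, 2, 2)),
               "below the threshold")
})

test_that("fixed-threshold volume is non-increasing in the threshold", {
  set.seed(21)
  vals <- array(runif(8^3, 0, 10), c(8, 8, 8))
  vals[4, 4, 4] <- 10  # seed always above any threshold used
  img <- toy_image(vals, c(5, 5, 5))
  vols <- sapply(seq(1, 9, by = 1), function(thr) {
    sum(segment_fixed(img, c(4, 4, 4), segmentation_config(fixed_threshold = thr)))
  })
  expect_true(all(diff(vols) <= 0))
})

test_that("every segmented voxel satisfies its defining inequality", {
  set.seed(31)
  for (rep in 1:5) {
    vals <- array(sample(0:10, 6^3, replace = TRUE), c(6, 6, 6))
    vals[3, 3, 3] <- 9
    img <- toy_image(vals, c(8, 8, 8))
    m <- segment_fixed(img, c(3, 3, 3))
    expect_true(all(img$values[as.logical(m)] >= 2.5))
    box <- box_voi(c(20, 20, 20), c(30, 30, 30))
    mp <- segment_pct_max(img, box)
    thr <- attr(mp, "threshold")
    expect_true(all(img$values[as.logical(mp)] >= thr))
    expect_true(all(as.logical(mp)[!box_mask(img, box)] == FALSE))
  }
})

test_that("41% method thresholds at max_fraction of the in-box maximum", {
  # uniform lesion SUV 10 filling the box: threshold 4.1, whole box kept
  img <- toy_image(array(10, c(4, 4, 4)), c(10, 10, 10))
  box <- box_voi(c(15, 15, 15), c(40, 40, 40))
  m <- segment_pct_max(img, box)
  expect_equal(attr(m, "threshold"), 4.1)
  expect_equal(sum(m), 64)

  # hot core 10, rim 3: rim is below 4.1 and excluded
  vals <- array(0, c(9, 9, 9))
  vals[3:7, 3:7, 3:7] <- 3; vals[4:6, 4:6, 4:6] <- 10
  img2 <- toy_image(vals, c(10, 10, 10))
  box2 <- box_voi(c(40, 40, 40), c(75, 75, 75))
  m2 <- segment_pct_max(img2, box2)
  expect_equal(sum(m2), 27)
  expect_true(all(img2$values[as.logical(m2)] == 10))

  # the fixed method keeps the rim (3 >= 2.5): pct41 volume < fixed25 volume
  mf <- segment_fixed(img2, c(5, 5, 5))
  expect_equal(sum(mf), 125)
  expect_lt(sum(m2), sum(mf))

  expect_error(segment_pct_max(toy_image(array(0, c(3, 3, 3))),
                               box_voi(c(10, 10, 10), c(20, 20, 20))),
               "degenerate")
})

test_that("uniform lesion on zero background: all three methods agree", {
  vals <- array(0, c(8, 8, 8))
  vals[3:6, 3:6, 3:6] <- 6
  img <- toy_image(vals, c(10, 10, 10))
  mf <- segment_fixed(img, c(4, 4, 4))
  mp <- segment_pct_max(img, box_voi(c(35, 35, 35), c(75, 75, 75)))
  labs <- percist_tumor_finder(img, threshold = 3.0)
  expect_identical(which(as.logical(mf)), which(vals >= 2.5))
  expect_identical(which(as.logical(mp)), which(as.logical(mf)))
  expect_identical(which(unclass(labs) == 1L), which(as.logical(mf)))
})

test_that("heterogeneity check flags per-box maxima differing by > 10%", {
  vals <- array(0, c(12, 4, 4))
  vals[2, 2, 2] <- 10; vals[6, 2, 2] <- 8; vals[10, 2, 2] <- 9.5
  img <- toy_image(vals, c(10, 10, 10))
  boxes <- list(box_voi(c(10, 10, 10), c(30, 30, 30)),
                box_voi(c(50, 10, 10), c(30, 30, 30)),
                box_voi(c(90, 10, 10), c(30, 30, 30)))
  chk <- heterogeneity_check(img, boxes)
  expect_equal(nrow(chk), 3)
  # 10 vs 8: 0.2 > 0.1 -> subdivide; 10 vs 9.5: 0.05 -> no; 8 vs 9.5: ~0.158 -> yes
  expect_true(chk$subdivide[chk$box_a == 1 & chk$box_b == 2])
  expect_false(chk$subdivide[chk$box_a == 1 & chk$box_b == 3])
  expect_true(chk$subdivide[chk$box_a == 2 & chk$box_b == 3])
  # equal maxima never flag
  chk2 <- heterogeneity_check(img, list(boxes[[1]], boxes[[1]]))
  expect_false(chk2$subdivide)
  expect_error(heterogeneity_check(img, boxes[1]), "at least two")
})

test_that("tumour finder labels all components in decreasing volume order", {
  vals <- array(0, c(10, 10, 3))
  vals[1:3, 1:3, 1] <- 5      # 9 voxels
  vals[6:10, 6:10, 1] <- 4    # 25 voxels
  vals[9:10, 1:2, 3] <- 6     # 4 voxels (separated in z)
  img <- toy_image(vals, c(10, 10, 10))
  labs <- percist_tumor_finder(img, threshold = 3.5)
  expect_equal(max(labs), 3)
  sizes <- tabulate(labs[labs > 0], 3)
  expect_equal(sizes, c(25, 9, 4))
  expect_equal(max(percist_tumor_finder(img, threshold = 100)), 0)
  expect_error(percist_tumor_finder(img, threshold = -1), "> 0")
})

test_that("component labelling matches the brute-force graph oracle", {
  skip_if_not_installed("igraph")
  set.seed(41)
  for (conn in c(6L, 18L, 26L)) {
    for (rep in 1:4) {
      mask <- array(runif(5^3) < 0.35, c(5, 5, 5))
      expect_equal(label_components(mask, conn), bf_label_components(mask, conn),
                   info = sprintf("connectivity %d rep %d", conn, rep))
    }
  }
})

test_that("label editing removes regions and carves adjacent uptake exactly", {
  vals <- array(0, c(10, 4, 4))
  vals[1:4, 1:4, 1:4] <- 5    # "tumour", 64 voxels
  vals[7:9, 1:3, 1:3] <- 12   # "brain", 27 voxels
  img <- toy_image(vals, c(10, 10, 10))
  labs <- percist_tumor_finder(img, threshold = 3)
  expect_equal(max(labs), 2)
  # excluding the brain-sized label leaves the tumour untouched, relabelled 1
  brain_label <- labs[8, 2, 2]
  ed <- edit_labels(labs, excluded = brain_label)
  expect_equal(max(ed), 1)
  expect_equal(sum(ed == 1), 64)
  # carving overlaps reduces the tumour by exactly the overlap
  carve <- array(FALSE, dim(vals)); carve[1:2, 1:4, 1:4] <- TRUE
  ed2 <- edit_labels(labs, excluded = brain_label, carve_mask = carve)
  expect_equal(sum(ed2 == 1), 64 - 32)
  # no-op edit is the identity
  expect_equal(unclass(edit_labels(labs)), unclass(labs))
  expect_error(edit_labels(labs, excluded = 9L), "not present")
})

test_that("total MTV sums disjoint lesion volumes and accumulates TLG", {
  img <- toy_image(array(4.0, c(10, 10, 10)), c(10, 10, 10))
  mk <- function(ix) { m <- array(FALSE, c(10, 10, 10)); m[ix, , 1] <- TRUE; m }
  # three slabs of 100, 50 and 16 cm^3
  l1 <- mk(1:10); l2 <- array(FALSE, c(10, 10, 10)); l2[1:5, , 2] <- TRUE
  l3 <- array(FALSE, c(10, 10, 10)); l3[1:2, 1:8, 3] <- TRUE
  rec <- total_mtv(list(l1, l2, l3), img)
  expect_equal(rec$lesion_volumes, c(100, 50, 16))
  expect_equal(rec$total_mtv, 166)
  # single 10 cm^3 lesion of mean SUV 4 -> TLG 40
  l4 <- array(FALSE, c(10, 10, 10)); l4[1:10, 1, 1] <- TRUE
  rec2 <- total_mtv(list(l4), img)
  expect_equal(rec2$total_mtv, 10)
  expect_equal(rec2$tlg, 40)
  # empty list
  rec3 <- total_mtv(list(), img)
  expect_equal(rec3$total_mtv, 0)
  expect_equal(rec3$tlg, 0)
  expect_error(total_mtv(list(l1, l1), img), "disjoint")
})
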