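make_stack <- function(il1b, dna = NULL, bit_depth = 16L) {
  chans <- list(il1b = il1b)
  if (!is.null(dna)) chans$dna <- dna
  image_stack(chans, bit_depth = bit_depth)
}

disk_logical <- function(center, radius, dim) {
  m <- matrix(FALSE, dim[1], dim[2])
  m[colocell:::disk_pixels(center, radius, dim)] <- TRUE
  m
}

test_that("cell mask: fixed thresholds behave as a contract", {
  z <- matrix(0, 32, 32)
  st <- make_stack(z)
  expect_true(!any(cell_mask(st, "il1b",
                             segmentation_params(cell_threshold = "otsu_low"))))
  img <- z; img[colocell:::disk_pixels(c(16, 16), 8, c(32L, 32L))] <- 100
  st2 <- make_stack(img)
  m <- cell_mask(st2, "il1b", segmentation_params(cell_threshold = 50))
  expect_equal(sum(m), oracle_disk_area(c(16, 16), 8, c(32L, 32L)))
  expect_true(!any(cell_mask(st2, "il1b",
                             segmentation_params(cell_threshold = 101))))
})

test_that("cell mask fills nuclear holes", {
  dim <- c(48L, 48L)
  img <- matrix(0, dim[1], dim[2])
  img[colocell:::disk_pixels(c(24, 24), 15, dim)] <- 500
  img[colocell:::disk_pixels(c(24, 24), 5, dim)] <- 0  # dim nucleus
  m <- cell_mask(make_stack(img), "il1b",
                 segmentation_params(cell_threshold = 100))
  expect_equal(sum(m), oracle_disk_area(c(24, 24), 15, dim))
})

test_that("watershed splitting: lone disks keep one label, necked pairs split", {
  dim <- c(64L, 96L)
  empty <- matrix(FALSE, dim[1], dim[2])
  expect_equal(max(split_touching(empty)), 0)
  one <- disk_logical(c(32, 32), 15, dim)
  lab1 <- split_touching(one)
  expect_equal(max(lab1), 1)
  expect_equal(sum(lab1 > 0), sum(one))
  # two equal disks, radius 15, centers 24 px apart (overlapping)
  two <- disk_logical(c(32, 36), 15, dim) | disk_logical(c(32, 60), 15, dim)
  lab2 <- split_touching(two)
  areas <- tabulate(lab2[lab2 > 0])
  expect_equal(length(areas), 2L)
  expect_lt(abs(areas[1] - areas[2]) / max(areas), 0.10)
  expect_equal(sum(areas), sum(two))
})

test_that("watershed never merges separate connected components", {
  dim <- c(128L, 128L)
  set.seed(7)
  for (trial in 1:5) {
    m <- matrix(FALSE, dim[1], dim[2])
    for (k in 1:4) {
      ctr <- runif(2, 20, 108)
      m <- m | disk_logical(ctr, runif(1, 6, 12), dim)
    }
    comp <- EBImage::bwlabel(m)
    lab <- split_touching(m)
    # every input component maps to >= 1 watershed label, and no watershed
    # label spans two input components
    for (l in seq_len(max(lab))) {
      px <- which(lab == l)
      if (!length(px)) next
      expect_length(unique(comp[px]), 1L)
    }
    expect_gte(max(lab), max(comp))
  }
})

test_that("ROI extraction filters by area and border, flags recorded", {
  dim <- c(64L, 64L)
  lab <- matrix(0L, dim[1], dim[2])
  lab[colocell:::disk_pixels(c(32, 32), 10, dim)] <- 1L      # area ~314
  lab[colocell:::disk_pixels(c(10, 10), 3, dim)] <- 2L       # tiny
  lab[colocell:::disk_pixels(c(5, 55), 10, dim)] <- 3L       # touches border
  rois <- extract_rois(lab, segmentation_params(min_cell_area_px = 50,
                                                exclude_border = TRUE))
  expect_length(rois, 1L)
  expect_equal(rois[[1]]$label, 1L)
  expect_false(rois[[1]]$touches_border)
  expect_equal(rois[[1]]$area_px, oracle_disk_area(c(32, 32), 10, dim))
  expect_equal(unname(round(rois[[1]]$centroid)), c(32, 32))
  rois2 <- extract_rois(lab, segmentation_params(min_cell_area_px = 50,
                                                 exclude_border = FALSE))
  expect_length(rois2, 2L)
  expect_true(any(vapply(rois2, function(r) r$touches_border, logical(1))))
})

test_that("ROIs are disjoint and contained in the cell mask", {
  sc <- generate_scene(small_params(), seed = 31)
  st <- render_scene(sc)
  cm <- cell_mask(st, "il1b")
  rois <- extract_rois(split_touching(cm))
  all_px <- unlist(lapply(rois, function(r) r$pixels))
  expect_equal(anyDuplicated(all_px), 0L)
  expect_true(all(cm[all_px]))
})

test_that("planted non-touching cells are recovered one ROI each", {
  for (seed in c(41, 42, 43)) {
    sc <- generate_scene(small_params(), seed = seed)
    st <- render_scene(sc)
    rois <- segment_cells(st, "il1b")
    expect_length(rois, length(sc$cells))
  }
})

test_that("nuclear mask matches planted nuclei and validates input", {
  sc <- generate_scene(small_params(), seed = 17)
  st <- render_scene(sc, noise = FALSE)
  nm <- nuclear_mask(st, "dna")
  true_area <- sum(vapply(sc$cells, function(cl)
    oracle_disk_area(cl$nucleus_center, cl$nucleus_radius, sc$field_shape),
    integer(1)))
  expect_equal(sum(nm), true_area)
  # zero channel -> empty mask; absent channel -> configuration error
  z <- make_stack(matrix(0, 16, 16), dna = matrix(0, 16, 16))
  expect_true(!any(nuclear_mask(z, "dna")))
  expect_error(nuclear_mask(z, "topro"), "not present")
  st2 <- make_stack(matrix(0, 16, 16), dna = matrix(c(0, 10), 16, 16))
  expect_true(!any(nuclear_mask(st2, "dna",
                                segmentation_params(nuclear_threshold = 11))))
})
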