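test_that("degenerate scenes: no cells, uniform background", {
  p <- scene_params(field_shape = c(64L, 64L), n_cells = 0L,
                    gaussian_sd = 0, poisson = FALSE,
                    background = c(il1b = 10, lc3b = 10, dna = 0))
  sc <- generate_scene(p, seed = 3)
  expect_length(sc$cells, 0)
  st <- render_scene(sc)
  expect_true(all(st$channels$il1b == 10))
  expect_true(all(st$channels$dna == 0))
  expect_equal(nrow(ground_truth_metrics(sc)), 0)
})

test_that("generation and rendering are deterministic for a fixed seed", {
  p <- small_params()
  s1 <- generate_scene(p, seed = 11)
  s2 <- generate_scene(p, seed = 11)
  expect_identical(s1, s2)
  expect_identical(render_scene(s1), render_scene(s2))
  s3 <- generate_scene(p, seed = 12)
  expect_false(identical(s1$cells, s3$cells))
})

test_that("colocalized vesicle counts follow the deterministic allocation", {
  p <- scene_params(field_shape = c(384L, 384L), n_cells = 5L,
                    vesicles_per_cell = 20L, colocalized_fraction = 0.5,
                    vesicle_radius_range = c(1.5, 2))
  sc <- generate_scene(p, seed = 2)
  n_coloc <- vapply(sc$cells, function(cl)
    sum(vapply(cl$vesicles, function(v) v$colocalized, logical(1))),
    integer(1))
  expect_equal(n_coloc, rep(10L, 5))
  # colocalized <=> positive amplitude in both measurement channels
  for (cl in sc$cells) for (v in cl$vesicles) {
    pos <- sum(v$amplitude > 0)
    expect_equal(pos, if (v$colocalized) 2L else 1L)
  }
})

test_that("scene geometry respects containment and separation invariants", {
  for (seed in 1:5) {
    sc <- generate_scene(small_params(), seed = seed)
    dim <- sc$field_shape
    ctrs <- t(vapply(sc$cells, function(cl) cl$center, numeric(2)))
    if (nrow(ctrs) > 1) {
      d <- as.matrix(stats::dist(ctrs))
      expect_true(all(d[upper.tri(d)] >= sc$params$min_separation))
    }
    for (cl in sc$cells) {
      expect_true(all(cl$center - cl$cell_radius >= 1) &&
                    all(cl$center + cl$cell_radius <= dim))
      # nucleus disk inside cell disk
      off <- sqrt(sum((cl$nucleus_center - cl$center)^2))
      expect_lte(off + cl$nucleus_radius, cl$cell_radius)
      for (v in cl$vesicles) {
        voff <- sqrt(sum((v$center - cl$center)^2))
        expect_lte(voff + v$radius, cl$cell_radius + 1e-9)
        noff <- sqrt(sum((v$center - cl$nucleus_center)^2))
        expect_gte(noff, cl$nucleus_radius + v$radius - 1e-9)
      }
    }
  }
})

test_that("placement fails cleanly when the field cannot hold the cells", {
  p <- scene_params(field_shape = c(64L, 64L), n_cells = 10L,
                    cell_radius_range = c(20, 20))
  expect_error(generate_scene(p, seed = 1), "crowded|place")
})

test_that("noiseless rendering is the constructive per-pixel sum", {
  sc <- one_cell_scene(field = c(64L, 64L), cell_radius = 15,
                       vesicles_per_cell = 3L, colocalized_fraction = 1)
  st <- render_scene(sc, noise = FALSE)
  ctr <- round(sc$cells[[1]]$center)
  # a cytoplasmic pixel away from nucleus and vesicles: background + cytoplasm
  sc0 <- one_cell_scene(field = c(64L, 64L), cell_radius = 15)
  st0 <- render_scene(sc0, noise = FALSE)
  cl <- sc0$cells[[1]]
  edge <- round(cl$center + c(0, cl$cell_radius - 1.5))
  expect_equal(st0$channels$il1b[edge[1], edge[2]],
               sc0$background[["il1b"]] + cl$cytoplasmic_intensity[["il1b"]])
  # nuclear channel positive only inside nuclei
  nuc <- st0$channels$dna
  expect_true(all(nuc[nuc > 0] == cl$nucleus_intensity))
  npx <- sum(nuc > 0)
  expect_equal(npx, oracle_disk_area(cl$nucleus_center, cl$nucleus_radius,
                                     sc0$field_shape))
  # full independent per-pixel summation oracle
  orc <- oracle_render(sc)
  for (ch in sc$channels)
    expect_equal(st$channels[[ch]], orc[[ch]], ignore_attr = TRUE)
})

test_that("noise model: seeds differ, field mean matches analytic mean", {
  p <- scene_params(field_shape = c(128L, 128L), n_cells = 2L,
                    cell_radius_range = c(14, 16), gaussian_sd = 2,
                    poisson = FALSE)
  s1 <- generate_scene(p, seed = 21)
  noiseless <- render_scene(s1, noise = FALSE)$channels$il1b
  n1 <- render_scene(s1)$channels$il1b
  s2 <- s1; s2$seed <- 22L
  n2 <- render_scene(s2)$channels$il1b
  expect_false(identical(n1, n2))
  npix <- length(noiseless)
  se <- 2 / sqrt(npix)  # gaussian_sd / sqrt(N); rounding adds < 3 SE here
  expect_lt(abs(mean(n1) - mean(noiseless)), 3 * se + 0.05)
})

test_that("single vesicle: true vesicular area fraction is the disk ratio", {
  sc <- one_cell_scene(field = c(64L, 64L), cell_radius = 20,
                       nucleus_radius = 5, vesicles_per_cell = 1L,
                       colocalized_fraction = 1,
                       vesicle_radius_range = c(3, 3))
  tr <- ground_truth_metrics(sc)
  cl <- sc$cells[[1]]
  v <- cl$vesicles[[1]]
  a_cell <- oracle_disk_area(cl$center, cl$cell_radius, sc$field_shape)
  a_ves <- oracle_disk_area(v$center, v$radius, sc$field_shape)
  expect_equal(tr$area_px, a_cell)
  expect_equal(tr$vesicular_area_percent_il1b, 100 * a_ves / a_cell)
})

test_that("ground-truth symmetry and boundary cases", {
  # all vesicles colocalized with equal amplitudes in both channels:
  # equal cytoplasm makes the channels identical, so M1 = M2
  p <- scene_params(field_shape = c(128L, 128L), n_cells = 1L,
                    vesicles_per_cell = 4L, colocalized_fraction = 1,
                    cytoplasmic_intensity = c(il1b = 400, lc3b = 400),
                    vesicle_amplitude = c(il1b = 5000, lc3b = 5000),
                    background = c(il1b = 50, lc3b = 50, dna = 0))
  tr <- ground_truth_metrics(generate_scene(p, seed = 4))
  expect_equal(tr$m1, tr$m2)
  # no colocalization and no second-channel signal at all
  p0 <- scene_params(field_shape = c(128L, 128L), n_cells = 2L,
                     vesicles_per_cell = 4L, colocalized_fraction = 0,
                     cytoplasmic_intensity = c(il1b = 400, lc3b = 0),
                     vesicle_amplitude = c(il1b = 5000, lc3b = 0))
  tr0 <- ground_truth_metrics(generate_scene(p0, seed = 5))
  expect_equal(tr0$coloc_area_percent, rep(0, 2))
})

test_that("true M1 and colocalized area are monotone in the planted fraction", {
  fracs <- c(0, 0.25, 0.5, 0.75, 1)
  m1s <- numeric(0); caps <- numeric(0)
  for (f in fracs) {
    p <- small_params(colocalized_fraction = f)
    tr <- ground_truth_metrics(generate_scene(p, seed = 9))
    m1s <- c(m1s, mean(tr$m1))
    caps <- c(caps, mean(tr$coloc_area_percent))
  }
  expect_true(all(diff(m1s) >= 0))
  expect_true(all(diff(caps) >= 0))
})

test_that("scenes serialize to YAML and back", {
  sc <- generate_scene(small_params(), seed = 6)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scene(sc, path)
  sc2 <- read_scene(path)
  expect_equal(length(sc2$cells), length(sc$cells))
  expect_equal(sc2$cells[[2]]$center, sc$cells[[2]]$center)
  expect_identical(render_scene(sc2, noise = FALSE),
                   render_scene(sc, noise = FALSE))
})
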