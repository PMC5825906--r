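# Scaled-down scene parameter sets used across the test files.

small_params <- function(...) {
  scene_params(field_shape = c(192L, 192L), n_cells = 3L, ...)
}

# one centered cell on a small field, geometry chosen directly
one_cell_scene <- function(field = c(96L, 96L), cell_radius = 24,
                           nucleus_radius = 7, vesicles_per_cell = 0L,
                           colocalized_fraction = 0, gaussian_sd = 0,
                           poisson = FALSE, seed = 1, ...) {
  p <- scene_params(field_shape = field, n_cells = 1L,
                    cell_radius_range = c(cell_radius, cell_radius),
                    nucleus_radius_range = c(nucleus_radius, nucleus_radius),
                    vesicles_per_cell = vesicles_per_cell,
                    colocalized_fraction = colocalized_fraction,
                    gaussian_sd = gaussian_sd, poisson = poisson, ...)
  generate_scene(p, seed = seed)
}

# match pipeline rows to truth rows by nearest centroid; returns the
# truth-row index for each measured row (NA when nothing within tol px)
match_to_truth <- function(cells, truth, tol = 5) {
  vapply(seq_len(nrow(cells)), function(i) {
    d <- sqrt((truth$center_row - cells$centroid_row[i])^2 +
                (truth$center_col - cells$centroid_col[i])^2)
    j <- which.min(d)
    if (length(j) && d[j] <= tol) j else NA_integer_
  }, integer(1))
}
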