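# Independent brute-force oracles: explicit double loops over pixels,
# sharing no code with the package's vectorized implementations.

oracle_manders <- function(ch1, ch2, roi_logical, t1, t2) {
  num1 <- 0; den1 <- 0; num2 <- 0; den2 <- 0
  for (r in seq_len(nrow(ch1))) {
    for (c in seq_len(ncol(ch1))) {
      if (!roi_logical[r, c]) next
      a <- ch1[r, c]; b <- ch2[r, c]
      if (a > t1) { den1 <- den1 + a; num2 <- num2 + b }
      if (b > t2) { den2 <- den2 + b; num1 <- num1 + a }
    }
  }
  list(m1 = if (den1 > 0) num1 / den1 else NA_real_,
       m2 = if (den2 > 0) num2 / den2 else NA_real_)
}

oracle_integrated_density <- function(grid, mask_logical) {
  s <- 0
  for (r in seq_len(nrow(grid)))
    for (c in seq_len(ncol(grid)))
      if (mask_logical[r, c]) s <- s + grid[r, c]
  s
}

oracle_coloc_area_percent <- function(mask1, mask2, roi_logical) {
  inter <- 0L; area <- 0L
  for (r in seq_len(nrow(mask1)))
    for (c in seq_len(ncol(mask1))) {
      if (roi_logical[r, c]) {
        area <- area + 1L
        if (mask1[r, c] && mask2[r, c]) inter <- inter + 1L
      }
    }
  100 * inter / area
}

oracle_background <- function(grid, nmask_logical) {
  s <- 0; n <- 0L
  for (r in seq_len(nrow(grid)))
    for (c in seq_len(ncol(grid)))
      if (nmask_logical[r, c]) { s <- s + grid[r, c]; n <- n + 1L }
  s / n
}

# pixel-count rasterized disk area by explicit loop (pixel-center rule)
oracle_disk_area <- function(center, radius, dim) {
  n <- 0L
  for (r in seq_len(dim[1]))
    for (c in seq_len(dim[2]))
      if ((r - center[1])^2 + (c - center[2])^2 <= radius^2) n <- n + 1L
  n
}

# full-enumeration two-sided Mann-Whitney p (no ties): all C(n1+n2, n1)
# group-A index sets, U from pair counts
oracle_mw_enumeration <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pool <- c(a, b)
  u_of <- function(idx_a) {
    av <- pool[idx_a]; bv <- pool[-idx_a]
    u <- 0
    for (x in av) for (y in bv) u <- u + (x > y) + 0.5 * (x == y)
    u
  }
  obs <- u_of(seq_len(n1))
  sets <- utils::combn(n1 + n2, n1)
  us <- apply(sets, 2, u_of)
  p_low <- mean(us <= obs)
  p_high <- mean(us >= obs)
  min(1, 2 * min(p_low, p_high))
}

# noiseless scene rendering by per-pixel summation over all primitives
oracle_render <- function(scene) {
  dim <- scene$field_shape
  out <- lapply(scene$channels, function(ch)
    matrix(scene$background[[ch]], dim[1], dim[2]))
  names(out) <- scene$channels
  meas <- scene$measurement_channels
  for (r in seq_len(dim[1])) {
    for (c in seq_len(dim[2])) {
      for (cl in scene$cells) {
        d2c <- (r - cl$center[1])^2 + (c - cl$center[2])^2
        in_cell <- d2c <= cl$cell_radius^2
        d2n <- (r - cl$nucleus_center[1])^2 + (c - cl$nucleus_center[2])^2
        in_nuc <- d2n <= cl$nucleus_radius^2
        if (in_cell && !in_nuc)
          for (ch in meas)
            out[[ch]][r, c] <- out[[ch]][r, c] + cl$cytoplasmic_intensity[[ch]]
        if (in_nuc)
          out[[scene$nucleus_channel]][r, c] <-
            out[[scene$nucleus_channel]][r, c] + cl$nucleus_intensity
        for (v in cl$vesicles) {
          if ((r - v$center[1])^2 + (c - v$center[2])^2 <= v$radius^2)
            for (ch in meas)
              out[[ch]][r, c] <- out[[ch]][r, c] + v$amplitude[[ch]]
        }
      }
    }
  }
  out
}

roi_logical <- function(roi) {
  m <- matrix(FALSE, roi$dim[1], roi$dim[2])
  m[roi$pixels] <- TRUE
  m
}
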