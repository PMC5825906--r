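#' Parameters for synthetic confocal fields
#'
#' Defaults emulate a low-density confocal field of rounded leukocytes
#' imaged at high magnification on a 16-bit detector: two measurement
#' channels (cytokine and autophagosome marker) with diffuse cytoplasmic
#' signal plus bright punctate vesicles, and a nuclear-stain channel that is
#' positive only inside nuclei. A controllable fraction of vesicles carries
#' signal in both measurement channels (colocalized); the rest carry signal
#' in exactly one, alternating between the two.
#'
#' @param field_shape image size `(rows, cols)` in pixels.
#' @param n_cells number of cells to place.
#' @param cell_radius_range min/max cell radius (px).
#' @param nucleus_radius_range min/max nucleus radius (px); nuclei are kept
#'   strictly inside their cell.
#' @param vesicles_per_cell number of vesicles planted in each cell.
#' @param vesicle_radius_range min/max vesicle radius (px).
#' @param colocalized_fraction fraction of each cell's vesicles positive in
#'   both measurement channels; the realized count is
#'   `round(colocalized_fraction * vesicles_per_cell)` per cell
#'   (deterministic allocation, random placement).
#' @param background per-channel background offset (grey values).
#' @param cytoplasmic_intensity per-measurement-channel diffuse cytoplasmic
#'   intensity added over the cell disk outside the nucleus.
#' @param nucleus_intensity nuclear-stain amplitude in the nucleus channel.
#' @param vesicle_amplitude per-measurement-channel amplitude added over a
#'   vesicle disk (when that vesicle is positive in the channel).
#' @param gaussian_sd read-noise standard deviation (grey values); 0 for
#'   noiseless rendering.
#' @param poisson apply shot noise (Poisson with the noiseless intensity as
#'   mean) before the Gaussian term.
#' @param bit_depth detector bit depth, 8 or 16; rendered values are
#'   clipped to range.
#' @param min_separation minimum center-to-center distance between cells
#'   (px); the default keeps default-radius cells non-touching.
#' @param allow_border_cells permit cell disks to extend past the field
#'   border.
#' @param border_margin minimum clearance (px) between a cell disk and the
#'   field border when `allow_border_cells` is `FALSE`; emulates selecting
#'   fields with whole cells in view.
#' @param touching_pairs number of deliberately overlapping cell pairs to
#'   place (for watershed-splitting tests); these pairs are exempt from
#'   `min_separation` with respect to each other only.
#' @param channels names of the three channels, in order: measurement 1
#'   (segmentation/cytokine), measurement 2 (marker), nucleus.
#' @return a `scene_params` list.
#' @export
scene_params <- function(field_shape = c(512L, 512L),
                         n_cells = 12L,
                         cell_radius_range = c(18, 26),
                         nucleus_radius_range = c(6, 9),
                         vesicles_per_cell = 8L,
                         vesicle_radius_range = c(2, 3),
                         colocalized_fraction = 0.5,
                         background = c(il1b = 100, lc3b = 100, dna = 0),
                         cytoplasmic_intensity = c(il1b = 600, lc3b = 300),
                         nucleus_intensity = 8000,
                         vesicle_amplitude = c(il1b = 8000, lc3b = 8000),
                         gaussian_sd = 20,
                         poisson = TRUE,
                         bit_depth = 16L,
                         min_separation = NULL,
                         allow_border_cells = FALSE,
                         border_margin = 4,
                         touching_pairs = 0L,
                         channels = c("il1b", "lc3b", "dna")) {
  stopifnot(length(field_shape) == 2L, all(field_shape >= 8),
            length(channels) == 3L,
            colocalized_fraction >= 0, colocalized_fraction <= 1,
            all(cytoplasmic_intensity >= 0), gaussian_sd >= 0,
            bit_depth %in% c(8L, 16L))
  meas <- channels[1:2]
  background <- normalize_per_channel(background, channels, "background")
  cytoplasmic_intensity <- normalize_per_channel(cytoplasmic_intensity, meas,
                                                 "cytoplasmic_intensity")
  vesicle_amplitude <- normalize_per_channel(vesicle_amplitude, meas,
                                             "vesicle_amplitude")
  if (is.null(min_separation))
    min_separation <- 2 * max(cell_radius_range) + 4
  structure(list(
    field_shape = as.integer(field_shape), n_cells = as.integer(n_cells),
    cell_radius_range = cell_radius_range,
    nucleus_radius_range = nucleus_radius_range,
    vesicles_per_cell = as.integer(vesicles_per_cell),
    vesicle_radius_range = vesicle_radius_range,
    colocalized_fraction = colocalized_fraction,
    background = background,
    cytoplasmic_intensity = cytoplasmic_intensity,
    nucleus_intensity = nucleus_intensity,
    vesicle_amplitude = vesicle_amplitude,
    gaussian_sd = gaussian_sd, poisson = poisson,
    bit_depth = as.integer(bit_depth),
    min_separation = min_separation,
    allow_border_cells = allow_border_cells,
    border_margin = border_margin,
    touching_pairs = as.integer(touching_pairs),
    channels = channels), class = "scene_params")
}

# recycle a scalar to the named per-channel form, or check names
normalize_per_channel <- function(x, channels, what) {
  if (length(x) == 1L && is.null(names(x))) {
    x <- rep(as.numeric(x), length(channels))
    names(x) <- channels
    return(x)
  }
  if (is.null(names(x)) && length(x) == length(channels)) {
    names(x) <- channels
    return(as.numeric(stats::setNames(x, channels)))
  }
  miss <- setdiff(channels, names(x))
  if (length(miss))
    stop(sprintf("`%s` missing channel(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  out <- as.numeric(x[channels])
  names(out) <- channels
  out
}

MAX_PLACEMENT_ATTEMPTS <- 10000L

#' Generate a synthetic scene with full ground truth
#'
#' Places cells by rejection sampling (centers at least `min_separation`
#' apart, disks inside the field unless `allow_border_cells`), nuclei
#' strictly inside cells, and vesicles by rejection sampling so each
#' vesicle disk lies inside its cell and disjoint from the nucleus.
#' Per cell, exactly `round(colocalized_fraction * vesicles_per_cell)`
#' vesicles are positive in both measurement channels; the remainder
#' alternate between single channels. Reproducible for a fixed seed.
#'
#' @param params a [scene_params()] list.
#' @param seed integer RNG seed (keep below 2^31).
#' @return an object of class `scene`: field/channel metadata, a list of
#'   cell specifications (each with nucleus and vesicle geometry and
#'   per-channel intensities), noise model, and the seed.
#' @export
generate_scene <- function(params = scene_params(), seed = 1L) {
  stopifnot(inherits(params, "scene_params"))
  set.seed(seed)
  dim <- params$field_shape
  meas <- params$channels[1:2]

  n_pair_cells <- 2L * params$touching_pairs
  if (n_pair_cells > params$n_cells)
    stop("touching_pairs requires 2 cells each; n_cells too small", call. = FALSE)

  centers <- matrix(numeric(0), ncol = 2)
  radii <- numeric(0)
  pair_of <- integer(0)   # 0 = free cell; >0 = pair id

  sample_radius <- function(rng) stats::runif(1, rng[1], rng[2])
  in_field <- function(ctr, r) {
    m <- params$border_margin %||% 0
    params$allow_border_cells ||
      (ctr[1] - r >= 1 + m && ctr[1] + r <= dim[1] - m &&
       ctr[2] - r >= 1 + m && ctr[2] + r <= dim[2] - m)
  }
  separated <- function(ctr, exempt_pair = 0L) {
    if (nrow(centers) == 0L) return(TRUE)
    d <- sqrt((centers[, 1] - ctr[1])^2 + (centers[, 2] - ctr[2])^2)
    ok <- d >= params$min_separation
    if (exempt_pair > 0L) ok <- ok | (pair_of == exempt_pair)
    all(ok)
  }
  place_cell <- function(exempt_pair = 0L, near = NULL, gap = NULL) {
    r <- sample_radius(params$cell_radius_range)
    for (i in seq_len(MAX_PLACEMENT_ATTEMPTS)) {
      if (is.null(near)) {
        ctr <- c(stats::runif(1, 1, dim[1]), stats::runif(1, 1, dim[2]))
      } else {
        a <- stats::runif(1, 0, 2 * pi)
        ctr <- near + gap * c(cos(a), sin(a))
      }
      if (in_field(ctr, r) && separated(ctr, exempt_pair))
        return(list(center = ctr, radius = r))
    }
    stop("could not place cell: field too crowded for min_separation",
         call. = FALSE)
  }

  specs <- vector("list", params$n_cells)
  k <- 0L
  if (params$touching_pairs > 0L) {
    for (p in seq_len(params$touching_pairs)) {
      a <- place_cell()
      centers <- rbind(centers, a$center); radii <- c(radii, a$radius)
      pair_of <- c(pair_of, p)
      # partner overlapping: centers ~80% of the summed radii apart
      b <- place_cell(exempt_pair = p, near = a$center,
                      gap = 0.8 * (a$radius + sample_radius(params$cell_radius_range)))
      centers <- rbind(centers, b$center); radii <- c(radii, b$radius)
      pair_of <- c(pair_of, p)
      k <- k + 2L
    }
  }
  while (k < params$n_cells) {
    a <- place_cell()
    centers <- rbind(centers, a$center); radii <- c(radii, a$radius)
    pair_of <- c(pair_of, 0L)
    k <- k + 1L
  }

  n_col <- round(params$colocalized_fraction * params$vesicles_per_cell)

  for (i in seq_len(params$n_cells)) {
    ctr <- centers[i, ]; cr <- radii[i]
    nr <- min(sample_radius(params$nucleus_radius_range), 0.45 * cr)
    # nucleus strictly inside the cell disk
    max_off <- cr - nr - 1
    a <- stats::runif(1, 0, 2 * pi)
    off <- stats::runif(1, 0, max(max_off * 0.5, 0))
    nctr <- ctr + off * c(cos(a), sin(a))

    vespecs <- list()
    nv <- params$vesicles_per_cell
    single_ch <- 0L
    for (v in seq_len(nv)) {
      vr <- sample_radius(params$vesicle_radius_range)
      placed <- FALSE
      for (att in seq_len(MAX_PLACEMENT_ATTEMPTS)) {
        ang <- stats::runif(1, 0, 2 * pi)
        rad <- sqrt(stats::runif(1)) * (cr - vr)
        vctr <- ctr + rad * c(cos(ang), sin(ang))
        if (sqrt(sum((vctr - nctr)^2)) >= nr + vr) { placed <- TRUE; break }
      }
      if (!placed)
        stop("could not place vesicle outside the nucleus", call. = FALSE)
      coloc <- v <= n_col
      amp <- stats::setNames(numeric(2), meas)
      if (coloc) {
        amp[meas] <- params$vesicle_amplitude[meas]
      } else {
        single_ch <- single_ch + 1L
        ch <- meas[1L + (single_ch - 1L) %% 2L]
        amp[ch] <- params$vesicle_amplitude[ch]
      }
      vespecs[[v]] <- list(center = vctr, radius = vr, amplitude = amp,
                           colocalized = coloc)
    }
    specs[[i]] <- list(
      label = i, center = ctr, cell_radius = cr,
      nucleus_center = nctr, nucleus_radius = nr,
      cytoplasmic_intensity = params$cytoplasmic_intensity,
      nucleus_intensity = params$nucleus_intensity,
      vesicles = vespecs)
  }

  structure(list(
    field_shape = dim,
    channels = params$channels,
    measurement_channels = meas,
    nucleus_channel = params$channels[3],
    cells = specs,
    background = params$background,
    noise_model = list(gaussian_sd = params$gaussian_sd,
                       poisson = params$poisson),
    bit_depth = params$bit_depth,
    seed = as.integer(seed),
    params = params), class = "scene")
}

#' @export
print.scene <- function(x, ...) {
  nv <- sum(vapply(x$cells, function(cl) length(cl$vesicles), integer(1)))
  cat(sprintf("<scene> %d x %d px, %d cells, %d vesicles, seed %d\n",
              x$field_shape[1], x$field_shape[2], length(x$cells), nv, x$seed))
  invisible(x)
}

#' Render a scene to an image stack
#'
#' Noiseless intensity at a pixel is the channel background plus the
#' cytoplasmic term of its cell (over the cell disk outside the nucleus for
#' measurement channels; the nuclear amplitude over the nucleus disk for
#' the nucleus channel) plus the summed amplitudes of overlapping vesicles.
#' Shot noise (Poisson) is applied to the noiseless intensity, then
#' additive Gaussian read noise; values are rounded and clipped to the
#' bit-depth range. Noise generation is seeded from the scene seed, so
#' rendering is bit-reproducible.
#'
#' @param scene a [generate_scene()] result.
#' @param noise apply the scene's noise model (set `FALSE` for the
#'   noiseless ground-truth rendering; noiseless values are returned
#'   unrounded).
#' @return an [image_stack()].
#' @export
render_scene <- function(scene, noise = TRUE) {
  stopifnot(inherits(scene, "scene"))
  dim <- scene$field_shape
  maxval <- 2^scene$bit_depth - 1
  mats <- lapply(scene$channels, function(ch)
    matrix(scene$background[[ch]], dim[1], dim[2]))
  names(mats) <- scene$channels
  meas <- scene$measurement_channels
  nuc_ch <- scene$nucleus_channel

  for (cl in scene$cells) {
    cell_px <- disk_pixels(cl$center, cl$cell_radius, dim)
    nuc_px <- disk_pixels(cl$nucleus_center, cl$nucleus_radius, dim)
    cyto_px <- setdiff(cell_px, nuc_px)
    for (ch in meas)
      mats[[ch]][cyto_px] <- mats[[ch]][cyto_px] + cl$cytoplasmic_intensity[[ch]]
    mats[[nuc_ch]][nuc_px] <- mats[[nuc_ch]][nuc_px] + cl$nucleus_intensity
    for (v in cl$vesicles) {
      vpx <- disk_pixels(v$center, v$radius, dim)
      for (ch in meas)
        if (v$amplitude[[ch]] > 0)
          mats[[ch]][vpx] <- mats[[ch]][vpx] + v$amplitude[[ch]]
    }
  }

  if (noise) {
    set.seed(scene$seed + 1L)
    n <- prod(dim)
    for (ch in scene$channels) {
      x <- mats[[ch]]
      if (scene$noise_model$poisson)
        x <- matrix(stats::rpois(n, lambda = x), dim[1], dim[2])
      if (scene$noise_model$gaussian_sd > 0)
        x <- x + stats::rnorm(n, 0, scene$noise_model$gaussian_sd)
      mats[[ch]] <- pmin(pmax(round(x), 0), maxval)
    }
  } else {
    mats <- lapply(mats, function(x) pmin(pmax(x, 0), maxval))
  }
  image_stack(mats, bit_depth = scene$bit_depth)
}

#' Ground-truth per-cell metrics of a scene
#'
#' The answer key for recovery tests: per-cell metrics computed by
#' exhaustive pixel loops over the noiseless rendering and the true
#' geometry, independently of the measurement pipeline. For each cell and
#' measurement channel it reports the true background, integrated densities
#' of the whole-cell and vesicular compartments (background-subtracted
#' noiseless intensities), the vesicular intensity percentage and
#' vesicular-area percentage, plus Manders' M1/M2 and the
#' colocalizing-area percentage. Manders truth uses per-channel thresholds
#' `background + cytoplasmic_intensity` (strict `>`), so exactly the
#' vesicle-bearing pixels of a channel count as above threshold.
#'
#' @param scene a [generate_scene()] result.
#' @return data.frame, one row per cell.
#' @export
ground_truth_metrics <- function(scene) {
  stopifnot(inherits(scene, "scene"))
  stack <- render_scene(scene, noise = FALSE)
  meas <- scene$measurement_channels
  dim <- scene$field_shape
  g1 <- stack$channels[[meas[1]]]
  g2 <- stack$channels[[meas[2]]]
  bg <- scene$background

  rows <- lapply(scene$cells, function(cl) {
    cpx <- sort(disk_pixels(cl$center, cl$cell_radius, dim))
    area <- length(cpx)
    # per-channel vesicle membership, by explicit loop over cell pixels
    in_ves <- matrix(FALSE, nrow = area, ncol = 2)
    for (v in cl$vesicles) {
      vpx <- disk_pixels(v$center, v$radius, dim)
      hit <- cpx %in% vpx
      for (j in 1:2)
        if (v$amplitude[[meas[j]]] > 0) in_ves[, j] <- in_ves[, j] | hit
    }
    thr1 <- bg[[meas[1]]] + cl$cytoplasmic_intensity[[meas[1]]]
    thr2 <- bg[[meas[2]]] + cl$cytoplasmic_intensity[[meas[2]]]

    id_cell <- c(0, 0); id_ves <- c(0, 0)
    m1_num <- 0; m1_den <- 0; m2_num <- 0; m2_den <- 0
    n_coloc_px <- 0L
    for (i in seq_len(area)) {
      p <- cpx[i]
      v1 <- g1[p]; v2 <- g2[p]
      id_cell[1] <- id_cell[1] + max(v1 - bg[[meas[1]]], 0)
      id_cell[2] <- id_cell[2] + max(v2 - bg[[meas[2]]], 0)
      if (in_ves[i, 1]) id_ves[1] <- id_ves[1] + max(v1 - bg[[meas[1]]], 0)
      if (in_ves[i, 2]) id_ves[2] <- id_ves[2] + max(v2 - bg[[meas[2]]], 0)
      if (v1 > thr1) { m1_den <- m1_den + v1; m2_num <- m2_num + v2 }
      if (v2 > thr2) { m2_den <- m2_den + v2; m1_num <- m1_num + v1 }
      if (in_ves[i, 1] && in_ves[i, 2]) n_coloc_px <- n_coloc_px + 1L
    }
    out <- data.frame(
      cell = cl$label,
      center_row = cl$center[1], center_col = cl$center[2],
      area_px = area,
      m1 = if (m1_den > 0) m1_num / m1_den else NA_real_,
      m2 = if (m2_den > 0) m2_num / m2_den else NA_real_,
      coloc_area_percent = 100 * n_coloc_px / area)
    for (j in 1:2) {
      ch <- meas[j]
      out[[paste0("background_", ch)]] <- bg[[ch]]
      out[[paste0("id_cellular_", ch)]] <- id_cell[j]
      out[[paste0("id_vesicular_", ch)]] <- id_ves[j]
      out[[paste0("vesicular_percent_", ch)]] <-
        if (id_cell[j] > 0) 100 * id_ves[j] / id_cell[j] else 0
      out[[paste0("vesicular_area_percent_", ch)]] <-
        100 * sum(in_ves[, j]) / area
    }
    out
  })
  if (length(rows) == 0L) return(empty_truth_table(meas))
  do.call(rbind, rows)
}

empty_truth_table <- function(meas) {
  cols <- c("cell", "center_row", "center_col", "area_px", "m1", "m2",
            "coloc_area_percent",
            unlist(lapply(meas, function(ch)
              paste0(c("background_", "id_cellular_", "id_vesicular_",
                       "vesicular_percent_", "vesicular_area_percent_"), ch))))
  df <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)), cols))
  df
}

#' Serialize a scene to a plain-text YAML file
#' @param scene a [generate_scene()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scene <- function(scene, path) {
  stopifnot(inherits(scene, "scene"))
  x <- unclass(scene)
  x$params <- unclass(x$params)
  yaml::write_yaml(yamlify(x), path)
  invisible(path)
}

# named atomic vectors must become maps, or YAML drops the names
yamlify <- function(x) {
  if (is.list(x)) return(lapply(x, yamlify))
  if (is.atomic(x) && !is.null(names(x))) return(as.list(x))
  x
}

#' Read a scene written by [write_scene()]
#' @param path YAML path.
#' @return a `scene` object.
#' @export
read_scene <- function(path) {
  x <- yaml::yaml.load_file(path)
  x$field_shape <- as.integer(unlist(x$field_shape))
  x$background <- unlist(x$background)
  x$channels <- unlist(x$channels)
  x$measurement_channels <- unlist(x$measurement_channels)
  x$cells <- lapply(x$cells, function(cl) {
    cl$center <- unlist(cl$center)
    cl$nucleus_center <- unlist(cl$nucleus_center)
    cl$cytoplasmic_intensity <- unlist(cl$cytoplasmic_intensity)
    cl$vesicles <- lapply(cl$vesicles, function(v) {
      v$center <- unlist(v$center)
      v$amplitude <- unlist(v$amplitude)
      v
    })
    cl
  })
  x$params <- structure(x$params, class = "scene_params")
  if (!is.null(x$params$background))
    x$params$background <- unlist(x$params$background)
  structure(x, class = "scene")
}
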