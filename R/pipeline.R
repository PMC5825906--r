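#' Pipeline configuration
#'
#' One declarative configuration drives the whole analysis: channel roles,
#' segmentation and quantification parameters, per-image colocalization
#' thresholds, condition-to-directory assignment and the output directory.
#'
#' The nucleus channel may be omitted only when `background_fallback`
#' supplies a constant background. Which measurement channel M1 indexes is
#' configurable (`m1_channel`) and recorded in the outputs rather than
#' assumed.
#'
#' @param measurement_1 name of the first measurement channel (cytokine;
#'   also the segmentation channel).
#' @param measurement_2 name of the second measurement channel (marker).
#' @param nucleus name of the nuclear channel, or `NULL`.
#' @param channel_order names of the TIFF pages in file order; defaults to
#'   `c(measurement_1, measurement_2, nucleus)`.
#' @param segmentation a [segmentation_params()] list.
#' @param quant a [quant_params()] list.
#' @param coloc_threshold per-channel Manders threshold: a named numeric
#'   vector, a scalar, or a method name (`"otsu"`, `"otsu_low"`) resolved
#'   per image per channel.
#' @param m1_channel channel whose intensity M1 integrates (default
#'   `measurement_1`).
#' @param background_fallback constant background used when no nuclear
#'   channel/mask is available.
#' @param conditions named character vector mapping condition labels to
#'   directories of multi-page TIFFs.
#' @param output_dir directory for the cell table, summaries, comparison
#'   and log.
#' @param seed integer seed recorded with the run.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(measurement_1 = "il1b",
                            measurement_2 = "lc3b",
                            nucleus = "dna",
                            channel_order = NULL,
                            segmentation = segmentation_params(),
                            quant = quant_params(),
                            coloc_threshold = "otsu",
                            m1_channel = measurement_1,
                            background_fallback = NULL,
                            conditions = character(0),
                            output_dir = "colocell_out",
                            seed = 1L) {
  if (!nzchar(measurement_1) || !nzchar(measurement_2))
    stop("config: both `measurement_1` and `measurement_2` must be named",
         call. = FALSE)
  if (is.null(nucleus) && is.null(background_fallback))
    stop("config: `nucleus` may be omitted only when `background_fallback` ",
         "is set", call. = FALSE)
  if (!m1_channel %in% c(measurement_1, measurement_2))
    stop("config: `m1_channel` must be one of the measurement channels",
         call. = FALSE)
  if (is.null(channel_order))
    channel_order <- c(measurement_1, measurement_2, nucleus)
  structure(list(
    measurement_1 = measurement_1, measurement_2 = measurement_2,
    nucleus = nucleus, channel_order = channel_order,
    segmentation = segmentation, quant = quant,
    coloc_threshold = coloc_threshold, m1_channel = m1_channel,
    background_fallback = background_fallback,
    conditions = conditions, output_dir = output_dir,
    seed = as.integer(seed)), class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Flat declarative keys mirroring the arguments of [pipeline_config()];
#' `segmentation:` and `quant:` sub-maps are passed to
#' [segmentation_params()] / [quant_params()].
#'
#' @param path YAML file path.
#' @return a `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::yaml.load_file(path)
  seg <- do.call(segmentation_params, y$segmentation %||% list())
  qp <- do.call(quant_params, lapply(y$quant %||% list(), unlist))
  ct <- y$coloc_threshold %||% "otsu"
  if (is.list(ct)) ct <- unlist(ct)
  conds <- unlist(y$conditions %||% character(0))
  pipeline_config(
    measurement_1 = y$measurement_1 %||% "il1b",
    measurement_2 = y$measurement_2 %||% "lc3b",
    nucleus = y$nucleus,
    channel_order = unlist(y$channel_order %||% NULL),
    segmentation = seg, quant = qp, coloc_threshold = ct,
    m1_channel = y$m1_channel %||% y$measurement_1 %||% "il1b",
    background_fallback = y$background_fallback,
    conditions = conds,
    output_dir = y$output_dir %||% "colocell_out",
    seed = y$seed %||% 1L)
}

# analyze a single image stack: segmentation, compartments, colocalization
analyze_image <- function(stack, image_id, config, condition = NA_character_) {
  m1ch <- config$measurement_1
  m2ch <- config$measurement_2
  rois <- segment_cells(stack, m1ch, config$segmentation)
  cell_thr <- attr(rois, "threshold")

  nmask <- NULL
  if (!is.null(config$nucleus) && config$nucleus %in% names(stack$channels))
    nmask <- nuclear_mask(stack, config$nucleus, config$segmentation)

  meas <- c(m1ch, m2ch)
  bg <- vapply(meas, function(ch)
    estimate_background(stack, ch, nmask,
                        fallback = config$background_fallback),
    numeric(1))
  corrected <- lapply(meas, function(ch)
    subtract_background(stack$channels[[ch]], bg[[ch]]))
  names(corrected) <- meas

  # per-image Manders thresholds, resolved per channel on the raw image
  ct <- config$coloc_threshold
  coloc_thr <- vapply(meas, function(ch) {
    spec <- if (!is.null(names(ct)) && ch %in% names(ct)) ct[[ch]]
            else if (is.character(ct)) ct else ct[[1]]
    resolve_threshold(stack$channels[[ch]], spec, stack$bit_depth)
  }, numeric(1))

  cha <- config$m1_channel
  chb <- setdiff(meas, cha)

  rows <- lapply(rois, function(roi) {
    mm <- lapply(meas, function(ch)
      measure_cell(stack, ch, roi, params = config$quant,
                   background = bg[[ch]]))
    names(mm) <- meas
    cc <- manders_coefficients(stack$channels[[cha]], stack$channels[[chb]],
                               roi, coloc_thr[[cha]], coloc_thr[[chb]])
    vm1 <- vesicular_mask(corrected[[m1ch]], roi, config$quant, m1ch)
    vm2 <- vesicular_mask(corrected[[m2ch]], roi, config$quant, m2ch)
    cap <- coloc_area_percent(vm1, vm2, roi)
    out <- data.frame(
      condition = condition, image_id = image_id,
      cell_label = roi$label, area_px = roi$area_px,
      centroid_row = roi$centroid[[1]], centroid_col = roi$centroid[[2]],
      touches_border = roi$touches_border,
      stringsAsFactors = FALSE)
    for (ch in meas) {
      out[[paste0("background_", ch)]] <- mm[[ch]]$background
      out[[paste0("id_vesicular_", ch)]] <- mm[[ch]]$id_vesicular
      out[[paste0("id_cellular_", ch)]] <- mm[[ch]]$id_cellular
      out[[paste0("vesicular_percent_", ch)]] <- mm[[ch]]$vesicular_percent
    }
    out$m1 <- cc$m1
    out$m2 <- cc$m2
    out$m1_defined <- cc$m1_defined
    out$m2_defined <- cc$m2_defined
    out$coloc_area_percent <- cap
    out
  })
  tab <- if (length(rows)) do.call(rbind, rows) else empty_cell_table(meas)
  attr(tab, "provenance") <- list(
    image_id = image_id, cell_threshold = cell_thr,
    coloc_threshold = coloc_thr, background = bg,
    n_cells = length(rois), m1_channel = cha)
  tab
}

empty_cell_table <- function(meas) {
  cols <- c("condition", "image_id", "cell_label", "area_px",
            "centroid_row", "centroid_col", "touches_border",
            unlist(lapply(meas, function(ch)
              paste0(c("background_", "id_vesicular_", "id_cellular_",
                       "vesicular_percent_"), ch))),
            "m1", "m2", "m1_defined", "m2_defined", "coloc_area_percent")
  proto <- list(condition = character(0), image_id = character(0),
                cell_label = integer(0), touches_border = logical(0),
                m1_defined = logical(0), m2_defined = logical(0))
  df <- stats::setNames(lapply(cols, function(cn)
    proto[[cn]] %||% numeric(0)), cols)
  as.data.frame(df, stringsAsFactors = FALSE)
}

pipeline_metrics <- function(config) {
  meas <- c(config$measurement_1, config$measurement_2)
  c(paste0("id_cellular_", meas), paste0("id_vesicular_", meas),
    paste0("vesicular_percent_", meas), "m1", "m2", "coloc_area_percent")
}

#' Run the full analysis over directories of images
#'
#' For every condition directory in the configuration, reads each
#' multi-page TIFF, segments cells on the first measurement channel,
#' measures compartment integrated densities and colocalization per cell,
#' and writes: `cells.csv` (per-cell table), `summary.json` (per-condition
#' mean/SEM/n per metric, undefined colocalization values excluded),
#' `comparisons.csv` (Mann-Whitney per metric when exactly two conditions
#' are present) and `run.log` (resolved thresholds and backgrounds per
#' image, cells dropped, failures). A failing image is logged and skipped;
#' the batch continues.
#'
#' @param config a [pipeline_config()] (or path to a YAML configuration).
#' @return a `pipeline_result` list: `cells`, `summaries`, `comparisons`,
#'   `failures`, `output_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("colocell run, seed %d", config$seed),
                 sprintf("channels: %s; m1 indexes %s",
                         paste(config$channel_order, collapse = ", "),
                         config$m1_channel))
  tabs <- list()
  failures <- list()
  conds <- config$conditions
  if (length(conds) == 0L)
    warning("no conditions configured: empty batch", call. = FALSE)
  for (cond in names(conds)) {
    files <- sort(list.files(conds[[cond]], pattern = "\\.tiff?$",
                             full.names = TRUE))
    if (length(files) == 0L)
      warning(sprintf("condition '%s': no TIFF images in %s", cond,
                      conds[[cond]]), call. = FALSE)
    for (f in files) {
      image_id <- sub("\\.tiff?$", "", basename(f))
      res <- tryCatch({
        stack <- read_stack(f, config$channel_order)
        analyze_image(stack, image_id, config, condition = cond)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures[[length(failures) + 1L]] <-
          list(image = f, message = conditionMessage(res))
        log_lines <- c(log_lines,
                       sprintf("FAIL %s: %s", f, conditionMessage(res)))
        next
      }
      pv <- attr(res, "provenance")
      log_lines <- c(log_lines, sprintf(
        "%s [%s]: cell_thr %.3f, coloc_thr %s, bg %s, %d cell(s)",
        image_id, cond, pv$cell_threshold,
        paste(sprintf("%s=%.3f", names(pv$coloc_threshold),
                      pv$coloc_threshold), collapse = " "),
        paste(sprintf("%s=%.3f", names(pv$background), pv$background),
              collapse = " "),
        pv$n_cells))
      tabs[[length(tabs) + 1L]] <- res
    }
  }
  meas <- c(config$measurement_1, config$measurement_2)
  cells <- if (length(tabs)) do.call(rbind, tabs) else empty_cell_table(meas)
  rownames(cells) <- NULL

  metrics <- pipeline_metrics(config)
  summaries <- list(m1_channel = config$m1_channel, conditions = list())
  for (cond in unique(cells$condition)) {
    sub <- cells[cells$condition == cond, , drop = FALSE]
    ms <- lapply(metrics, function(m) {
      v <- metric_values(sub, m)
      if (length(v) == 0L) return(list(mean = NA, sem = NA, n = 0L))
      s <- summarize_group(v)
      list(mean = s[["mean"]], sem = s[["sem"]], n = as.integer(s[["n"]]))
    })
    names(ms) <- metrics
    summaries$conditions[[cond]] <- ms
  }

  comparisons <- NULL
  cond_levels <- unique(cells$condition)
  if (length(cond_levels) == 2L) {
    comparisons <- do.call(rbind, lapply(metrics, function(m) {
      va <- metric_values(cells[cells$condition == cond_levels[1], ], m)
      vb <- metric_values(cells[cells$condition == cond_levels[2], ], m)
      if (length(va) == 0L || length(vb) == 0L) return(NULL)
      gc <- mann_whitney(va, vb)
      data.frame(metric = m, group_a = cond_levels[1],
                 group_b = cond_levels[2],
                 n1 = gc$n1, n2 = gc$n2, U = gc$U,
                 p_two_sided = gc$p_two_sided, method = gc$method,
                 mean_a = gc$mean_a, sem_a = gc$sem_a,
                 mean_b = gc$mean_b, sem_b = gc$sem_b,
                 stringsAsFactors = FALSE)
    }))
  }

  write_cell_table(cells, file.path(config$output_dir, "cells.csv"))
  jsonlite::write_json(summaries,
                       file.path(config$output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(comparisons))
    utils::write.csv(comparisons,
                     file.path(config$output_dir, "comparisons.csv"),
                     row.names = FALSE)
  writeLines(log_lines, file.path(config$output_dir, "run.log"))

  structure(list(cells = cells, summaries = summaries,
                 comparisons = comparisons, failures = failures,
                 output_dir = config$output_dir),
            class = "pipeline_result")
}

# metric values with undefined colocalization flagged out
metric_values <- function(tab, metric) {
  v <- tab[[metric]]
  if (metric == "m1") v <- v[tab$m1_defined]
  if (metric == "m2") v <- v[tab$m2_defined]
  v[!is.na(v)]
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d cell(s), %d condition(s), %d failure(s)\n",
              nrow(x$cells), length(unique(x$cells$condition)),
              length(x$failures)))
  if (!is.null(x$comparisons)) {
    cat("comparisons (Mann-Whitney, two-sided):\n")
    print(x$comparisons[, c("metric", "U", "p_two_sided", "mean_a", "mean_b")],
          row.names = FALSE)
  }
  invisible(x)
}

#' Simulate a batch of synthetic images to disk
#'
#' Renders `n_images` independent scenes (seeds `seed + 1 ... seed +
#' n_images`) into multi-page TIFFs suitable as direct input to
#' [run_pipeline()], alongside the scene descriptions (YAML) and the
#' pooled ground-truth table (`truth.csv`).
#'
#' @param params a [scene_params()] list.
#' @param n_images number of fields to simulate.
#' @param out_dir output directory (created if missing).
#' @param seed integer base seed.
#' @param prefix image file-name prefix.
#' @return list with `image_paths`, `scene_paths`, `truth` (data.frame
#'   with an `image_id` column), invisibly.
#' @export
simulate_batch <- function(params = scene_params(), n_images = 1L,
                           out_dir = "colocell_sim", seed = 1L,
                           prefix = "img") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  image_paths <- character(n_images)
  scene_paths <- character(n_images)
  truths <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    scene <- generate_scene(params, seed = seed + i)
    stack <- render_scene(scene)
    image_id <- sprintf("%s_%03d", prefix, i)
    image_paths[i] <- file.path(out_dir, paste0(image_id, ".tif"))
    scene_paths[i] <- file.path(out_dir, paste0(image_id, "_scene.yaml"))
    write_stack(stack, image_paths[i])
    write_scene(scene, scene_paths[i])
    tr <- ground_truth_metrics(scene)
    if (nrow(tr)) tr <- cbind(image_id = image_id, tr)
    truths[[i]] <- tr
  }
  truth <- do.call(rbind, truths[vapply(truths, nrow, integer(1)) > 0])
  if (is.null(truth)) truth <- data.frame()
  utils::write.csv(truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
  invisible(list(image_paths = image_paths, scene_paths = scene_paths,
                 truth = truth))
}

#' Compare one per-cell metric between two conditions
#'
#' @param cells per-cell table from [run_pipeline()] (`$cells`).
#' @param metric column name, e.g. `"coloc_area_percent"`.
#' @param condition_col grouping column (must have exactly two levels).
#' @return a `group_comparison` from [mann_whitney()].
#' @export
compare_conditions <- function(cells, metric,
                               condition_col = "condition") {
  lev <- unique(cells[[condition_col]])
  if (length(lev) != 2L)
    stop("exactly two conditions required", call. = FALSE)
  va <- metric_values(cells[cells[[condition_col]] == lev[1], , drop = FALSE],
                      metric)
  vb <- metric_values(cells[cells[[condition_col]] == lev[2], , drop = FALSE],
                      metric)
  mann_whitney(va, vb)
}
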