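#' Create a multi-channel image stack
#'
#' Container for one field of view: a named list of equally-sized 2D
#' intensity matrices (one per channel) plus bit-depth metadata. Intensities
#' are stored as raw grey values in `[0, 2^bit_depth - 1]`.
#'
#' @param channels named list of numeric matrices, all with identical
#'   dimensions.
#' @param bit_depth 8 or 16.
#' @param pixel_size_um optional physical pixel size in micrometers.
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(channels, bit_depth = 16L, pixel_size_um = NULL) {
  if (!is.list(channels) || length(channels) == 0L)
    stop("`channels` must be a non-empty named list of matrices", call. = FALSE)
  if (is.null(names(channels)) || any(!nzchar(names(channels))))
    stop("every channel must be named", call. = FALSE)
  if (!bit_depth %in% c(8L, 16L))
    stop("`bit_depth` must be 8 or 16", call. = FALSE)
  dims <- lapply(channels, dim)
  if (any(vapply(channels, function(m) !is.matrix(m), logical(1))))
    stop("each channel must be a 2D matrix", call. = FALSE)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L)
    stop("all channels must share identical dimensions", call. = FALSE)
  maxval <- 2^bit_depth - 1
  for (nm in names(channels)) {
    v <- channels[[nm]]
    if (any(v < 0) || any(v > maxval))
      stop(sprintf("channel '%s' has intensities outside [0, %d]", nm, maxval),
           call. = FALSE)
  }
  structure(
    list(channels = channels, bit_depth = as.integer(bit_depth),
         pixel_size_um = pixel_size_um),
    class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<image_stack> %d x %d px, %d-bit, channels: %s\n",
              d[1], d[2], x$bit_depth,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$channels[[1]])

#' Read a multi-page TIFF into an image stack
#'
#' Page `i` of the file becomes channel `channel_names[i]`; the page count
#' must equal the number of names supplied. 8- and 16-bit greyscale pages
#' are read losslessly as raw grey values.
#'
#' @param path TIFF file path.
#' @param channel_names character vector naming the pages in order.
#' @return an [image_stack()].
#' @export
read_stack <- function(path, channel_names) {
  if (!file.exists(path)) stop("cannot read '", path, "'", call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != length(channel_names))
    stop(sprintf("'%s' has %d page(s) but %d channel name(s) were supplied",
                 path, length(pages), length(channel_names)), call. = FALSE)
  bits <- attr(pages[[1]], "bits.per.sample") %||% 16L
  channels <- lapply(pages, function(p) {
    m <- unclass(p)
    attributes(m) <- list(dim = dim(p))
    storage.mode(m) <- "double"
    m
  })
  names(channels) <- channel_names
  image_stack(channels, bit_depth = as.integer(bits))
}

#' Write an image stack to a multi-page TIFF
#'
#' One page per channel in the stack's channel order; lossless for integer
#' grey values at the stack's bit depth.
#'
#' @param stack an [image_stack()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  maxval <- 2^stack$bit_depth - 1
  pages <- lapply(stack$channels, function(m) round(m) / maxval)
  ok <- tiff::writeTIFF(pages, path, bits.per.sample = stack$bit_depth,
                        compression = "none")
  if (!ok) stop("failed to write '", path, "'", call. = FALSE)
  invisible(path)
}

#' Write the per-cell measurement table as CSV
#'
#' One row per cell, stable column order, full numeric precision (values
#' re-parse to equality). An empty table yields a header-only file.
#'
#' @param records data.frame of per-cell records.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  utils::write.csv(format_full_precision(records), path,
                   row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

# render numerics at full precision so read.csv recovers equal doubles
format_full_precision <- function(df) {
  as.data.frame(lapply(df, function(col) {
    if (is.double(col)) {
      out <- vapply(col, function(v)
        if (is.na(v)) NA_character_ else format(v, digits = 17, scientific = FALSE),
        character(1))
      out
    } else col
  }), stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a per-cell measurement table written by [write_cell_table()]
#' @param path CSV path.
#' @return data.frame.
#' @export
read_cell_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}
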