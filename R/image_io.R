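#' Construct an image raster
#'
#' An `image_raster` is the package's carrier for a single co-registered
#' source or fused image: a `height x width x channels` numeric array of
#' intensities on the unit range, with 1 (gray) or 3 (RGB) channels.
#'
#' @param pixels Numeric matrix (`height x width`) or 3-d array
#'   (`height x width x channels`, channels 1 or 3) of intensities in
#'   `[0, 1]`.
#' @param source_bit_depth Bit depth of the originating file (8 or 16);
#'   purely informative, kept for round-trip writing.
#' @return An `image_raster` object: the array with attributes
#'   `source_bit_depth`.
#' @export
image_raster <- function(pixels, source_bit_depth = 8L) {
  if (is.matrix(pixels)) dim(pixels) <- c(dim(pixels), 1L)
  if (!is.array(pixels) || length(dim(pixels)) != 3L || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix or height x width x channels array",
         call. = FALSE)
  }
  d <- dim(pixels)
  if (!d[3] %in% c(1L, 3L)) {
    stop("channels must be 1 or 3, got ", d[3], call. = FALSE)
  }
  if (d[1] < 2L || d[2] < 2L) {
    stop("image must be at least 2x2 (adjacent-pixel differences need a neighbor)",
         call. = FALSE)
  }
  if (anyNA(pixels) || min(pixels) < -1e-9 || max(pixels) > 1 + 1e-9) {
    stop("intensities must lie in [0, 1] and be finite", call. = FALSE)
  }
  pixels <- pmin(pmax(pixels, 0), 1)
  structure(pixels,
            source_bit_depth = as.integer(source_bit_depth),
            class = "image_raster")
}

#' @export
print.image_raster <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<image_raster> %d x %d, %d channel(s), %d-bit source\n",
              d[1], d[2], d[3], attr(x, "source_bit_depth")))
  cat(sprintf("  intensity range [%.4f, %.4f]\n", min(x), max(x)))
  invisible(x)
}

is_image_raster <- function(x) inherits(x, "image_raster")

raster_height <- function(x) dim(x)[1]
raster_width <- function(x) dim(x)[2]
raster_channels <- function(x) dim(x)[3]

#' Bundle co-registered images into a stack
#'
#' @param ... Two or more `image_raster` objects (or a single list of them)
#'   with identical height, width and channel count.
#' @return An `image_stack`: a list of rasters with element count `K`.
#' @export
image_stack <- function(...) {
  imgs <- list(...)
  if (length(imgs) == 1L && is.list(imgs[[1]]) && !is_image_raster(imgs[[1]])) {
    imgs <- imgs[[1]]
  }
  if (length(imgs) < 2L) stop("an image stack needs K >= 2 images", call. = FALSE)
  imgs <- lapply(imgs, function(im) {
    if (is_image_raster(im)) im else image_raster(im)
  })
  dims <- vapply(imgs, function(im) dim(im), integer(3))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]) ||
      any(dims[3, ] != dims[3, 1])) {
    stop("all images in a stack must share height, width and channels",
         call. = FALSE)
  }
  structure(imgs, class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x[[1]])
  cat(sprintf("<image_stack> K = %d images, %d x %d x %d\n",
              length(x), d[1], d[2], d[3]))
  invisible(x)
}

#' Read a raster image from disk
#'
#' Reads PNG, TIFF or JPEG files and normalizes intensities to the unit
#' range by dividing by `2^bit_depth - 1`. Gray+alpha and RGBA images are
#' reduced to gray/RGB (the alpha channel is dropped with a warning).
#'
#' @param path Path to a `.png`, `.tif(f)`, `.jpg`/`.jpeg` file.
#' @return An `image_raster`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path, info = TRUE),
    jpg = ,
    jpeg = jpeg::readJPEG(path),
    stop("unsupported image format: .", ext, " (expected png, tiff or jpg)",
         call. = FALSE)
  )
  # readers already scale to [0,1]; recover the source depth from the file
  bits <- 8L
  if (ext %in% c("tif", "tiff")) {
    info <- try(attr(px, "bits.per.sample"), silent = TRUE)
    if (is.numeric(info) && length(info) >= 1 && info[1] == 16) bits <- 16L
    # r-tiff does not attach depth by default; infer from value granularity
    if (is.null(info)) {
      q8 <- px * 255
      if (max(abs(q8 - round(q8))) > 1e-6) bits <- 16L
    }
  } else if (ext == "png") {
    q8 <- px * 255
    if (max(abs(q8 - round(q8))) > 1e-6) bits <- 16L
  }
  if (is.matrix(px)) dim(px) <- c(dim(px), 1L)
  nc <- dim(px)[3]
  if (nc %in% c(2L, 4L)) {
    warning("dropping alpha channel of ", path, call. = FALSE)
    px <- px[, , seq_len(nc - 1L), drop = FALSE]
    nc <- dim(px)[3]
  }
  if (!nc %in% c(1L, 3L)) {
    stop("unsupported channel count ", nc, " in ", path, call. = FALSE)
  }
  image_raster(px, source_bit_depth = bits)
}

#' Write a raster image to disk
#'
#' Intensities are quantized as `round(v * (2^bit_depth - 1))`; reading the
#' file back yields values within one quantization step of the original.
#'
#' @param raster An `image_raster`.
#' @param path Output path; the extension picks the format (PNG default,
#'   TIFF supported; JPEG is lossy and refused for exactness).
#' @param bit_depth 8 or 16 (16-bit requires TIFF output).
#' @return `path`, invisibly.
#' @export
write_image <- function(raster, path, bit_depth = 8L) {
  if (!is_image_raster(raster)) raster <- image_raster(raster)
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16", call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  px <- unclass(raster)
  attributes(px)$source_bit_depth <- NULL
  if (dim(px)[3] == 1L) dim(px) <- dim(px)[1:2]
  # quantize explicitly so the on-disk levels are round(v * maxval)
  maxval <- 2^bit_depth - 1
  q <- round(px * maxval) / maxval
  switch(ext,
    png = {
      if (bit_depth == 16L) {
        stop("16-bit output requires TIFF (.tif); PNG is written at 8 bits",
             call. = FALSE)
      }
      png::writePNG(q, target = path)
    },
    tif = ,
    tiff = {
      tiff::writeTIFF(q, where = path,
                      bits.per.sample = as.integer(bit_depth))
    },
    stop("unsupported output format: .", ext, " (use png or tiff)",
         call. = FALSE)
  )
  if (!file.exists(path)) stop("could not write ", path, call. = FALSE)
  invisible(path)
}

#' Reduce an image to a single channel
#'
#' RGB images are reduced by the unweighted channel mean (the convention
#' used for activity maps and metric inputs); gray images pass through
#' unchanged.
#'
#' @param raster An `image_raster` (1 or 3 channels).
#' @return A 1-channel `image_raster`.
#' @export
to_single_channel <- function(raster) {
  if (!is_image_raster(raster)) raster <- image_raster(raster)
  if (raster_channels(raster) == 1L) return(raster)
  m <- (raster[, , 1] + raster[, , 2] + raster[, , 3]) / 3
  image_raster(m, source_bit_depth = attr(raster, "source_bit_depth"))
}

#' Extract the single-channel plane of a raster as a plain matrix
#'
#' Convenience accessor used throughout the fusion pipeline and metrics:
#' multi-channel rasters are first reduced via [to_single_channel()].
#'
#' @param x An `image_raster`, matrix, or plane-like array.
#' @return A numeric matrix.
#' @export
as_plane <- function(x) {
  if (is_image_raster(x)) {
    x <- to_single_channel(x)
    m <- x[, , 1]
    return(m)
  }
  if (is.matrix(x)) return(x)
  if (is.array(x) && length(dim(x)) == 3L) {
    if (dim(x)[3] == 1L) return(x[, , 1])
    return(as_plane(image_raster(x)))
  }
  stop("cannot interpret input as an image plane", call. = FALSE)
}
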