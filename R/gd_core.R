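#' GD fusion configuration
#'
#' The method has two control parameters: the Gaussian window half-size `s`
#' (window side `2s + 1`) and its spread `sigma`. The conventional presets
#' tie the spread to the size as `sigma = s / 3`.
#'
#' @param s Integer half-size of the Gaussian window, `>= 1`.
#' @param sigma Positive spread, or `"auto"` for `s / 3`.
#' @param magnitude_rule How column/row differences combine into one edge
#'   magnitude: `"euclidean"` (`sqrt(cd^2 + rd^2)`, default), `"sum_abs"`
#'   (`|cd| + |rd|`) or `"sum_sq"` (`cd^2 + rd^2`).
#' @param boundary Out-of-image handling for differences and smoothing:
#'   `"replicate"` (default) or `"zero"`.
#' @return A `gd_config` list with the effective sigma resolved.
#' @export
gd_config <- function(s = 10L, sigma = "auto",
                      magnitude_rule = c("euclidean", "sum_abs", "sum_sq"),
                      boundary = c("replicate", "zero")) {
  magnitude_rule <- match.arg(magnitude_rule)
  boundary <- match.arg(boundary)
  if (!is.numeric(s) || length(s) != 1L || s < 1 || s != round(s)) {
    stop("`s` must be a single integer >= 1", call. = FALSE)
  }
  auto <- identical(sigma, "auto")
  if (auto) sigma <- s / 3
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop("`sigma` must be a positive number or \"auto\"", call. = FALSE)
  }
  structure(list(s = as.integer(s), sigma = as.numeric(sigma),
                 sigma_auto = auto,
                 magnitude_rule = magnitude_rule, boundary = boundary),
            class = "gd_config")
}

#' Named GD parameter presets
#'
#' `gd5`, `gd10` and `gd15` are the standard predefined parameter sets
#' `(s, sigma) = (5, 1.6)`, `(10, 3.3)` and `(15, 5)` — the spread stored
#' as conventionally printed, i.e. `s/3` rounded to one decimal.
#'
#' @param name One of `"gd5"`, `"gd10"`, `"gd15"`.
#' @inheritParams gd_config
#' @return A `gd_config`.
#' @export
gd_preset <- function(name = c("gd10", "gd5", "gd15"),
                      magnitude_rule = "euclidean", boundary = "replicate") {
  name <- match.arg(tolower(name), c("gd10", "gd5", "gd15"))
  par <- switch(name,
    gd5 = list(s = 5L, sigma = 1.6),
    gd10 = list(s = 10L, sigma = 3.3),
    gd15 = list(s = 15L, sigma = 5))
  gd_config(s = par$s, sigma = par$sigma,
            magnitude_rule = magnitude_rule, boundary = boundary)
}

# ---- padding / convolution helpers ------------------------------------------

# Pad a matrix by `s` on every side. replicate: clamp indices to the edge
# (works for any s, even wider than the image); zero: zero fill.
pad_matrix <- function(x, s, boundary = "replicate") {
  if (s == 0L) return(x)
  n <- nrow(x); m <- ncol(x)
  if (boundary == "replicate") {
    ri <- pmin(pmax(seq_len(n + 2L * s) - s, 1L), n)
    ci <- pmin(pmax(seq_len(m + 2L * s) - s, 1L), m)
    x[ri, ci, drop = FALSE]
  } else {
    out <- matrix(0, n + 2L * s, m + 2L * s)
    out[s + seq_len(n), s + seq_len(m)] <- x
    out
  }
}

# Separable correlation of a matrix with a symmetric 1-d kernel g of length
# 2s+1 (row pass then column pass), same-size output. Symmetric kernels make
# correlation and convolution identical.
conv_sep <- function(x, g, boundary = "replicate") {
  s <- (length(g) - 1L) %/% 2L
  if (s == 0L) return(x * g)
  n <- nrow(x); m <- ncol(x)
  xp <- pad_matrix(x, s, boundary)
  # rows pass (vertical): accumulate shifted row-blocks
  tmp <- matrix(0, n, m + 2L * s)
  for (p in seq_along(g)) {
    tmp <- tmp + g[p] * xp[(p - 1L) + seq_len(n), , drop = FALSE]
  }
  out <- matrix(0, n, m)
  for (r in seq_along(g)) {
    out <- out + g[r] * tmp[, (r - 1L) + seq_len(m), drop = FALSE]
  }
  out
}

# Full (non-separable) correlation with a (2s+1)^2 coefficient matrix;
# used for Sobel-type kernels and as the general path.
conv2_full <- function(x, coef, boundary = "replicate") {
  s <- (nrow(coef) - 1L) %/% 2L
  n <- nrow(x); m <- ncol(x)
  xp <- pad_matrix(x, s, boundary)
  out <- matrix(0, n, m)
  for (p in seq_len(nrow(coef))) {
    for (r in seq_len(ncol(coef))) {
      if (coef[p, r] == 0) next
      out <- out + coef[p, r] *
        xp[(p - 1L) + seq_len(n), (r - 1L) + seq_len(m), drop = FALSE]
    }
  }
  out
}

# ---- pipeline steps ----------------------------------------------------------

#' Column and row differences of an image plane
#'
#' First-order adjacent-pixel differences: `cd(i,j) = I(i,j) - I(i,j+1)` and
#' `rd(i,j) = I(i,j) - I(i+1,j)`. The last column of `cd` / last row of `rd`
#' has no right/lower neighbor; under `"replicate"` that neighbor equals the
#' edge pixel, giving a zero difference, while `"zero"` treats the outside
#' as black.
#'
#' @param plane Single-channel `image_raster` or matrix.
#' @param boundary `"replicate"` (default) or `"zero"`.
#' @return A `difference_pair` list with matrices `cd` and `rd`.
#' @export
directional_differences <- function(plane, boundary = c("replicate", "zero")) {
  boundary <- match.arg(boundary)
  if (is_image_raster(plane) && raster_channels(plane) > 1L) {
    stop("directional_differences() needs a single-channel plane; ",
         "reduce with to_single_channel() first", call. = FALSE)
  }
  x <- as_plane(plane)
  n <- nrow(x); m <- ncol(x)
  cd <- matrix(0, n, m)
  rd <- matrix(0, n, m)
  cd[, -m] <- x[, -m, drop = FALSE] - x[, -1L, drop = FALSE]
  rd[-n, ] <- x[-n, , drop = FALSE] - x[-1L, , drop = FALSE]
  if (boundary == "zero") {
    cd[, m] <- x[, m]
    rd[n, ] <- x[n, ]
  }
  structure(list(cd = cd, rd = rd), class = "difference_pair")
}

#' Combine directional differences into an edge magnitude
#'
#' @param pair A `difference_pair` from [directional_differences()].
#' @param rule `"euclidean"` (gradient magnitude, default), `"sum_abs"` or
#'   `"sum_sq"`.
#' @return A non-negative matrix of per-pixel edge magnitudes.
#' @export
edge_magnitude <- function(pair, rule = c("euclidean", "sum_abs", "sum_sq")) {
  rule <- match.arg(rule)
  if (!identical(dim(pair$cd), dim(pair$rd))) {
    stop("cd and rd must have the same shape", call. = FALSE)
  }
  switch(rule,
    euclidean = sqrt(pair$cd^2 + pair$rd^2),
    sum_abs = abs(pair$cd) + abs(pair$rd),
    sum_sq = pair$cd^2 + pair$rd^2)
}

#' Sampled Gaussian weighting window
#'
#' Coefficients proportional to `exp(-(x^2 + y^2) / (2 sigma^2))` at integer
#' offsets in `[-s, s]^2`, normalized to unit sum. The center holds the
#' maximum weight and the window is symmetric in both axes.
#'
#' @param s Non-negative integer half-size; window side is `2s + 1`.
#' @param sigma Positive spread.
#' @return A `gaussian_kernel` list: `s`, `sigma`, the `coefficients`
#'   matrix, and the normalized 1-d factor `g1d` (the window is separable:
#'   `coefficients == outer(g1d, g1d)`).
#' @export
gaussian_kernel <- function(s, sigma) {
  if (!is.numeric(s) || length(s) != 1L || s < 0 || s != round(s)) {
    stop("`s` must be a single integer >= 0", call. = FALSE)
  }
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop("`sigma` must be > 0", call. = FALSE)
  }
  s <- as.integer(s)
  off <- seq(-s, s)
  g <- exp(-off^2 / (2 * sigma^2))
  g <- g / sum(g)
  structure(list(s = s, sigma = sigma, g1d = g,
                 coefficients = outer(g, g)),
            class = "gaussian_kernel")
}

#' Smooth an edge-magnitude map with a Gaussian window
#'
#' `gd(i,j) = sum_{p,r in [-s,s]} w(p,r) d(i+p, j+r)`, out-of-bounds
#' neighbors supplied by the boundary rule.
#'
#' @param dmap Non-negative matrix of edge magnitudes.
#' @param kernel A `gaussian_kernel`.
#' @param boundary `"replicate"` (default) or `"zero"`.
#' @return Matrix of smoothed (non-negative) edge responses, same shape.
#' @export
smooth_differences <- function(dmap, kernel,
                               boundary = c("replicate", "zero")) {
  boundary <- match.arg(boundary)
  if (!inherits(kernel, "gaussian_kernel")) {
    stop("`kernel` must come from gaussian_kernel()", call. = FALSE)
  }
  if (2L * kernel$s + 1L > 2L * min(dim(dmap)) + 1L) {
    warning("kernel window (", 2L * kernel$s + 1L,
            ") much wider than the image; result dominated by boundary rule",
            call. = FALSE)
  }
  out <- conv_sep(dmap, kernel$g1d, boundary)
  pmax(out, 0)
}

#' Normalize smoothed responses into per-pixel fusion weights
#'
#' At each pixel the K responses are divided by their sum, so weights are
#' convex coefficients summing to one regardless of how many input images
#' exist. Pixels where all responses vanish (below `1e-12`) fall back to the
#' uniform weight `1/K`.
#'
#' @param gds List of `K >= 2` equally shaped smoothed response matrices.
#' @return List of K weight matrices in `[0, 1]` summing to 1 per pixel.
#' @export
normalize_weights <- function(gds) {
  if (!is.list(gds) || length(gds) < 2L) {
    stop("need K >= 2 smoothed maps", call. = FALSE)
  }
  dims <- lapply(gds, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    stop("smoothed maps must share one shape", call. = FALSE)
  }
  K <- length(gds)
  denom <- Reduce(`+`, gds)
  flat <- denom < 1e-12
  denom[flat] <- 1
  fw <- lapply(gds, function(g) {
    w <- g / denom
    w[flat] <- 1 / K
    pmin(pmax(w, 0), 1)
  })
  fw
}

#' Fuse an image stack with per-pixel weight maps
#'
#' `F(i,j) = sum_k fw_k(i,j) I_k(i,j)`, applied to every channel with the
#' same per-image weight map; the result is a per-pixel convex combination
#' of the inputs.
#'
#' @param stack An `image_stack`.
#' @param weights List of K weight matrices (one per image).
#' @return An `image_raster` of the fused image.
#' @export
fuse <- function(stack, weights) {
  if (!inherits(stack, "image_stack")) stack <- image_stack(stack)
  if (length(weights) != length(stack)) {
    stop("need one weight map per image (K mismatch)", call. = FALSE)
  }
  d <- dim(stack[[1]])
  if (!identical(dim(weights[[1]]), d[1:2])) {
    stop("weight maps must match the image planes in shape", call. = FALSE)
  }
  out <- array(0, d)
  for (k in seq_along(stack)) {
    for (ch in seq_len(d[3])) {
      out[, , ch] <- out[, , ch] + weights[[k]] * stack[[k]][, , ch]
    }
  }
  # guard against floating-point drift only
  image_raster(pmin(pmax(out, 0), 1),
               source_bit_depth = attr(stack[[1]], "source_bit_depth"))
}

#' Gaussian-of-differences image fusion
#'
#' The full pixel-domain pipeline: each source is reduced to a single
#' channel for the activity measure, first-order column/row differences are
#' combined into an edge magnitude, smoothed with a Gaussian window, and
#' the smoothed responses are normalized across images into convex weight
#' maps that linearly blend the original (possibly multi-channel)
#' intensities.
#'
#' @param stack An `image_stack` (or list of rasters/matrices), `K >= 2`.
#' @param config A `gd_config`; defaults to the `gd10` preset rule
#'   `s = 10, sigma = "auto"`.
#' @return A `gd_fusion` object: `pixels` (`image_raster` of the fused
#'   image), `weights` (list of K matrices), `activity` (list of smoothed
#'   maps) and the resolved `config`.
#' @examples
#' a <- matrix(seq(0, 1, length.out = 64 * 64), 64, 64)
#' b <- t(a)
#' fz <- gd_fuse(image_stack(image_raster(a), image_raster(b)),
#'               gd_config(s = 5, sigma = "auto"))
#' range(fz$pixels)
#' @export
gd_fuse <- function(stack, config = gd_config()) {
  if (!inherits(stack, "image_stack")) stack <- image_stack(stack)
  if (!inherits(config, "gd_config")) stop("`config` must be a gd_config",
                                           call. = FALSE)
  kern <- gaussian_kernel(config$s, config$sigma)
  gds <- lapply(stack, function(im) {
    plane <- as_plane(im)
    pr <- directional_differences(plane, boundary = config$boundary)
    d <- edge_magnitude(pr, rule = config$magnitude_rule)
    smooth_differences(d, kern, boundary = config$boundary)
  })
  fw <- normalize_weights(gds)
  fused <- fuse(stack, fw)
  structure(list(pixels = fused, weights = fw, activity = gds,
                 config = config),
            class = "gd_fusion")
}

#' @export
print.gd_fusion <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<gd_fusion> %d x %d x %d, K = %d, s = %d, sigma = %.4g\n",
              d[1], d[2], d[3], length(x$weights),
              x$config$s, x$config$sigma))
  invisible(x)
}
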