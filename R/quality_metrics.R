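# Nine objective fusion-quality metrics and the average-rank aggregation.
# All metrics are defined on gray-level images: multi-channel inputs are
# reduced by the unweighted channel mean first. Information-theoretic
# metrics quantize the unit range to the 256 levels round(v * 255);
# amplitude-based metrics (PSNR, SSIM, Qcb, Qcv) work on the 0..255 scale.

quantize256 <- function(x) {
  as.integer(round(pmin(pmax(as_plane(x), 0), 1) * 255))
}

hist256 <- function(q) {
  tabulate(q + 1L, nbins = 256L) / length(q)
}

metric_planes <- function(stack, fused) {
  if (!inherits(stack, "image_stack")) stack <- image_stack(stack)
  list(inputs = lapply(stack, as_plane), fused = as_plane(fused))
}

#' Shannon entropy of an image (bits)
#'
#' Intensities are quantized to 256 gray levels; entropy is
#' `-sum h * log2(h)` over non-empty histogram bins, so values lie in
#' `[0, 8]` bits. Higher means more information content.
#'
#' @param img `image_raster` or matrix on the unit range.
#' @return Entropy in bits.
#' @export
metric_entropy <- function(img) {
  h <- hist256(quantize256(img))
  h <- h[h > 0]
  -sum(h * log2(h))
}

mi_pair <- function(qa, qf) {
  n <- length(qa)
  joint <- tabulate(qa * 256L + qf + 1L, nbins = 256L * 256L) / n
  pa <- hist256(qa)
  pf <- hist256(qf)
  nz <- which(joint > 0)
  u <- ((nz - 1L) %/% 256L) + 1L
  v <- ((nz - 1L) %% 256L) + 1L
  sum(joint[nz] * log2(joint[nz] / (pa[u] * pf[v])))
}

#' Mutual information between the sources and the fused image (bits)
#'
#' Sum over the input images of the pairwise mutual information with the
#' fused image, from 256-level joint histograms, log base 2. Higher is
#' better; for `F` identical to an input the pair contributes that input's
#' entropy.
#'
#' @param stack `image_stack` of sources.
#' @param fused Fused `image_raster`.
#' @param aggregate `"sum"` (conventional for fusion tables) or `"mean"`.
#' @return Mutual information in bits.
#' @export
metric_mi <- function(stack, fused, aggregate = c("sum", "mean")) {
  aggregate <- match.arg(aggregate)
  pl <- metric_planes(stack, fused)
  qf <- quantize256(pl$fused)
  vals <- vapply(pl$inputs, function(p) mi_pair(quantize256(p), qf),
                 numeric(1))
  if (aggregate == "sum") sum(vals) else mean(vals)
}

#' Peak signal-to-noise ratio of the fusion (dB)
#'
#' Mean squared error against each input on the 0..255 gray scale, averaged
#' over inputs; `PSNR = 10 log10(255^2 / MSE)`. A fused image identical to
#' every input has zero error and is capped at 100 dB so the value stays
#' finite and sortable.
#'
#' @inheritParams metric_mi
#' @return PSNR in decibels, capped at 100.
#' @export
metric_psnr <- function(stack, fused) {
  pl <- metric_planes(stack, fused)
  mses <- vapply(pl$inputs,
                 function(p) mean((255 * (p - pl$fused))^2), numeric(1))
  mse <- mean(mses)
  if (mse <= 0) return(100)
  min(10 * log10(255^2 / mse), 100)
}

#' Sigmoid constants of the edge-preservation model
#'
#' The published edge-information preservation model maps relative gradient
#' strength and orientation agreement through sigmoids with these
#' constants; they are exposed here rather than hard-coded.
#'
#' @return Named list: `gamma_g`, `kappa_g`, `sigma_g` (strength sigmoid),
#'   `gamma_a`, `kappa_a`, `sigma_a` (orientation sigmoid), `L` (weight
#'   exponent).
#' @export
qabf_constants <- function() {
  list(gamma_g = 0.9994, kappa_g = -15, sigma_g = 0.5,
       gamma_a = 0.9879, kappa_a = -22, sigma_a = 0.8,
       L = 1)
}

sobel_features <- function(p) {
  sx <- conv2_full(p, matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3),
                   boundary = "replicate")
  sy <- conv2_full(p, matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3),
                   boundary = "replicate")
  g <- sqrt(sx^2 + sy^2)
  a <- atan(sy / sx)
  a[sx == 0] <- pi / 2
  list(g = g, a = a)
}

#' Edge-based fusion quality Qabf
#'
#' Measures how much of each source's gradient strength and orientation
#' survives in the fused image. Per pixel, the relative strength (smaller
#' over larger gradient magnitude) and the orientation agreement are mapped
#' through sigmoids and multiplied into a preservation score, then averaged
#' with the source gradient magnitudes as weights.
#'
#' @param a,b Source planes (`image_raster` or matrix).
#' @param fused Fused plane.
#' @param constants Sigmoid constants, see [qabf_constants()].
#' @param saturate_one If `TRUE` (default) the score is rescaled by the
#'   sigmoids' value at perfect preservation, so a fused image identical to
#'   both sources scores exactly 1. `FALSE` gives the literal published
#'   model, which saturates slightly below 1.
#' @return Score in `[0, 1]`; 0 by convention when all images are constant.
#' @export
metric_qabf <- function(a, b, fused, constants = qabf_constants(),
                        saturate_one = TRUE) {
  pa <- as_plane(a); pb <- as_plane(b); pf <- as_plane(fused)
  fa <- sobel_features(pa * 255)
  fb <- sobel_features(pb * 255)
  ff <- sobel_features(pf * 255)
  cst <- constants
  pres <- function(fs, ft) {
    # relative gradient strength: ratio of smaller to larger, 0 where both 0
    hi <- pmax(fs$g, ft$g)
    lo <- pmin(fs$g, ft$g)
    G <- ifelse(hi > 0, lo / hi, 0)
    A <- 1 - abs(fs$a - ft$a) / (pi / 2)
    Qg <- cst$gamma_g / (1 + exp(cst$kappa_g * (G - cst$sigma_g)))
    Qa <- cst$gamma_a / (1 + exp(cst$kappa_a * (A - cst$sigma_a)))
    Qg * Qa
  }
  qaf <- pres(fa, ff)
  qbf <- pres(fb, ff)
  wa <- fa$g^cst$L
  wb <- fb$g^cst$L
  denom <- sum(wa) + sum(wb)
  if (denom == 0) return(0)
  val <- sum(qaf * wa + qbf * wb) / denom
  if (saturate_one) {
    qmax <- (cst$gamma_g / (1 + exp(cst$kappa_g * (1 - cst$sigma_g)))) *
      (cst$gamma_a / (1 + exp(cst$kappa_a * (1 - cst$sigma_a))))
    val <- val / qmax
  }
  min(val, 1)
}

ssim_window <- function(size = 11L, sigma = 1.5) {
  off <- seq(-(size - 1L) / 2, (size - 1L) / 2)
  g <- exp(-off^2 / (2 * sigma^2))
  g / sum(g)
}

#' Structural similarity between two image planes
#'
#' Standard single-scale SSIM with an 11x11 Gaussian window (sigma 1.5) and
#' stabilizers `c1 = (0.01*255)^2`, `c2 = (0.03*255)^2` on the 0..255
#' scale, averaged over the valid (un-padded) window positions.
#'
#' @param x,y Planes on the unit range.
#' @return SSIM index in `[-1, 1]`.
#' @export
ssim_pair <- function(x, y) {
  px <- as_plane(x) * 255
  py <- as_plane(y) * 255
  g <- ssim_window()
  s <- (length(g) - 1L) %/% 2L
  n <- nrow(px); m <- ncol(px)
  if (n < 2L * s + 1L || m < 2L * s + 1L) {
    stop("image smaller than the 11x11 SSIM window", call. = FALSE)
  }
  valid <- function(z) z[(s + 1L):(n - s), (s + 1L):(m - s), drop = FALSE]
  f <- function(z) valid(conv_sep(z, g, boundary = "replicate"))
  mx <- f(px); my <- f(py)
  vx <- f(px^2) - mx^2
  vy <- f(py^2) - my^2
  vxy <- f(px * py) - mx * my
  c1 <- (0.01 * 255)^2
  c2 <- (0.03 * 255)^2
  map <- ((2 * mx * my + c1) * (2 * vxy + c2)) /
    ((mx^2 + my^2 + c1) * (vx + vy + c2))
  mean(map)
}

#' Fusion SSIM: summed structural similarity against the sources
#'
#' `sum_k SSIM(I_k, F)`; with two sources a perfect fusion of identical
#' inputs scores 2. Higher is better.
#'
#' @inheritParams metric_mi
#' @param aggregate `"sum"` (conventional; table magnitudes near 2) or
#'   `"mean"`.
#' @return Summed (or mean) SSIM.
#' @export
metric_ssim <- function(stack, fused, aggregate = c("sum", "mean")) {
  aggregate <- match.arg(aggregate)
  pl <- metric_planes(stack, fused)
  vals <- vapply(pl$inputs, function(p) ssim_pair(p, pl$fused), numeric(1))
  if (aggregate == "sum") sum(vals) else mean(vals)
}

# ---- perceptual metrics (contrast-sensitivity based) ------------------------

# Mannos-Sakrison contrast sensitivity, f in cycles/degree.
csf_mannos <- function(f) {
  2.6 * (0.0192 + 0.114 * f) * exp(-(0.114 * f)^1.1)
}

# Filter a matrix in the frequency domain with a radially symmetric CSF.
# pixels_per_degree maps discrete frequency (cycles/pixel) to cycles/degree.
csf_filter <- function(x, pixels_per_degree = 32) {
  n <- nrow(x); m <- ncol(x)
  fu <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)[seq_len(n)] / n
  fv <- c(0:floor(m / 2), -(ceiling(m / 2) - 1):-1)[seq_len(m)] / m
  r <- sqrt(outer(fu^2, fv^2, `+`)) * pixels_per_degree
  s <- csf_mannos(r)
  Re(stats::fft(stats::fft(x) * s, inverse = TRUE)) / (n * m)
}

gauss_blur <- function(x, sigma, half = NULL) {
  if (is.null(half)) half <- max(1L, ceiling(3 * sigma))
  off <- seq(-half, half)
  g <- exp(-off^2 / (2 * sigma^2))
  conv_sep(x, g / sum(g), boundary = "replicate")
}

#' Parameters of the perceptual contrast model
#'
#' Settings shared by the Chen-Blum and Chen-Varshney metrics: the
#' frequency mapping of the contrast-sensitivity filter, the two Gaussian
#' scales of the local band-limited contrast, the contrast-masking
#' exponents, and the Chen-Varshney window/saliency settings.
#'
#' @param pixels_per_degree Visual resolution assumed when mapping image
#'   frequency to cycles per degree (default 32).
#' @param contrast_sigmas Center/surround Gaussian spreads of the local
#'   contrast (default `c(2, 4)`).
#' @param mask_k,mask_h,mask_p,mask_q,mask_z Contrast-masking constants
#'   (defaults 1, 1, 3, 2, 1e-4).
#' @param window Square window side for the region-based metric
#'   (default 16).
#' @param saliency_exponent Exponent on local edge strength in the region
#'   saliency (default 2).
#' @return Named list of settings.
#' @export
perceptual_params <- function(pixels_per_degree = 32,
                              contrast_sigmas = c(2, 4),
                              mask_k = 1, mask_h = 1,
                              mask_p = 3, mask_q = 2, mask_z = 1e-4,
                              window = 16L, saliency_exponent = 2) {
  list(pixels_per_degree = pixels_per_degree,
       contrast_sigmas = contrast_sigmas,
       mask_k = mask_k, mask_h = mask_h,
       mask_p = mask_p, mask_q = mask_q, mask_z = mask_z,
       window = as.integer(window),
       saliency_exponent = saliency_exponent)
}

masked_contrast <- function(p, params) {
  x <- csf_filter(p, params$pixels_per_degree)
  lo1 <- gauss_blur(x, params$contrast_sigmas[1])
  lo2 <- gauss_blur(x, params$contrast_sigmas[2])
  c0 <- ifelse(abs(lo2) > 1e-12, lo1 / lo2 - 1, 0)
  ac <- abs(c0)
  (params$mask_k * ac^params$mask_p) /
    (params$mask_h * ac^params$mask_q + params$mask_z)
}

#' Chen-Blum perceptual fusion quality Qcb
#'
#' Referenceless, human-perception-inspired metric: images are filtered
#' with a contrast-sensitivity function, local band-limited contrast is
#' computed from a center/surround Gaussian pair and passed through a
#' contrast-masking nonlinearity; the per-pixel preservation of masked
#' contrast in the fused image is weighted by the sources' relative
#' contrast saliency and averaged. Higher is better; identical images
#' score 1.
#'
#' @inheritParams metric_qabf
#' @param params See [perceptual_params()].
#' @return Score in `[0, 1]`.
#' @export
metric_qcb <- function(a, b, fused, params = perceptual_params()) {
  ca <- masked_contrast(as_plane(a) * 255, params)
  cb <- masked_contrast(as_plane(b) * 255, params)
  cf <- masked_contrast(as_plane(fused) * 255, params)
  ratio <- function(cs, ct) {
    hi <- pmax(cs, ct)
    lo <- pmin(cs, ct)
    ifelse(hi > 0, lo / hi, 1)   # both zero: nothing lost
  }
  qaf <- ratio(ca, cf)
  qbf <- ratio(cb, cf)
  tot <- ca^2 + cb^2
  lam_a <- ifelse(tot > 0, ca^2 / tot, 0.5)
  lam_b <- 1 - lam_a
  mean(lam_a * qaf + lam_b * qbf)
}

#' Cross entropy between source and fused histograms (bits)
#'
#' Kullback-Leibler divergence of each source's 256-level histogram from
#' the fused histogram, averaged over sources, log base 2. Zero when the
#' fused image carries the same intensity distribution as the sources;
#' lower is better. Empty fused bins are smoothed by `1e-12` so the value
#' stays finite.
#'
#' @inheritParams metric_mi
#' @return Cross entropy in bits.
#' @export
metric_ce <- function(stack, fused) {
  pl <- metric_planes(stack, fused)
  hf <- pmax(hist256(quantize256(pl$fused)), 1e-12)
  vals <- vapply(pl$inputs, function(p) {
    hi <- hist256(quantize256(p))
    nz <- hi > 0
    sum(hi[nz] * log2(hi[nz] / hf[nz]))
  }, numeric(1))
  mean(vals)
}

#' Root mean square error against the sources (unit intensity scale)
#'
#' Per-input RMSE averaged over the inputs; 0 when the fused image equals
#' every source, lower is better.
#'
#' @inheritParams metric_mi
#' @return RMSE on the unit intensity scale.
#' @export
metric_rmse <- function(stack, fused) {
  pl <- metric_planes(stack, fused)
  mean(vapply(pl$inputs,
              function(p) sqrt(mean((p - pl$fused)^2)), numeric(1)))
}

#' Chen-Varshney region-based fusion distortion Qcv
#'
#' The image is partitioned into square windows; each window's saliency is
#' its local edge energy (Sobel magnitude raised to the saliency exponent)
#' and its distortion is the mean squared CSF-filtered difference between
#' source and fused image. Qcv is the saliency-weighted mean distortion
#' over windows and sources; 0 for a perfect fusion, lower is better.
#'
#' @inheritParams metric_mi
#' @param params See [perceptual_params()].
#' @return Non-negative distortion score.
#' @export
metric_qcv <- function(stack, fused, params = perceptual_params()) {
  pl <- metric_planes(stack, fused)
  w <- params$window
  n <- nrow(pl$fused); m <- ncol(pl$fused)
  nb <- n %/% w; mb <- m %/% w
  if (nb < 1L || mb < 1L) {
    stop("image smaller than the ", w, "x", w, " analysis window",
         call. = FALSE)
  }
  block_sum <- function(z) {
    z <- z[seq_len(nb * w), seq_len(mb * w), drop = FALSE]
    rowgrp <- rep(seq_len(nb), each = w)
    colgrp <- rep(seq_len(mb), each = w)
    rowsum(t(rowsum(z, rowgrp)), colgrp)   # mb x nb sums
  }
  num <- 0
  den <- 0
  for (p in pl$inputs) {
    g <- sobel_features(p * 255)$g
    lam <- block_sum(g^params$saliency_exponent)
    d <- csf_filter((p - pl$fused) * 255, params$pixels_per_degree)
    dist <- block_sum(d^2) / (w * w)
    num <- num + sum(lam * dist)
    den <- den + sum(lam)
  }
  if (den == 0) return(0)
  num / den
}

#' Evaluate all nine fusion-quality metrics
#'
#' @inheritParams metric_mi
#' @param constants Qabf sigmoid constants ([qabf_constants()]).
#' @param params Perceptual-model settings ([perceptual_params()]).
#' @param saturate_one Passed to [metric_qabf()].
#' @return A `metric_report` data frame with columns `metric`, `value` and
#'   `higher_better`, one row per metric (EN, MI, PSNR, Qabf, SSIM, Qcb,
#'   CE, RMSE, Qcv). For stacks with more than two images the pairwise
#'   metrics (Qabf, Qcb) use the first two inputs, with a warning.
#' @export
evaluate_all <- function(stack, fused, constants = qabf_constants(),
                         params = perceptual_params(),
                         saturate_one = TRUE) {
  if (!inherits(stack, "image_stack")) stack <- image_stack(stack)
  if (length(stack) > 2L) {
    warning("Qabf and Qcb are defined pairwise; using the first two inputs",
            call. = FALSE)
  }
  a <- stack[[1]]; b <- stack[[2]]
  values <- c(
    EN = metric_entropy(fused),
    MI = metric_mi(stack, fused),
    PSNR = metric_psnr(stack, fused),
    Qabf = metric_qabf(a, b, fused, constants, saturate_one),
    SSIM = metric_ssim(stack, fused),
    Qcb = metric_qcb(a, b, fused, params),
    CE = metric_ce(stack, fused),
    RMSE = metric_rmse(stack, fused),
    Qcv = metric_qcv(stack, fused, params)
  )
  report <- data.frame(
    metric = names(values),
    value = unname(values),
    higher_better = names(values) %in%
      c("EN", "MI", "PSNR", "Qabf", "SSIM", "Qcb"),
    stringsAsFactors = FALSE
  )
  class(report) <- c("metric_report", "data.frame")
  report
}

#' Metric orientations
#'
#' @return Named logical vector: `TRUE` where higher values indicate a
#'   better fusion (EN, MI, PSNR, Qabf, SSIM, Qcb), `FALSE` where lower is
#'   better (CE, RMSE, Qcv).
#' @export
metric_orientations <- function() {
  c(EN = TRUE, MI = TRUE, PSNR = TRUE, Qabf = TRUE, SSIM = TRUE, Qcb = TRUE,
    CE = FALSE, RMSE = FALSE, Qcv = FALSE)
}

#' Rank fusion methods by their metric scores
#'
#' Per metric, methods are ranked 1 = best respecting the metric's
#' orientation, ties receiving averaged ranks; the per-method ranks are
#' then averaged across metrics.
#'
#' @param scores Data frame or matrix, one row per method, one column per
#'   metric; method names from a `method` column or row names.
#' @param higher_better Named logical vector over the metric columns
#'   (defaults from [metric_orientations()] by column name).
#' @return A `ranking_table` data frame: `method`, one rank column per
#'   metric, and `avg_rank`, sorted best first.
#' @export
rank_methods <- function(scores, higher_better = NULL) {
  scores <- as.data.frame(scores)
  if ("method" %in% names(scores)) {
    methods <- as.character(scores$method)
    scores$method <- NULL
  } else {
    methods <- rownames(scores)
    if (is.null(methods)) methods <- paste0("method", seq_len(nrow(scores)))
  }
  if (!all(vapply(scores, is.numeric, logical(1)))) {
    stop("all metric columns must be numeric", call. = FALSE)
  }
  if (any(!is.finite(as.matrix(scores)))) {
    stop("non-finite metric values cannot be ranked", call. = FALSE)
  }
  if (is.null(higher_better)) {
    ori <- metric_orientations()
    if (!all(names(scores) %in% names(ori))) {
      stop("unknown metric columns; supply `higher_better` explicitly",
           call. = FALSE)
    }
    higher_better <- ori[names(scores)]
  }
  higher_better <- higher_better[names(scores)]
  ranks <- mapply(function(col, hb) {
    rank(if (hb) -col else col, ties.method = "average")
  }, scores, higher_better, SIMPLIFY = TRUE)
  ranks <- matrix(ranks, nrow = nrow(scores),
                  dimnames = list(NULL, names(scores)))
  out <- data.frame(method = methods, ranks, check.names = FALSE,
                    stringsAsFactors = FALSE)
  out$avg_rank <- rowMeans(ranks)
  out <- out[order(out$avg_rank), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ranking_table", "data.frame")
  out
}

#' Write a metric report to JSON or CSV
#'
#' @param report A `metric_report` from [evaluate_all()].
#' @param path Output file; format from the extension unless given.
#' @param format `"json"` or `"csv"` (default from extension).
#' @return `path`, invisibly.
#' @export
write_metric_report <- function(report, path,
                                format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) == "csv") "csv" else "json"
  }
  if (format == "csv") {
    utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  } else {
    vals <- stats::setNames(as.list(report$value), report$metric)
    jsonlite::write_json(
      list(metrics = vals,
           higher_better = stats::setNames(as.list(report$higher_better),
                                           report$metric)),
      path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
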