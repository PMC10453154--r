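# Seeded generators of co-registered test stacks emulating the four
# application regimes (multi-modal medical, infrared-visible, multi-focus,
# multi-exposure), with ground truth, so the pipeline is testable without
# external datasets.

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic fixture stack
#'
#' @param scenario One of `"multifocus"`, `"multiexposure"`, `"multimodal"`,
#'   `"irvisible"`.
#' @param size `(height, width)`, each at least 32 (default 128x128: large
#'   enough for an `s = 15` window, small enough for fast tests).
#' @param seed Integer; a fixed seed reproduces the stack bit for bit.
#' @param K Number of images (default 2; `multimodal`/`irvisible` are
#'   two-image scenarios).
#' @param blur_sigma Out-of-focus blur spread for `multifocus` (default 3).
#' @param stops Exposure shift in photographic stops for `multiexposure`
#'   (default 1.5; the bright member clips at white).
#' @param density Structure density of the base scene in `(0, 1]`
#'   (default 0.5).
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(scenario = c("multifocus", "multiexposure",
                                      "multimodal", "irvisible"),
                         size = c(128L, 128L), seed = 1L, K = 2L,
                         blur_sigma = 3, stops = 1.5, density = 0.5) {
  scenario <- match.arg(scenario)
  size <- as.integer(size)
  if (length(size) != 2L || any(size < 32L)) {
    stop("size must be (height, width) with both >= 32", call. = FALSE)
  }
  if (K < 2L) stop("K must be >= 2", call. = FALSE)
  if (scenario %in% c("multimodal", "irvisible") && K != 2L) {
    stop(scenario, " fixtures are defined for K = 2", call. = FALSE)
  }
  structure(list(scenario = scenario, size = size, seed = as.integer(seed),
                 K = as.integer(K), blur_sigma = blur_sigma, stops = stops,
                 density = density),
            class = "fixture_spec")
}

# Scene building blocks: smooth low-frequency background, geometric shapes
# (rectangles and disks with per-shape intensity), high-frequency texture
# patches. All randomness is drawn inside the caller-set seed.
scene_components <- function(spec) {
  h <- spec$size[1]; w <- spec$size[2]
  ii <- matrix(seq_len(h), h, w)
  jj <- matrix(seq_len(w), h, w, byrow = TRUE)
  # background: three low-frequency oriented cosine gratings
  bg <- matrix(0, h, w)
  for (g in 1:3) {
    th <- stats::runif(1, 0, pi)
    fr <- stats::runif(1, 0.5, 2) / max(h, w)
    ph <- stats::runif(1, 0, 2 * pi)
    bg <- bg + stats::runif(1, 0.3, 1) *
      cos(2 * pi * fr * (ii * cos(th) + jj * sin(th)) + ph)
  }
  bg <- (bg - min(bg)) / (max(bg) - min(bg)) * 0.5 + 0.2
  # shapes: masks with intensities
  nshape <- max(4L, round(10 * spec$density))
  shapes <- vector("list", nshape)
  for (k in seq_len(nshape)) {
    kind <- if (stats::runif(1) < 0.5) "rect" else "disk"
    cy <- stats::runif(1, 0.15, 0.85) * h
    cx <- stats::runif(1, 0.15, 0.85) * w
    rad <- stats::runif(1, 0.05, 0.16) * min(h, w)
    mask <- if (kind == "disk") {
      (ii - cy)^2 + (jj - cx)^2 <= rad^2
    } else {
      abs(ii - cy) <= rad & abs(jj - cx) <= rad * stats::runif(1, 0.6, 1.6)
    }
    shapes[[k]] <- list(mask = mask, value = stats::runif(1, 0, 1))
  }
  # texture patches: band-limited noise in two rectangles
  tex <- matrix(0, h, w)
  for (t in 1:2) {
    y0 <- floor(stats::runif(1, 0, 0.6) * h) + 1L
    x0 <- floor(stats::runif(1, 0, 0.6) * w) + 1L
    hh <- floor(0.3 * h); ww <- floor(0.3 * w)
    noise <- matrix(stats::rnorm(hh * ww), hh, ww)
    noise <- gauss_blur(noise, 0.8)
    ys <- y0:min(y0 + hh - 1L, h)
    xs <- x0:min(x0 + ww - 1L, w)
    tex[ys, xs] <- tex[ys, xs] + 0.12 * noise[seq_along(ys), seq_along(xs)]
  }
  list(bg = bg, shapes = shapes, tex = tex)
}

compose_scene <- function(comp, shape_idx = NULL) {
  x <- comp$bg
  idx <- if (is.null(shape_idx)) seq_along(comp$shapes) else shape_idx
  for (k in idx) {
    sh <- comp$shapes[[k]]
    # shapes blend over the background rather than replace it outright
    x[sh$mask] <- 0.25 * x[sh$mask] + 0.75 * sh$value
  }
  x <- x + comp$tex
  (x - min(x)) / (max(x) - min(x))
}

#' Generate the seeded ground-truth base scene
#'
#' A smooth low-frequency background, geometric shapes and high-frequency
#' texture patches, deterministic per seed, rescaled to span the unit
#' range.
#'
#' @param spec A [fixture_spec()].
#' @return A single-channel `image_raster` (the ground truth).
#' @export
make_base_scene <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    comp <- scene_components(spec)
    image_raster(compose_scene(comp))
  })
}

#' Generate a co-registered fixture stack with ground truth
#'
#' Degrades the seeded base scene according to the scenario:
#' \describe{
#'   \item{multifocus}{Each image is Gaussian-blurred outside its own
#'     vertical band (K = 2: image 1 blurred on the left half, image 2 on
#'     the right), so every image equals the ground truth exactly where it
#'     is sharp; masks mark each image's sharp region.}
#'   \item{multiexposure}{Exposure shifts of `+/- stops` photographic
#'     stops with clipping at white; the over-exposed member saturates,
#'     the under-exposed member buries shadow detail.}
#'   \item{multimodal}{Complementary structure subsets: each image shows
#'     only half of the scene's shapes (bone-like vs tissue-like
#'     contrast), the ground truth shows all.}
#'   \item{irvisible}{Image 1 emulates a thermal channel: a low-texture
#'     smoothed background with bright ("hot") objects where the scene's
#'     shapes sit; image 2 is the fully textured visible scene.}
#' }
#'
#' @param spec A [fixture_spec()].
#' @return A `fixture_stack` list: `stack` (`image_stack`), `truth`
#'   (`image_raster`), `masks` (per-image logical matrices marking where
#'   each image is informative/undegraded) and `spec`.
#' @export
make_stack <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    comp <- scene_components(spec)
    truth <- compose_scene(comp)
    h <- spec$size[1]; w <- spec$size[2]
    out <- switch(spec$scenario,
      multifocus = {
        blurred <- gauss_blur(truth, spec$blur_sigma)
        cuts <- floor(seq(0, w, length.out = spec$K + 1L))
        imgs <- vector("list", spec$K)
        masks <- vector("list", spec$K)
        for (k in seq_len(spec$K)) {
          # image 1 is blurred on the left (sharp rightmost band), image K
          # on the right, matching the left-blur/right-blur convention
          bk <- spec$K + 1L - k
          band <- (cuts[bk] + 1L):cuts[bk + 1L]
          img <- blurred
          img[, band] <- truth[, band]
          msk <- matrix(FALSE, h, w)
          msk[, band] <- TRUE
          imgs[[k]] <- img
          masks[[k]] <- msk
        }
        list(imgs = imgs, masks = masks)
      },
      multiexposure = {
        stops <- seq(spec$stops, -spec$stops, length.out = spec$K)
        imgs <- lapply(stops, function(st) pmin(truth * 2^st, 1))
        masks <- lapply(stops, function(st) truth * 2^st < 1)
        list(imgs = imgs, masks = masks)
      },
      multimodal = {
        ns <- length(comp$shapes)
        half <- seq_len(ceiling(ns / 2))
        other <- setdiff(seq_len(ns), half)
        # modality 1: bone-like, bright structures on a dark background
        c1 <- comp
        c1$bg <- 0.15 + 0.1 * (comp$bg - min(comp$bg))
        c1$tex <- comp$tex * 0.2
        for (k in half) c1$shapes[[k]]$value <- 0.85 + 0.15 * c1$shapes[[k]]$value
        img1 <- compose_scene(c1, half)
        # modality 2: tissue-like, textured mid-tones with the other shapes
        img2 <- compose_scene(comp, other)
        m1 <- Reduce(`|`, lapply(comp$shapes[half], `[[`, "mask"),
                     matrix(FALSE, h, w))
        m2 <- Reduce(`|`, lapply(comp$shapes[other], `[[`, "mask"),
                     matrix(FALSE, h, w))
        list(imgs = list(img1, img2), masks = list(m1, m2))
      },
      irvisible = {
        hot <- Reduce(`|`, lapply(comp$shapes, `[[`, "mask"),
                      matrix(FALSE, h, w))
        ir <- gauss_blur(truth, 4) * 0.35
        ir[hot] <- 0.9 + 0.1 * truth[hot]
        list(imgs = list(pmin(ir, 1), truth),
             masks = list(hot, !hot))
      })
    structure(list(stack = image_stack(lapply(out$imgs, image_raster)),
                   truth = image_raster(truth),
                   masks = out$masks, spec = spec),
              class = "fixture_stack")
  })
}

#' @export
print.fixture_stack <- function(x, ...) {
  cat(sprintf("<fixture_stack> %s, %d x %d, K = %d, seed = %d\n",
              x$spec$scenario, x$spec$size[1], x$spec$size[2],
              x$spec$K, x$spec$seed))
  invisible(x)
}
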