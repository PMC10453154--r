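test_that("directional differences match hand-evaluated cases", {
  # constant plane: no adjacent-pixel change anywhere
  dp <- directional_differences(matrix(0.5, 5, 5))
  expect_true(all(dp$cd == 0) && all(dp$rd == 0))
  # 2x2 hand case with replicate boundary
  dp <- directional_differences(matrix(c(0, 2, 1, 3), 2, 2))
  expect_equal(dp$cd, matrix(c(-1, -1, 0, 0), 2, 2))
  expect_equal(dp$rd, matrix(c(-2, 0, -2, 0), 2, 2))
  # horizontal ramp: constant column difference, zero row difference
  w <- 9L
  ramp <- matrix(rep((0:(w - 1)) / (w - 1), each = 6), 6, w)
  dp <- directional_differences(ramp)
  expect_equal(dp$cd[, 1:(w - 1)], matrix(-1 / (w - 1), 6, w - 1))
  expect_true(all(dp$cd[, w] == 0))
  expect_true(all(dp$rd == 0))
  expect_error(directional_differences(image_raster(array(0.1, c(4, 4, 3)))),
               "single-channel")
})

test_that("edge magnitude rules evaluate directly", {
  pair <- structure(list(cd = matrix(c(-1, 3), 1, 2),
                         rd = matrix(c(-2, 4), 1, 2)),
                    class = "difference_pair")
  expect_equal(edge_magnitude(pair, "euclidean"),
               matrix(c(sqrt(5), 5), 1, 2))
  expect_equal(edge_magnitude(pair, "sum_abs"), matrix(c(3, 7), 1, 2))
  expect_equal(edge_magnitude(pair, "sum_sq"), matrix(c(5, 25), 1, 2))
  expect_error(edge_magnitude(pair, "manhattan"))
  zero <- structure(list(cd = matrix(0, 3, 3), rd = matrix(0, 3, 3)),
                    class = "difference_pair")
  expect_true(all(edge_magnitude(zero) == 0))
})

test_that("gaussian kernel has the documented geometry", {
  k <- gaussian_kernel(3, 1)
  expect_equal(dim(k$coefficients), c(7L, 7L))
  expect_equal(sum(k$coefficients), 1)
  # symmetric under reflection and axis swap; center is the max
  expect_equal(k$coefficients, k$coefficients[7:1, 7:1])
  expect_equal(k$coefficients, t(k$coefficients))
  expect_equal(which.max(k$coefficients), 25L)  # (4,4) of 7x7
  # singleton normalizes to 1
  expect_equal(gaussian_kernel(0, 2)$coefficients, matrix(1, 1, 1))
  # center/corner ratio for s = 1, sigma = 1 is e
  k1 <- gaussian_kernel(1, 1)$coefficients
  expect_equal(k1[2, 2] / k1[1, 1], exp(1))
  expect_error(gaussian_kernel(2, 0), "sigma")
  expect_error(gaussian_kernel(-1, 1), ">= 0")
})

test_that("smoothing matches the brute-force convolution and keeps constants", {
  k <- gaussian_kernel(2, 1.2)
  cst <- matrix(0.37, 10, 10)
  expect_equal(smooth_differences(cst, k), cst, tolerance = 1e-12)
  # impulse response in the interior reproduces the kernel
  imp <- matrix(0, 9, 9); imp[5, 5] <- 1
  sm <- smooth_differences(imp, k)
  expect_equal(sm[3:7, 3:7], k$coefficients, tolerance = 1e-12)
  # random map equals the per-pixel double loop
  d <- rand_plane(8, 8, 7)
  got <- smooth_differences(d, k)
  ref <- matrix(0, 8, 8)
  for (i in 1:8) for (j in 1:8) {
    acc <- 0
    for (p in -2:2) for (r in -2:2) {
      acc <- acc + k$coefficients[p + 3, r + 3] *
        d[clamp_idx(i + p, 8L), clamp_idx(j + r, 8L)]
    }
    ref[i, j] <- acc
  }
  expect_lt(max(abs(got - ref)), 1e-12)
  expect_warning(smooth_differences(matrix(0.1, 3, 3), gaussian_kernel(8, 2)),
                 "wider")
})

test_that("weight normalization follows the worked example and fallbacks", {
  fw <- normalize_weights(list(matrix(2, 2, 2), matrix(3, 2, 2)))
  expect_equal(fw[[1]], matrix(0.4, 2, 2))
  expect_equal(fw[[2]], matrix(0.6, 2, 2))
  # identical maps share weight equally for any K
  fw3 <- normalize_weights(replicate(3, rand_plane(4, 4, 2) + 0.1,
                                     simplify = FALSE))
  for (w in fw3) expect_equal(w, matrix(1 / 3, 4, 4))
  # all-zero pixels fall back to uniform
  g1 <- matrix(0, 3, 3); g1[1, 1] <- 1
  g2 <- matrix(0, 3, 3); g2[1, 1] <- 3
  fw <- normalize_weights(list(g1, g2))
  expect_equal(fw[[1]][1, 1], 0.25)
  expect_equal(fw[[1]][2, 2], 0.5)
  expect_error(normalize_weights(list(matrix(1, 2, 2), matrix(1, 3, 3))),
               "shape")
  expect_error(normalize_weights(list(matrix(1, 2, 2))), "K >= 2")
})

test_that("fusion is the per-pixel convex combination", {
  a <- matrix(0.2, 4, 4); b <- matrix(0.7, 4, 4)
  st <- image_stack(image_raster(a), image_raster(b))
  fz <- fuse(st, list(matrix(0.4, 4, 4), matrix(0.6, 4, 4)))
  expect_equal(as_plane(fz), matrix(0.4 * 0.2 + 0.6 * 0.7, 4, 4))
  # identical inputs reproduce themselves under any weights
  st2 <- image_stack(image_raster(a), image_raster(a))
  w <- rand_plane(4, 4, 3)
  expect_equal(as_plane(fuse(st2, list(w, 1 - w))), a)
  expect_error(fuse(st, list(matrix(0.5, 4, 4))), "K mismatch")
})

test_that("presets carry the standard parameter pairs and auto sigma = s/3", {
  expect_equal(gd_preset("gd5")[c("s", "sigma")], list(s = 5L, sigma = 1.6))
  expect_equal(gd_preset("gd10")[c("s", "sigma")], list(s = 10L, sigma = 3.3))
  expect_equal(gd_preset("gd15")[c("s", "sigma")], list(s = 15L, sigma = 5))
  expect_equal(gd_config(s = 9)$sigma, 3)
  expect_equal(gd_config(s = 3)$sigma, 1)
  expect_error(gd_config(s = 0), ">= 1")
})

test_that("gd_fuse reproduces identical inputs and matches the chained oracle", {
  x <- rand_plane(12, 12, 11)
  st <- image_stack(image_raster(x), image_raster(x))
  fz <- gd_fuse(st, gd_config(s = 2))
  expect_equal(as_plane(fz$pixels), x, tolerance = 1e-12)
  # end-to-end equality with the nested-loop pipeline
  a <- rand_plane(8, 8, 21); b <- rand_plane(8, 8, 22)
  fz <- gd_fuse(image_stack(image_raster(a), image_raster(b)),
                gd_config(s = 2, sigma = 2 / 3))
  ref <- naive_gd_fuse(list(a, b), 2L, 2 / 3)
  expect_lt(max(abs(as_plane(fz$pixels) - ref$fused)), 1e-12)
  expect_lt(max(abs(fz$weights[[1]] - ref$weights[[1]])), 1e-12)
})

test_that("weights conserve mass, fusion is convex and order-equivariant", {
  planes <- lapply(1:3, function(k) rand_plane(16, 16, 30 + k))
  st <- image_stack(lapply(planes, image_raster))
  fz <- gd_fuse(st, gd_config(s = 3))
  wsum <- Reduce(`+`, fz$weights)
  expect_lt(max(abs(wsum - 1)), 1e-9)
  lo <- Reduce(pmin, planes); hi <- Reduce(pmax, planes)
  f <- as_plane(fz$pixels)
  expect_true(all(f >= lo - 1e-12 & f <= hi + 1e-12))
  # permuting the stack permutes weights and leaves the fusion unchanged
  fz_perm <- gd_fuse(image_stack(lapply(planes[c(3, 1, 2)], image_raster)),
                     gd_config(s = 3))
  expect_equal(as_plane(fz_perm$pixels), f, tolerance = 1e-12)
  expect_equal(fz_perm$weights[[2]], fz$weights[[1]], tolerance = 1e-12)
})

test_that("weights are invariant to rescaling the kernel coefficients", {
  a <- rand_plane(10, 10, 41); b <- rand_plane(10, 10, 42)
  k <- gaussian_kernel(2, 1)
  smooth_with <- function(kern) {
    lapply(list(a, b), function(p) {
      d <- edge_magnitude(directional_differences(p))
      smooth_differences(d, kern)
    })
  }
  fw1 <- normalize_weights(smooth_with(k))
  k_scaled <- k
  k_scaled$g1d <- k$g1d * sqrt(7.3)       # coefficient matrix scaled by 7.3
  fw2 <- normalize_weights(smooth_with(k_scaled))
  expect_lt(max(abs(fw1[[1]] - fw2[[1]])), 1e-12)
})

test_that("RGB stacks use one weight map across channels", {
  set.seed(5)
  mk <- function() {
    arr <- array(stats::runif(8 * 8 * 3), c(8, 8, 3))
    image_raster(arr)
  }
  st <- image_stack(mk(), mk())
  fz <- gd_fuse(st, gd_config(s = 2))
  expect_equal(dim(fz$pixels)[3], 3L)
  for (ch in 1:3) {
    manual <- fz$weights[[1]] * st[[1]][, , ch] +
      fz$weights[[2]] * st[[2]][, , ch]
    expect_equal(fz$pixels[, , ch], manual, tolerance = 1e-12)
  }
})

test_that("the sharp source dominates the weights on its sharp half", {
  fx <- make_stack(fixture_spec("multifocus", seed = 3))
  fz <- gd_fuse(fx$stack, gd_config(s = 10, sigma = "auto"))
  w1_sharp <- mean(fz$weights[[1]][fx$masks[[1]]])
  w2_sharp <- mean(fz$weights[[2]][fx$masks[[2]]])
  expect_gt(w1_sharp, 0.5)
  expect_gt(w2_sharp, 0.5)
})
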