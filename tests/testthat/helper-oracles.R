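# Independent straight-line oracles: naive nested-loop transcriptions of the
# fusion pipeline and of the edge/perceptual metric models, kept free of the
# package's vectorized code paths. Used on small fixtures only.

clamp_idx <- function(i, n) min(max(i, 1L), n)

# Full pipeline, Eqs-style: differences -> magnitude -> Gaussian smoothing ->
# weight normalization -> linear fusion; replicate boundary throughout.
naive_gd_fuse <- function(planes, s, sigma, rule = "euclidean") {
  n <- nrow(planes[[1]]); m <- ncol(planes[[1]])
  K <- length(planes)
  off <- -s:s
  w <- outer(off, off, function(p, r) exp(-(p^2 + r^2) / (2 * sigma^2)))
  w <- w / sum(w)
  gds <- vector("list", K)
  for (k in seq_len(K)) {
    I <- planes[[k]]
    cd <- matrix(0, n, m); rd <- matrix(0, n, m)
    for (i in seq_len(n)) for (j in seq_len(m)) {
      cd[i, j] <- I[i, j] - I[i, clamp_idx(j + 1L, m)]
      rd[i, j] <- I[i, j] - I[clamp_idx(i + 1L, n), j]
    }
    d <- switch(rule,
      euclidean = sqrt(cd^2 + rd^2),
      sum_abs = abs(cd) + abs(rd),
      sum_sq = cd^2 + rd^2)
    gd <- matrix(0, n, m)
    for (i in seq_len(n)) for (j in seq_len(m)) {
      acc <- 0
      for (p in off) for (r in off) {
        acc <- acc + w[p + s + 1L, r + s + 1L] *
          d[clamp_idx(i + p, n), clamp_idx(j + r, m)]
      }
      gd[i, j] <- acc
    }
    gds[[k]] <- gd
  }
  fw <- vector("list", K)
  denom <- Reduce(`+`, gds)
  for (k in seq_len(K)) {
    fw[[k]] <- matrix(0, n, m)
    for (i in seq_len(n)) for (j in seq_len(m)) {
      fw[[k]][i, j] <- if (denom[i, j] < 1e-12) 1 / K
                       else gds[[k]][i, j] / denom[i, j]
    }
  }
  F <- matrix(0, n, m)
  for (k in seq_len(K)) F <- F + fw[[k]] * planes[[k]]
  list(fused = F, weights = fw, gds = gds)
}

# Loop-based Sobel features with replicate boundary (correlation form,
# matching the metric convention).
naive_sobel <- function(p) {
  n <- nrow(p); m <- ncol(p)
  kx <- rbind(c(-1, 0, 1), c(-2, 0, 2), c(-1, 0, 1))
  ky <- t(kx)
  g <- matrix(0, n, m); a <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    sx <- 0; sy <- 0
    for (p1 in -1:1) for (p2 in -1:1) {
      v <- p[clamp_idx(i + p1, n), clamp_idx(j + p2, m)]
      sx <- sx + kx[p1 + 2L, p2 + 2L] * v
      sy <- sy + ky[p1 + 2L, p2 + 2L] * v
    }
    g[i, j] <- sqrt(sx^2 + sy^2)
    a[i, j] <- if (sx == 0) pi / 2 else atan(sy / sx)
  }
  list(g = g, a = a)
}

# Literal per-pixel transcription of the edge-preservation (Qabf) model,
# unsaturated published sigmoids.
oracle_qabf <- function(a, b, f) {
  Tg <- 0.9994; kg <- -15; Dg <- 0.5
  Ta <- 0.9879; ka <- -22; Da <- 0.8
  fa <- naive_sobel(a * 255); fb <- naive_sobel(b * 255)
  ff <- naive_sobel(f * 255)
  num <- 0; den <- 0
  n <- nrow(a); m <- ncol(a)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    pres <- function(gs, as_, gt, at) {
      G <- if (max(gs, gt) > 0) min(gs, gt) / max(gs, gt) else 0
      A <- 1 - abs(as_ - at) / (pi / 2)
      (Tg / (1 + exp(kg * (G - Dg)))) * (Ta / (1 + exp(ka * (A - Da))))
    }
    qaf <- pres(fa$g[i, j], fa$a[i, j], ff$g[i, j], ff$a[i, j])
    qbf <- pres(fb$g[i, j], fb$a[i, j], ff$g[i, j], ff$a[i, j])
    num <- num + qaf * fa$g[i, j] + qbf * fb$g[i, j]
    den <- den + fa$g[i, j] + fb$g[i, j]
  }
  if (den == 0) 0 else num / den
}

# DFT via explicit transform matrices (independent of stats::fft).
dft_mat <- function(n) {
  jk <- outer(0:(n - 1), 0:(n - 1))
  exp(-2i * pi * jk / n)
}

naive_csf_filter <- function(x, ppd = 32) {
  n <- nrow(x); m <- ncol(x)
  Wn <- dft_mat(n); Wm <- dft_mat(m)
  X <- Wn %*% x %*% Wm
  for (i in seq_len(n)) for (j in seq_len(m)) {
    ui <- i - 1L; if (ui > floor(n / 2)) ui <- ui - n
    vj <- j - 1L; if (vj > floor(m / 2)) vj <- vj - m
    fr <- sqrt((ui / n)^2 + (vj / m)^2) * ppd
    X[i, j] <- X[i, j] * 2.6 * (0.0192 + 0.114 * fr) * exp(-(0.114 * fr)^1.1)
  }
  Re(Conj(Wn) %*% X %*% Conj(Wm)) / (n * m)
}

naive_gauss_blur <- function(x, sigma) {
  half <- max(1L, ceiling(3 * sigma))
  off <- -half:half
  g <- exp(-off^2 / (2 * sigma^2)); g <- g / sum(g)
  w <- outer(g, g)
  n <- nrow(x); m <- ncol(x)
  out <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    acc <- 0
    for (p in off) for (r in off) {
      acc <- acc + w[p + half + 1L, r + half + 1L] *
        x[clamp_idx(i + p, n), clamp_idx(j + r, m)]
    }
    out[i, j] <- acc
  }
  out
}

naive_masked_contrast <- function(p) {
  x <- naive_csf_filter(p)
  lo1 <- naive_gauss_blur(x, 2)
  lo2 <- naive_gauss_blur(x, 4)
  n <- nrow(p); m <- ncol(p)
  out <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    c0 <- if (abs(lo2[i, j]) > 1e-12) lo1[i, j] / lo2[i, j] - 1 else 0
    ac <- abs(c0)
    out[i, j] <- ac^3 / (ac^2 + 1e-4)
  }
  out
}

oracle_qcb <- function(a, b, f) {
  ca <- naive_masked_contrast(a * 255)
  cb <- naive_masked_contrast(b * 255)
  cf <- naive_masked_contrast(f * 255)
  n <- nrow(ca); m <- ncol(ca)
  acc <- 0
  for (i in seq_len(n)) for (j in seq_len(m)) {
    rat <- function(cs, ct) {
      hi <- max(cs, ct); lo <- min(cs, ct)
      if (hi > 0) lo / hi else 1
    }
    qaf <- rat(ca[i, j], cf[i, j])
    qbf <- rat(cb[i, j], cf[i, j])
    tot <- ca[i, j]^2 + cb[i, j]^2
    la <- if (tot > 0) ca[i, j]^2 / tot else 0.5
    acc <- acc + la * qaf + (1 - la) * qbf
  }
  acc / (n * m)
}

oracle_qcv <- function(planes, f, w1 = 16L) {
  num <- 0; den <- 0
  n <- nrow(f); m <- ncol(f)
  nb <- n %/% w1; mb <- m %/% w1
  for (p in planes) {
    g <- naive_sobel(p * 255)$g
    d <- naive_csf_filter((p - f) * 255)
    for (bi in seq_len(nb)) for (bj in seq_len(mb)) {
      ys <- ((bi - 1L) * w1 + 1L):(bi * w1)
      xs <- ((bj - 1L) * w1 + 1L):(bj * w1)
      lam <- sum(g[ys, xs]^2)
      dist <- mean(d[ys, xs]^2)
      num <- num + lam * dist
      den <- den + lam
    }
  }
  if (den == 0) 0 else num / den
}

# Deterministic random plane on [0,1] under a local seed.
rand_plane <- function(n, m, seed) {
  with_seed_test(seed, matrix(stats::runif(n * m), n, m))
}

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}
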