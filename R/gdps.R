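# Adaptive parameter selection: classic compass pattern search over
# (s, sigma) maximizing a fusion-quality objective.

#' Pattern-search configuration
#'
#' Classic compass search over the Gaussian window parameters. Defaults
#' follow the standard setup: start at `(s, sigma) = (10, 3.3)`, bounds
#' `[5, 80] x [1, 100]`, 20 polling iterations; mesh size 1 initially,
#' doubled on an improving poll and halved otherwise, stopping early once
#' the mesh falls below the tolerance.
#'
#' @param init Initial `(s, sigma)`.
#' @param lower,upper Componentwise bounds.
#' @param max_iter Maximum number of polling iterations.
#' @param objective Fusion-quality objective: `"qabf"`, `"qcb"` or
#'   `"qcv"` (Qcv is internally negated so every objective is maximized).
#' @param mesh Initial mesh size.
#' @param expand,contract Mesh multipliers on success/failure.
#' @param tol Mesh-size stopping tolerance.
#' @return A `ps_config` list.
#' @export
ps_config <- function(init = c(10, 3.3), lower = c(5, 1),
                      upper = c(80, 100), max_iter = 20L,
                      objective = c("qabf", "qcb", "qcv"),
                      mesh = 1, expand = 2, contract = 0.5, tol = 1e-3) {
  objective <- match.arg(objective)
  stopifnot(length(init) == 2L, length(lower) == 2L, length(upper) == 2L)
  if (any(lower >= upper)) stop("need lower < upper componentwise",
                                call. = FALSE)
  if (max_iter < 1L) stop("max_iter must be >= 1", call. = FALSE)
  structure(list(init = as.numeric(init), lower = as.numeric(lower),
                 upper = as.numeric(upper), max_iter = as.integer(max_iter),
                 objective = objective, mesh = mesh,
                 expand = expand, contract = contract, tol = tol),
            class = "ps_config")
}

#' Fusion-quality fitness of a GD parameter pair
#'
#' Runs the full GD fusion at `(s, sigma)` and scores the result with the
#' chosen quality metric, on a maximization orientation (Qcv, where lower
#' is better, is returned negated). `s` is rounded to the nearest integer
#' `>= 1` before the kernel is built; the search itself treats it as a
#' real.
#'
#' @param stack An `image_stack`.
#' @param s,sigma GD parameters (real-valued `s` allowed).
#' @param objective `"qabf"`, `"qcb"` or `"qcv"`.
#' @param ... Passed to the metric (constants/params).
#' @return Objective value (higher is better).
#' @export
gd_fitness <- function(stack, s, sigma, objective = c("qabf", "qcb", "qcv"),
                       ...) {
  objective <- match.arg(objective)
  if (!inherits(stack, "image_stack")) stack <- image_stack(stack)
  s_int <- max(1L, as.integer(round(s)))
  fz <- gd_fuse(stack, gd_config(s = s_int, sigma = sigma))
  a <- stack[[1]]; b <- stack[[2]]
  switch(objective,
    qabf = metric_qabf(a, b, fz$pixels, ...),
    qcb = metric_qcb(a, b, fz$pixels, ...),
    qcv = -metric_qcv(stack, fz$pixels, ...))
}

#' Classic compass pattern search (maximization)
#'
#' Polls the four axis-direction neighbors of the incumbent at the current
#' mesh size in the fixed order `(+s, -s, +sigma, -sigma)`, accepting the
#' first improvement. On success the incumbent moves and the mesh expands;
#' otherwise the mesh contracts. Iterates are clamped to the bounds. Stops
#' after `max_iter` polls or when the mesh drops below the tolerance.
#'
#' @param fn Objective `function(par)` over a length-2 parameter vector,
#'   to be maximized.
#' @param config A [ps_config()].
#' @return List with `par` (best point), `value` (best objective),
#'   `evaluations` (objective call count) and `trace` (data frame with one
#'   row per iteration: iteration, s, sigma, best fitness, mesh size,
#'   cumulative evaluations, whether the poll improved).
#' @export
pattern_search <- function(fn, config = ps_config()) {
  clamp <- function(p) pmin(pmax(p, config$lower), config$upper)
  evals <- 0L
  eval_fn <- function(p) {
    evals <<- evals + 1L
    as.numeric(fn(p))
  }
  cur <- clamp(config$init)
  best <- eval_fn(cur)
  if (!is.finite(best)) {
    stop("objective is not finite at the initial point", call. = FALSE)
  }
  mesh <- config$mesh
  trace <- data.frame(iteration = 0L, s = cur[1], sigma = cur[2],
                      fitness = best, mesh = mesh, evaluations = evals,
                      improved = NA)
  directions <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  for (it in seq_len(config$max_iter)) {
    if (mesh < config$tol) break
    improved <- FALSE
    polled <- 0L
    finite_polls <- 0L
    for (d in directions) {
      cand <- clamp(cur + mesh * d)
      if (all(cand == cur)) next   # clamped onto the incumbent: no new point
      val <- eval_fn(cand)
      polled <- polled + 1L
      if (is.finite(val)) finite_polls <- finite_polls + 1L
      if (is.finite(val) && val > best) {
        cur <- cand
        best <- val
        improved <- TRUE
        break
      }
    }
    if (polled > 0L && finite_polls == 0L) {
      err <- simpleError("objective non-finite at every polled point")
      err$trace <- trace
      stop(err)
    }
    mesh <- mesh * if (improved) config$expand else config$contract
    trace <- rbind(trace,
                   data.frame(iteration = it, s = cur[1], sigma = cur[2],
                              fitness = best, mesh = mesh,
                              evaluations = evals, improved = improved))
  }
  list(par = cur, value = best, evaluations = evals, trace = trace)
}

#' GD fusion with pattern-search-optimized parameters (GDPS)
#'
#' Starts the compass search at the preset `(10, 3.3)` point and maximizes
#' the chosen fusion-quality objective over `(s, sigma)`; the returned
#' fusion can therefore never score worse on that objective than the
#' starting preset.
#'
#' @param stack An `image_stack`.
#' @param objective `"qabf"`, `"qcb"` or `"qcv"`.
#' @param config A [ps_config()]; its `objective` field is overridden by
#'   the `objective` argument.
#' @return A `gdps_fusion` list: `fusion` (the `gd_fusion` at the best
#'   parameters), `s`, `sigma` (best pair, `s` rounded as fused), `value`
#'   (best objective), `objective`, `evaluations` and `trace`.
#' @export
gdps_fuse <- function(stack, objective = c("qabf", "qcb", "qcv"),
                      config = ps_config()) {
  objective <- match.arg(objective)
  if (!inherits(stack, "image_stack")) stack <- image_stack(stack)
  fn <- function(p) gd_fitness(stack, p[1], p[2], objective)
  res <- pattern_search(fn, config)
  s_best <- max(1L, as.integer(round(res$par[1])))
  fz <- gd_fuse(stack, gd_config(s = s_best, sigma = res$par[2]))
  structure(list(fusion = fz, s = s_best, sigma = res$par[2],
                 value = res$value, objective = objective,
                 evaluations = res$evaluations, trace = res$trace),
            class = "gdps_fusion")
}

#' @export
print.gdps_fusion <- function(x, ...) {
  cat(sprintf(
    "<gdps_fusion> objective %s = %.6g at (s, sigma) = (%d, %.4g); %d evaluations\n",
    x$objective, x$value, x$s, x$sigma, x$evaluations))
  invisible(x)
}
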