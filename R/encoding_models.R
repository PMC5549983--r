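#' Specifications of the five encoding models
#'
#' The candidate models map a reach-target position `x = (x, y) = (theta, r)`
#' (angle in radians, radius in cm) to a scalar response, later mid-range
#' normalized before any comparison:
#'
#' * **1** cosine directional tuning: `cos(theta - theta0)`
#' * **2** cosine tuning with linear amplitude gain: `cos(theta - theta0) * k * r`
#' * **3** Von Mises directional tuning:
#'   `exp(sigma * cos(theta - theta0)) / (2 * pi * I0(sigma))`
#' * **4** Von Mises tuning with linear amplitude gain: model 3 `* k * r`
#' * **5** 2D Gaussian position tuning:
#'   `exp(-1/2 * (x - mu)' Sigma^-1 (x - mu))` with
#'   `Sigma = [[sx^2, rho*sx*sy], [rho*sx*sy, sy^2]]`.
#'
#' Note on model 5: the defining equation is sometimes written without the
#' negative exponent, which would diverge away from `mu`; a position model
#' that "fires maximally at a particular location" requires the negative
#' sign (and the conventional 1/2), which is what this package implements.
#'
#' Box constraints: `theta0` in \[-pi, pi\]; `k` in \[-100, 100\]; `sigma`
#' in \[0.01, Inf) (capped at 1e3 for the optimizer -- at sigma = 1e3 the
#' normalized pattern is numerically a delta on the sampled grid);
#' `mu_x, mu_y` in \[-20, 20\] cm; `sigma_x, sigma_y` nominally \[-5, 50\]
#' but, entering Sigma only as squares, implemented on \[1e-3, 50\];
#' `rho` in \[-0.99, 0.99\] with a positive-definiteness check on Sigma.
#'
#' @param model_id integer 1-5.
#' @return list with `model_id`, `par_names`, `lower`, `upper`, `n_params`.
#' @export
model_spec <- function(model_id) {
  model_id <- as.integer(model_id)
  sig_cap <- 1e3
  specs <- list(
    list(par_names = "theta0", lower = -pi, upper = pi),
    list(par_names = c("theta0", "k"), lower = c(-pi, -100), upper = c(pi, 100)),
    list(par_names = c("theta0", "sigma"), lower = c(-pi, 0.01),
         upper = c(pi, sig_cap)),
    list(par_names = c("theta0", "sigma", "k"), lower = c(-pi, 0.01, -100),
         upper = c(pi, sig_cap, 100)),
    list(par_names = c("mu_x", "mu_y", "sigma_x", "sigma_y", "rho"),
         lower = c(-20, -20, 1e-3, 1e-3, -0.99),
         upper = c(20, 20, 50, 50, 0.99))
  )
  if (!model_id %in% 1:5) stop_invalid("model_id must be in 1..5")
  s <- specs[[model_id]]
  list(model_id = model_id, par_names = s$par_names,
       lower = stats::setNames(s$lower, s$par_names),
       upper = stats::setNames(s$upper, s$par_names),
       n_params = length(s$par_names))
}

check_params <- function(spec, params) {
  if (is.null(names(params))) names(params) <- spec$par_names
  if (!setequal(names(params), spec$par_names)) {
    stop_invalid("model ", spec$model_id, " expects parameters ",
                 paste(spec$par_names, collapse = ", "))
  }
  params <- params[spec$par_names]
  if (any(params < spec$lower - 1e-12) || any(params > spec$upper + 1e-12)) {
    stop_invalid("parameters out of bounds for model ", spec$model_id)
  }
  params
}

#' Evaluate an encoding model at a set of points
#'
#' Returns the raw (un-normalized) model response; mid-range normalization
#' over the evaluation grid is applied separately before any comparison
#' with data patterns (see [fit_model()]).
#'
#' @param model_id integer 1-5 (see [model_spec()]).
#' @param params named parameter vector within bounds.
#' @param points list with components `theta` (radians), `r` (cm) and/or
#'   `x`, `y` (cm); directional models use (theta, r), the position model
#'   uses (x, y). Missing polar/Cartesian components are derived from the
#'   other representation.
#' @return numeric vector of model values.
#' @examples
#' evaluate_model(1, c(theta0 = 0), list(theta = 0, r = 1)) # 1
#' @export
evaluate_model <- function(model_id, params, points) {
  sp <- model_spec(model_id)
  p <- check_params(sp, params)
  pts <- complete_points(points)
  switch(sp$model_id,
    cos(pts$theta - p[["theta0"]]),
    cos(pts$theta - p[["theta0"]]) * p[["k"]] * pts$r,
    von_mises(pts$theta, p[["theta0"]], p[["sigma"]]),
    von_mises(pts$theta, p[["theta0"]], p[["sigma"]]) * p[["k"]] * pts$r,
    gauss2d(pts$x, pts$y, p)
  )
}

complete_points <- function(points) {
  if (is.null(points$theta) && !is.null(points$x)) {
    points$theta <- atan2(points$y, points$x)
    points$r <- sqrt(points$x^2 + points$y^2)
  }
  if (is.null(points$x) && !is.null(points$theta)) {
    points$x <- points$r * cos(points$theta)
    points$y <- points$r * sin(points$theta)
  }
  if (is.null(points$theta) || is.null(points$x)) {
    stop_invalid("points must provide (theta, r) and/or (x, y)")
  }
  points
}

# exponentially-scaled Bessel keeps this finite up to the sigma cap
von_mises <- function(theta, theta0, sigma) {
  exp(sigma * (cos(theta - theta0) - 1)) /
    (2 * pi * besselI(sigma, 0, expon.scaled = TRUE))
}

gauss2d <- function(x, y, p) {
  a <- p[["sigma_x"]]^2
  d <- p[["sigma_y"]]^2
  b <- p[["rho"]] * p[["sigma_x"]] * p[["sigma_y"]]
  det <- a * d - b * b
  if (det <= 0) stop_invalid("Sigma is not positive-definite")
  dx <- x - p[["mu_x"]]; dy <- y - p[["mu_y"]]
  q <- (d * dx * dx - 2 * b * dx * dy + a * dy * dy) / det
  exp(-0.5 * q)
}

#' Fit an encoding model to a normalized response pattern
#'
#' Constrained nonlinear least squares: minimizes the sum of squared
#' differences between the mid-range-normalized model pattern and the data
#' pattern over the grid bins, subject to the box constraints of
#' [model_spec()]. Multi-start: `n_restarts` bound-uniform starts plus one
#' data-driven start (`theta0` at the angular argmax / `mu` at the spatial
#' argmax of the pattern), each polished with a clamped Nelder-Mead
#' implemented in C++ (objective tolerance 1e-8 relative, see vignette).
#' Deterministic given `seed`.
#'
#' @param model_id integer 1-5.
#' @param pattern a normalized, non-degenerate `response_pattern`, or a
#'   plain numeric vector of normalized values at the points in `points`.
#' @param points evaluation points (defaults to the pattern's grid).
#' @param n_restarts number of random restarts (default 10).
#' @param seed RNG seed for the restarts.
#' @param mask_only fit over in-hull bins only.
#' @return a `fit_result`: list with `model_id`, `params` (named), the
#'   `objective`, the normalized `fitted` values, `converged`, `failed`,
#'   `n_restarts` and `seed`.
#' @export
fit_model <- function(model_id, pattern, points = NULL, n_restarts = 10,
                      seed = 1, mask_only = FALSE) {
  sp <- model_spec(model_id)
  if (inherits(pattern, "response_pattern")) {
    target <- pattern_values(pattern, mask_only)
    g <- pattern$grid
    gx <- g$gx; gy <- g$gy
    if (mask_only) { keep <- as.vector(pattern$mask); gx <- gx[keep]; gy <- gy[keep] }
    points <- list(x = gx, y = gy)
  } else {
    target <- as.numeric(pattern)
    if (is.null(points)) stop_invalid("points required for a plain vector pattern")
  }
  pts <- complete_points(points)
  rng <- range(target)
  if (rng[2] - rng[1] <= 0) {
    return(structure(list(model_id = model_id, params = NULL,
                          objective = NA_real_, fitted = NULL,
                          converged = FALSE, failed = TRUE,
                          n_restarts = n_restarts, seed = seed),
                     class = "fit_result"))
  }
  target <- (target - rng[1]) / (rng[2] - rng[1])
  starts <- with_seed(seed, make_starts(sp, target, pts, n_restarts))
  res <- fit_model_cpp(sp$model_id, target, pts$theta, pts$r, pts$x, pts$y,
                       starts, sp$lower, sp$upper, 2000L, 1e-10)
  params <- stats::setNames(res$par, sp$par_names)
  fitted <- midrange_normalize(evaluate_model(model_id, params, pts))
  structure(list(model_id = model_id, params = params,
                 objective = res$value, fitted = as.vector(fitted),
                 converged = is.finite(res$value), failed = !is.finite(res$value),
                 n_restarts = n_restarts, seed = seed),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  if (x$failed) {
    cat("<fit_result model", x$model_id, ": FAILED (degenerate pattern)>\n")
  } else {
    cat("<fit_result model", x$model_id, ": objective", format(x$objective),
        "params", paste(names(x$params), round(x$params, 3), sep = "=",
                        collapse = " "), ">\n")
  }
  invisible(x)
}

# restart starting points: bound-uniform draws over a sensible sub-box plus
# one data-driven start
make_starts <- function(sp, target, pts, n_restarts) {
  peak <- which.max(target)
  data_start <- switch(sp$model_id,
    c(atan2(pts$y[peak], pts$x[peak])),
    c(atan2(pts$y[peak], pts$x[peak]), 1),
    c(atan2(pts$y[peak], pts$x[peak]), 2),
    c(atan2(pts$y[peak], pts$x[peak]), 2, 1),
    c(pts$x[peak], pts$y[peak], 3, 3, 0)
  )
  lo <- sp$lower; hi <- sp$upper
  # draw restarts from a moderate sub-box (wide sigma/k tails waste starts)
  slo <- pmax(lo, c(theta0 = -pi, sigma = 0.1, k = -10, mu_x = -10,
                    mu_y = -10, sigma_x = 0.5, sigma_y = 0.5,
                    rho = -0.9)[sp$par_names], na.rm = TRUE)
  shi <- pmin(hi, c(theta0 = pi, sigma = 10, k = 10, mu_x = 10,
                    mu_y = 10, sigma_x = 10, sigma_y = 10,
                    rho = 0.9)[sp$par_names], na.rm = TRUE)
  rand <- do.call(rbind, lapply(seq_len(n_restarts),
                                function(i) runif(sp$n_params, slo, shi)))
  rbind(matrix(data_start, nrow = 1), rand)
}
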