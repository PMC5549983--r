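#' Grid specification for response patterns
#'
#' @param n bins per side (default 11).
#' @param span window side length in cm (default 14, centered at the origin).
#'   The `n` bins tile the window, so the bin side is `span / n` and bin
#'   centers run from `-span/2 + span/(2n)` to `span/2 - span/(2n)`.
#' @return list with bin centers `xc`, `yc` (length `n`), `bin_cm` (bin side)
#'   and the full bin-center lattice `gx`, `gy` (length `n^2`, x varying
#'   fastest, i.e. column-major over `matrix(n, n)` rows = x, cols = y).
#' @export
grid_spec <- function(n = 11, span = 14) {
  if (n < 2 || span <= 0) stop_invalid("invalid grid spec")
  bin <- span / n
  centers <- -span / 2 + bin * (seq_len(n) - 0.5)
  list(n = as.integer(n), span = span, xc = centers, yc = centers,
       bin_cm = bin,
       gx = rep(centers, n), gy = rep(centers, each = n))
}

#' Interpolate per-target mean rates into a 2D spatial response pattern
#'
#' Piecewise-linear (Delaunay barycentric) interpolation of per-target mean
#' firing rates, evaluated at the bin centers of a Cartesian grid (default
#' 11 x 11 bins spanning 14 cm x 14 cm). Bins outside the convex hull of the
#' targets are filled with the nearest target's rate and flagged invalid in
#' the mask. The interpolant is exact at target locations and on affine
#' functions of (x, y).
#'
#' @param rates numeric vector of mean rates, one per target row.
#' @param config a `target_config`; only non-omitted targets are used when
#'   `rates` is named by target index or has the length of the full table
#'   (rates of omitted targets are ignored).
#' @param grid a [grid_spec()].
#' @param op optional precomputed interpolation operator (internal; lets the
#'   split-half protocol reuse the triangulation across thousands of calls).
#' @return a `response_pattern`: list with `values` (n x n matrix, rows = x,
#'   cols = y), `xc`, `yc`, `mask` (n x n logical, TRUE = inside hull),
#'   `normalized`, `smoothed`, `degenerate` flags and the `grid`.
#' @export
interpolate_pattern <- function(rates, config, grid = grid_spec(), op = NULL) {
  tg <- active_targets(config)
  if (length(rates) == nrow(config$targets) && nrow(tg) != nrow(config$targets)) {
    rates <- rates[!config$targets$omitted]
  }
  if (length(rates) != nrow(tg)) {
    stop_invalid("need one rate per active target (", nrow(tg), "), got ",
                 length(rates))
  }
  if (nrow(tg) < 3) stop_invalid("need >= 3 targets")
  if (is.null(op)) op <- pattern_operator(config, grid)
  v <- as.vector(op$W %*% rates)
  structure(list(values = matrix(v, grid$n, grid$n),
                 xc = grid$xc, yc = grid$yc,
                 mask = matrix(op$mask, grid$n, grid$n),
                 normalized = FALSE, smoothed = FALSE, degenerate = FALSE,
                 grid = grid),
            class = "response_pattern")
}

#' Precompute the interpolation operator for a configuration
#'
#' @inheritParams interpolate_pattern
#' @return list(W, mask) mapping active-target rates to grid bins.
#' @export
pattern_operator <- function(config, grid = grid_spec()) {
  tg <- active_targets(config)
  interp_operator(tg$x_cm, tg$y_cm, grid$gx, grid$gy)
}

#' @export
print.response_pattern <- function(x, ...) {
  cat(sprintf("<response_pattern %dx%d, %d/%d bins in hull%s%s%s>\n",
              nrow(x$values), ncol(x$values), sum(x$mask), length(x$mask),
              if (x$normalized) ", normalized" else "",
              if (x$smoothed) ", smoothed" else "",
              if (x$degenerate) ", DEGENERATE" else ""))
  invisible(x)
}

pattern_values <- function(pattern, mask_only = FALSE) {
  v <- as.vector(pattern$values)
  if (mask_only) v[as.vector(pattern$mask)] else v
}

#' Eccentricity of the peak response bin, in visual degrees
#'
#' Euclidean distance of the argmax bin center from the origin, converted to
#' degrees of visual angle. Ties are broken by smallest eccentricity, then
#' smallest polar angle. Smoothed patterns are for display only and are
#' rejected unless `allow_smoothed = TRUE`.
#'
#' @param pattern a `response_pattern` (raw or normalized; the argmax, hence
#'   the eccentricity, is invariant to mid-range normalization).
#' @param screen_distance eye-to-screen distance in cm.
#' @param convention visual-angle convention, see [cm_to_visual_degrees()].
#' @param mask_only restrict to in-hull bins.
#' @param allow_smoothed override the display-only contract of
#'   [smooth_for_display()].
#' @return list(eccentricity_deg, peak_x_cm, peak_y_cm, tie = logical).
#'   Degenerate (constant) patterns return `NA` with `degenerate = TRUE`.
#' @export
peak_eccentricity <- function(pattern, screen_distance = 45,
                              convention = c("atan", "linear"),
                              mask_only = FALSE, allow_smoothed = FALSE) {
  convention <- match.arg(convention)
  if (pattern$smoothed && !allow_smoothed) {
    stop_invalid("pattern was smoothed for display; quantification refused ",
                 "(set allow_smoothed = TRUE to override)")
  }
  v <- pattern_values(pattern, mask_only)
  gx <- pattern$grid$gx; gy <- pattern$grid$gy
  if (mask_only) { keep <- as.vector(pattern$mask); gx <- gx[keep]; gy <- gy[keep] }
  if (near_constant(v)) {
    return(list(eccentricity_deg = NA_real_, peak_x_cm = NA_real_,
                peak_y_cm = NA_real_, tie = TRUE, degenerate = TRUE))
  }
  top <- which(v >= max(v) - 1e-12)
  ecc <- sqrt(gx[top]^2 + gy[top]^2)
  ang <- (rad2deg(atan2(gy[top], gx[top]))) %% 360
  o <- order(ecc, ang)[1]
  list(eccentricity_deg = cm_to_visual_degrees(ecc[o], screen_distance, convention),
       peak_x_cm = gx[top[o]], peak_y_cm = gy[top[o]],
       tie = length(top) > 1, degenerate = FALSE)
}

#' Response-field width in visual degrees
#'
#' The square root of the spatial area covered by the top quartile of bin
#' values (bins with value >= their own 75th percentile; percentile computed
#' with linear interpolation between order statistics, ties included by >=),
#' converted to visual degrees. Affine-invariant, so raw and mid-range
#' normalized patterns give the same width.
#'
#' @inheritParams peak_eccentricity
#' @return list(width_deg, area_cm2, n_bins, degenerate).
#' @export
field_width <- function(pattern, screen_distance = 45,
                        convention = c("atan", "linear"),
                        mask_only = FALSE, allow_smoothed = FALSE) {
  convention <- match.arg(convention)
  if (pattern$smoothed && !allow_smoothed) {
    stop_invalid("pattern was smoothed for display; quantification refused")
  }
  v <- pattern_values(pattern, mask_only)
  degen <- near_constant(v)
  if (degen) {
    # limiting case of the >= rule: every bin ties at the percentile
    nb <- length(v)
  } else {
    thr <- quantile(v, 0.75, type = 7, names = FALSE)
    nb <- sum(v >= thr)
  }
  area <- nb * pattern$grid$bin_cm^2
  list(width_deg = cm_to_visual_degrees(sqrt(area), screen_distance, convention),
       area_cm2 = area, n_bins = nb, degenerate = degen)
}

#' Gaussian blur of a response pattern, for display only
#'
#' Convolution with a 2D Gaussian kernel (default width 0.5 bins) under
#' symmetric (reflective) padding, which preserves total mass. The result is
#' flagged `smoothed`; quantification functions refuse it unless overridden.
#'
#' @param pattern a `response_pattern`.
#' @param kernel_width Gaussian sigma in bins.
#' @return the smoothed `response_pattern`.
#' @export
smooth_for_display <- function(pattern, kernel_width = 0.5) {
  if (kernel_width <= 0) return(pattern)
  r <- max(1L, ceiling(3 * kernel_width))
  k <- exp(-0.5 * ((-r:r) / kernel_width)^2)
  k <- k / sum(k)
  conv1 <- function(v) {
    n <- length(v)
    p <- v[c(rev(seq_len(r)), seq_len(n), n - seq_len(r) + 1L)]
    vapply(seq_len(n), function(i) sum(k * p[i:(i + 2 * r)]), 0)
  }
  m <- apply(pattern$values, 2, conv1)       # along x (rows)
  m <- t(apply(m, 1, conv1))                 # along y (cols)
  pattern$values <- m
  pattern$smoothed <- TRUE
  pattern
}

#' Serialize / load a response pattern as plain text
#'
#' The pattern matrix is written as a tab-delimited 11 x 11 table and its
#' metadata (window, bin centers, mask, flags) as a JSON sidecar.
#'
#' @param pattern a `response_pattern`.
#' @param path base path; writes `<path>.tsv` and `<path>.json`.
#' @return `write_pattern()` the base path, invisibly; `read_pattern()` the
#'   reconstructed `response_pattern`.
#' @export
write_pattern <- function(pattern, path) {
  write.table(pattern$values, paste0(path, ".tsv"), sep = "\t",
              row.names = FALSE, col.names = FALSE)
  meta <- list(n = pattern$grid$n, span = pattern$grid$span,
               xc = pattern$xc, yc = pattern$yc,
               mask = as.vector(pattern$mask),
               normalized = pattern$normalized, smoothed = pattern$smoothed,
               degenerate = pattern$degenerate)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_pattern
#' @export
read_pattern <- function(path) {
  vals <- as.matrix(read.delim(paste0(path, ".tsv"), header = FALSE))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  g <- grid_spec(meta$n, meta$span)
  structure(list(values = unname(vals), xc = meta$xc, yc = meta$yc,
                 mask = matrix(meta$mask, meta$n, meta$n),
                 normalized = meta$normalized, smoothed = meta$smoothed,
                 degenerate = meta$degenerate, grid = g),
            class = "response_pattern")
}
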