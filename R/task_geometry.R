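#' Reach-target configurations
#'
#' Center-out memory-reach target layouts on a fronto-parallel touch screen,
#' with the fixation point at the origin. Directions are measured in degrees
#' counterclockwise from screen-rightward (+x), so 0 = RIGHT, 90 = UP,
#' 180 = LEFT, 270 = DOWN; amplitudes are radial distances in cm. Degrees are
#' used at every interface; model internals work in radians.
#'
#' `make_task1()` builds the sparse layout: two amplitudes along each of four
#' equally spaced directions (8 targets). `make_task2()` builds the dense
#' layout: three amplitudes in each of 16 equally spaced directions
#' (48 targets), with each amplitude ring optionally staggered by a fixed
#' angular offset so the configuration is slightly off a perfectly radial
#' grid (as used to cover a square touch screen). Individual targets can be
#' marked as omitted (e.g. dropped for insufficient trials).
#'
#' @param amp_small,amp_large the two Task-1 amplitudes in cm,
#'   `0 < amp_small < amp_large`.
#' @param amps three strictly increasing positive Task-2 amplitudes in cm.
#'   The defaults (3, 5, 7 cm) span the 14 cm x 14 cm interpolation window.
#' @param radial_offset angular stagger in degrees applied per amplitude
#'   ring (ring k is rotated by `k * radial_offset`); must be smaller in
#'   magnitude than the 22.5 deg ring spacing.
#' @param omit integer indices (1-based) of targets to mark as omitted.
#' @param screen_distance eye-to-screen distance in cm (default 45).
#' @return A `target_config`: a list with `task_id`, `targets` (data.frame
#'   with columns `index`, `dir_index`, `amp_index`, `direction_deg`,
#'   `amplitude_cm`, `x_cm`, `y_cm`, `omitted`), `n_directions`,
#'   `n_amplitudes`, `screen_distance`, `omitted_targets`.
#' @examples
#' cfg <- make_task1(5, 10)
#' nrow(cfg$targets) # 8
#' cfg2 <- make_task2(omit = c(1, 2, 3))
#' sum(!cfg2$targets$omitted) # 45
#' @export
make_task1 <- function(amp_small = 5, amp_large = 10, screen_distance = 45) {
  if (!(amp_small > 0 && amp_large > amp_small)) {
    stop_invalid("amplitudes must satisfy 0 < amp_small < amp_large")
  }
  dirs <- c(0, 90, 180, 270)
  grid <- expand.grid(amp_index = 1:2, dir_index = 1:4)
  amps <- c(amp_small, amp_large)
  new_target_config("task1", dirs[grid$dir_index], amps[grid$amp_index],
                    grid$dir_index, grid$amp_index,
                    n_directions = 4L, n_amplitudes = 2L,
                    screen_distance = screen_distance)
}

#' @rdname make_task1
#' @export
make_task2 <- function(amps = c(3, 5, 7), radial_offset = 7.5,
                       omit = integer(), screen_distance = 45) {
  if (length(amps) != 3 || any(amps <= 0) || any(diff(amps) <= 0)) {
    stop_invalid("amps must be 3 strictly increasing positive values")
  }
  spacing <- 360 / 16
  if (abs(radial_offset) >= spacing) {
    stop_invalid("radial_offset must be smaller than the ", spacing,
                 " degree ring spacing")
  }
  base <- seq(0, 360 - spacing, by = spacing)
  grid <- expand.grid(dir_index = 1:16, amp_index = 1:3)
  dirs <- (base[grid$dir_index] + radial_offset * (grid$amp_index - 1)) %% 360
  cfg <- new_target_config("task2", dirs, amps[grid$amp_index],
                           grid$dir_index, grid$amp_index,
                           n_directions = 16L, n_amplitudes = 3L,
                           screen_distance = screen_distance)
  mark_omitted(cfg, omit)
}

new_target_config <- function(task_id, direction_deg, amplitude_cm,
                              dir_index, amp_index, n_directions,
                              n_amplitudes, screen_distance) {
  if (screen_distance <= 0) stop_invalid("screen_distance must be positive")
  dir <- direction_deg %% 360
  targets <- data.frame(
    index = seq_along(dir),
    dir_index = as.integer(dir_index),
    amp_index = as.integer(amp_index),
    direction_deg = dir,
    amplitude_cm = amplitude_cm,
    x_cm = amplitude_cm * cos(deg2rad(dir)),
    y_cm = amplitude_cm * sin(deg2rad(dir)),
    omitted = FALSE
  )
  structure(list(task_id = task_id, targets = targets,
                 n_directions = n_directions, n_amplitudes = n_amplitudes,
                 screen_distance = screen_distance,
                 omitted_targets = integer()),
            class = "target_config")
}

#' Mark targets of a configuration as omitted
#'
#' @param config a `target_config`.
#' @param omit integer target indices to omit.
#' @return the configuration with `omitted` flags and `omitted_targets` set.
#' @export
mark_omitted <- function(config, omit) {
  omit <- as.integer(omit)
  if (length(omit) && (any(omit < 1) || any(omit > nrow(config$targets)))) {
    stop_invalid("omitted target indices out of range")
  }
  config$targets$omitted <- config$targets$index %in% omit
  config$omitted_targets <- sort(unique(omit))
  config
}

#' Usable (non-omitted) targets of a configuration
#' @param config a `target_config`.
#' @return the `targets` data.frame restricted to non-omitted rows.
#' @export
active_targets <- function(config) {
  config$targets[!config$targets$omitted, , drop = FALSE]
}

#' @export
print.target_config <- function(x, ...) {
  cat(sprintf("<target_config %s: %d directions x %d amplitudes, %d targets (%d omitted), screen %g cm>\n",
              x$task_id, x$n_directions, x$n_amplitudes, nrow(x$targets),
              length(x$omitted_targets), x$screen_distance))
  invisible(x)
}

#' Convert a screen distance in cm to degrees of visual angle
#'
#' The default convention is the exact one, `atan(d / screen_distance)`
#' expressed in degrees. A linear small-angle convention
#' (`(180/pi) * d / screen_distance`) is selectable; the two agree to < 1%
#' for `d / screen_distance < 0.15`. Eccentricities and field widths are
#' reported through this conversion.
#'
#' @param d distance(s) on the screen in cm, `d >= 0`.
#' @param screen_distance eye-to-screen distance in cm (default 45).
#' @param convention `"atan"` (default) or `"linear"`.
#' @return visual angle(s) in degrees.
#' @examples
#' cm_to_visual_degrees(45, 45) # 45
#' @export
cm_to_visual_degrees <- function(d, screen_distance = 45,
                                 convention = c("atan", "linear")) {
  convention <- match.arg(convention)
  if (screen_distance <= 0) stop_invalid("screen_distance must be positive")
  if (any(d < 0)) stop_invalid("d must be non-negative")
  if (convention == "atan") rad2deg(atan(d / screen_distance))
  else rad2deg(d / screen_distance)
}

#' Write / read a target table as delimited text
#'
#' @param config a `target_config`.
#' @param path output (input) file path; tab-separated with header
#'   `index, direction_deg, amplitude_cm, x_cm, y_cm`.
#' @return `write_targets()` returns `path` invisibly; `read_targets()`
#'   returns a data.frame.
#' @export
write_targets <- function(config, path) {
  cols <- c("index", "direction_deg", "amplitude_cm", "x_cm", "y_cm")
  write.table(config$targets[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_targets
#' @export
read_targets <- function(path) {
  read.delim(path, check.names = FALSE)
}
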