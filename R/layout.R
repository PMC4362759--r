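#' Trap-grid layout specification
#'
#' Describes a rectangular trapping grid: traps every `trap_spacing` metres
#' along lines that are `line_spacing` metres apart, surrounded by an
#' untrapped buffer so that animals at the edge of the trapped block still
#' hold full circular home ranges.  Coordinates are metres on a continuous
#' plane with the origin at the outer corner of the buffer; the first trap
#' sits at `(buffer, buffer)`.
#'
#' `buffered_area` is the area (hectares) over which animals are placed.
#' By default it is the geometric area of the buffered rectangle; the
#' species presets override it with the nominal planning figure used to
#' convert density to animal numbers, which can differ from the geometric
#' span by a few percent.
#'
#' @param trap_spacing metres between traps along a line (> 0).
#' @param line_spacing metres between trap lines (> 0).
#' @param traps_per_line number of traps on each line (>= 1).
#' @param n_lines number of trap lines (>= 1).
#' @param buffer width in metres of the untrapped margin on every side
#'   (>= 0).
#' @param buffered_area hectares over which animals are placed; defaults to
#'   the geometric area of the buffered rectangle.
#' @return An object of class `layout_spec` with the given fields plus
#'   `width` and `height`, the metre dimensions of the buffered rectangle.
#' @examples
#' # possum preset geometry: 81 x 26 = 2106 trap sites over ~1000 ha
#' possum <- layout_spec(50, 100, 81, 26, buffer = 100, buffered_area = 1140)
#' n_traps(build_trap_grid(possum))
#' @export
layout_spec <- function(trap_spacing, line_spacing, traps_per_line, n_lines,
                        buffer = 0, buffered_area = NULL) {
  chk <- function(x, nm, min, int = FALSE) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min)
      stop(sprintf("`%s` must be a single number >= %g", nm, min), call. = FALSE)
    if (int && x != round(x))
      stop(sprintf("`%s` must be a whole number", nm), call. = FALSE)
  }
  chk(trap_spacing, "trap_spacing", 1e-9)
  chk(line_spacing, "line_spacing", 1e-9)
  chk(traps_per_line, "traps_per_line", 1, int = TRUE)
  chk(n_lines, "n_lines", 1, int = TRUE)
  chk(buffer, "buffer", 0)
  width <- (traps_per_line - 1) * trap_spacing + 2 * buffer
  height <- (n_lines - 1) * line_spacing + 2 * buffer
  if (is.null(buffered_area)) buffered_area <- width * height / 1e4
  chk(buffered_area, "buffered_area", 1e-9)
  structure(list(trap_spacing = trap_spacing, line_spacing = line_spacing,
                 traps_per_line = as.integer(traps_per_line),
                 n_lines = as.integer(n_lines), buffer = buffer,
                 buffered_area = buffered_area,
                 width = width, height = height),
            class = "layout_spec")
}

#' @export
print.layout_spec <- function(x, ...) {
  cat(sprintf("Trap layout: %d traps/line x %d lines (%g m x %g m spacing)\n",
              x$traps_per_line, x$n_lines, x$trap_spacing, x$line_spacing))
  cat(sprintf("  buffer %g m; buffered rectangle %g x %g m; placement area %g ha\n",
              x$buffer, x$width, x$height, x$buffered_area))
  invisible(x)
}

#' Build a trap grid with a per-site capture capacity
#'
#' Lays the traps of a [layout_spec()] out on a regular grid, each starting
#' with `capacity` remaining captures and active.  A trap is active exactly
#' while it has remaining capacity; once its capacity is exhausted it is
#' retired for the rest of the trapping period (single-capture traps have
#' `capacity = 1`, self-resetting multiple-capture traps more).
#'
#' @param layout a [layout_spec()].
#' @param capacity maximum captures per trap site (>= 1).
#' @return An object of class `trap_grid` with fields `positions` (n x 2
#'   matrix of metre coordinates), `capacity`, `remaining` and `active`.
#' @export
build_trap_grid <- function(layout, capacity = 1) {
  stopifnot(inherits(layout, "layout_spec"))
  if (!is.numeric(capacity) || length(capacity) != 1L || is.na(capacity) ||
      capacity < 1 || capacity != round(capacity))
    stop("`capacity` must be a whole number >= 1", call. = FALSE)
  x <- layout$buffer + (seq_len(layout$traps_per_line) - 1) * layout$trap_spacing
  y <- layout$buffer + (seq_len(layout$n_lines) - 1) * layout$line_spacing
  n <- length(x) * length(y)
  positions <- cbind(x = rep(x, times = length(y)), y = rep(y, each = length(x)))
  structure(list(positions = positions, capacity = as.integer(capacity),
                 remaining = rep(as.integer(capacity), n),
                 active = rep(TRUE, n)),
            class = "trap_grid")
}

#' Number of trap sites in a grid
#'
#' @param grid a [build_trap_grid()] object.
#' @return Integer count of trap sites.
#' @export
n_traps <- function(grid) {
  stopifnot(inherits(grid, "trap_grid"))
  nrow(grid$positions)
}

#' @export
print.trap_grid <- function(x, ...) {
  cat(sprintf("Trap grid: %d sites, capacity %d per site, %d active\n",
              n_traps(x), x$capacity, sum(x$active)))
  invisible(x)
}
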