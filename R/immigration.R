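#' Immigration specification
#'
#' Describes reinvasion of the trapped block during the trapping period:
#' over the full period a number of immigrants equal (by default) to the
#' initial resident population arrives, spread evenly across nights, with
#' home-range centres weighted towards the perimeter.  The buffered
#' rectangle is partitioned into `n_zones` nested frames of equal step
#' width (the step being `min(width, height) / (2 * n_zones)`); the default
#' weights place 60%, 30% and 10% of immigrants in the outer, middle and
#' inner zone respectively.
#'
#' @param total total immigrants over the period; `NULL` (default) means
#'   "equal to the initial resident population", resolved when a scenario
#'   runs.
#' @param n_zones number of nested placement zones (default 3).
#' @param zone_weights proportions of immigrants per zone, outermost first;
#'   must be non-negative and sum to 1.
#' @return An object of class `immigration_spec`.
#' @export
immigration_spec <- function(total = NULL, n_zones = 3,
                             zone_weights = c(0.6, 0.3, 0.1)) {
  if (!is.null(total)) {
    if (!is.numeric(total) || length(total) != 1L || is.na(total) ||
        total < 0 || total != round(total))
      stop("`total` must be NULL or a single whole number >= 0", call. = FALSE)
    total <- as.integer(total)
  }
  if (!is.numeric(n_zones) || length(n_zones) != 1L || n_zones < 1 ||
      n_zones != round(n_zones))
    stop("`n_zones` must be a whole number >= 1", call. = FALSE)
  if (!is.numeric(zone_weights) || length(zone_weights) != n_zones)
    stop(sprintf("`zone_weights` must be %d proportions (outer to inner)", n_zones),
         call. = FALSE)
  if (any(zone_weights < 0) || abs(sum(zone_weights) - 1) > 1e-8)
    stop("`zone_weights` must be non-negative and sum to 1", call. = FALSE)
  structure(list(total = total, n_zones = as.integer(n_zones),
                 zone_weights = as.numeric(zone_weights)),
            class = "immigration_spec")
}

#' @export
print.immigration_spec <- function(x, ...) {
  cat(sprintf("Immigration: total %s over the period; zone weights %s (outer to inner)\n",
              if (is.null(x$total)) "= initial population" else x$total,
              paste(x$zone_weights, collapse = "/")))
  invisible(x)
}

#' Nightly immigrant arrivals
#'
#' Spreads `total` immigrants over `nights` deterministically: night `k`
#' receives `floor(k * total / nights) - floor((k - 1) * total / nights)`
#' arrivals, so the fractional remainder is carried forward, nightly counts
#' differ by at most one, and the counts sum exactly to the total.
#'
#' @param spec an [immigration_spec()] with a resolved `total`, or a single
#'   total count.
#' @param nights number of nights (>= 1).
#' @return Integer vector of length `nights`.
#' @examples
#' table(immigrant_schedule(12628, 30))  # nights of 420 and 421
#' @export
immigrant_schedule <- function(spec, nights) {
  total <- if (inherits(spec, "immigration_spec")) spec$total else spec
  if (is.null(total))
    stop("immigration total has not been resolved; supply a count", call. = FALSE)
  if (!is.numeric(nights) || length(nights) != 1L || nights < 1 ||
      nights != round(nights))
    stop("`nights` must be a whole number >= 1", call. = FALSE)
  as.integer(diff(floor((0:nights) * total / nights)))
}

#' Draw placement zones for immigrants
#'
#' Zone labels (1 = outermost) drawn independently with the spec's weights.
#'
#' @param n number of immigrants (>= 0).
#' @param spec an [immigration_spec()].
#' @return Integer vector of zone labels of length `n`.
#' @export
assign_zones <- function(n, spec) {
  stopifnot(inherits(spec, "immigration_spec"))
  if (!is.numeric(n) || length(n) != 1L || n < 0 || n != round(n))
    stop("`n` must be a whole number >= 0", call. = FALSE)
  if (n == 0) return(integer(0))
  sample.int(spec$n_zones, size = n, replace = TRUE, prob = spec$zone_weights)
}

## Zone of a point: nested rectangular frames of equal step width measured
## inward from the perimeter of the buffered rectangle.
zone_of_point <- function(x, y, layout, n_zones) {
  step <- min(layout$width, layout$height) / (2 * n_zones)
  d <- pmin(x, y, layout$width - x, layout$height - y)
  pmin(floor(d / step) + 1, n_zones)
}

#' Place immigrants in their zones
#'
#' Each immigrant's home-range centre is drawn uniformly within its zone's
#' rectangular frame (by rejection from the buffered rectangle), giving the
#' perimeter-to-centre gradient of arriving animals.
#'
#' @param zones integer zone labels from [assign_zones()] (1 = outermost).
#' @param layout a [layout_spec()].
#' @param spec an [immigration_spec()] (supplies the number of zones).
#' @return A [population_state()] of at-large immigrants, rows in the order
#'   of `zones`.
#' @export
place_immigrants <- function(zones, layout, spec = immigration_spec()) {
  stopifnot(inherits(layout, "layout_spec"), inherits(spec, "immigration_spec"))
  n <- length(zones)
  if (n == 0)
    return(population_state(matrix(numeric(0), ncol = 2), origin = "immigrant"))
  if (any(zones < 1 | zones > spec$n_zones))
    stop("zone labels out of range", call. = FALSE)
  centres <- matrix(NA_real_, n, 2)
  todo <- seq_len(n)
  while (length(todo)) {
    m <- max(2L * length(todo), 100L)
    px <- runif(m, 0, layout$width)
    py <- runif(m, 0, layout$height)
    pz <- zone_of_point(px, py, layout, spec$n_zones)
    for (z in unique(zones[todo])) {
      want <- todo[zones[todo] == z]
      have <- which(pz == z)
      k <- min(length(want), length(have))
      if (k) {
        centres[want[seq_len(k)], ] <- cbind(px[have[seq_len(k)]],
                                             py[have[seq_len(k)]])
      }
    }
    todo <- which(is.na(centres[, 1]))
  }
  population_state(centres, status = "at-large", origin = "immigrant")
}
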