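#' Construct a population state
#'
#' A population is a set of fixed home-range centres with a capture status
#' and an origin label per animal.  Centres never move during a trapping
#' period and captured animals never return to the at-large pool.
#'
#' @param centres numeric matrix with two columns (x, y metre coordinates),
#'   one row per animal.
#' @param status character vector, `"at-large"` or `"captured"`; recycled
#'   from length 1.
#' @param origin character vector, `"resident"` or `"immigrant"`; recycled
#'   from length 1.
#' @return An object of class `population_state`.
#' @export
population_state <- function(centres, status = "at-large", origin = "resident") {
  centres <- as.matrix(centres)
  if (length(centres) == 0L) centres <- matrix(numeric(0), ncol = 2)
  if (ncol(centres) != 2L || !is.numeric(centres))
    stop("`centres` must be a numeric matrix with columns x and y", call. = FALSE)
  n <- nrow(centres)
  status <- rep_len(as.character(status), n)
  origin <- rep_len(as.character(origin), n)
  if (n && !all(status %in% c("at-large", "captured")))
    stop("`status` values must be 'at-large' or 'captured'", call. = FALSE)
  if (n && !all(origin %in% c("resident", "immigrant")))
    stop("`origin` values must be 'resident' or 'immigrant'", call. = FALSE)
  colnames(centres) <- c("x", "y")
  structure(list(centres = centres, status = status, origin = origin),
            class = "population_state")
}

#' Number of animals in a population state
#' @param pop a [population_state()].
#' @return Integer count.
#' @export
n_animals <- function(pop) {
  stopifnot(inherits(pop, "population_state"))
  nrow(pop$centres)
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf("Population: %d animals (%d at large, %d captured; %d immigrants)\n",
              n_animals(x), sum(x$status == "at-large"),
              sum(x$status == "captured"), sum(x$origin == "immigrant")))
  invisible(x)
}

#' Place the initial resident population
#'
#' Draws `round(density * buffered_area)` home-range centres uniformly over
#' the buffered rectangle of the layout.  The buffer ensures animals living
#' just outside the trapped block, whose ranges overlap it, are represented.
#' Animal numbers use the layout's nominal `buffered_area`, so the planning
#' densities convert to the exact animal counts practitioners quote.
#'
#' Uses the current RNG stream; seed control lives in the replicate driver.
#'
#' @param layout a [layout_spec()].
#' @param density mean animals per hectare (>= 0).
#' @return A [population_state()] of residents, all at large.
#' @examples
#' set.seed(1)
#' lay <- layout_spec(50, 100, 81, 26, buffer = 100, buffered_area = 1140)
#' n_animals(init_population(lay, density = 0.5))  # 570
#' @export
init_population <- function(layout, density) {
  stopifnot(inherits(layout, "layout_spec"))
  if (!is.numeric(density) || length(density) != 1L || is.na(density) || density < 0)
    stop("`density` must be a single non-negative number per hectare", call. = FALSE)
  n <- as.integer(round(density * layout$buffered_area))
  centres <- cbind(x = runif(n, 0, layout$width), y = runif(n, 0, layout$height))
  population_state(centres, status = "at-large", origin = "resident")
}
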