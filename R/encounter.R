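#' Build the animal-trap encounter table
#'
#' Computes, for every animal, the traps within `truncation * sigma` of its
#' home-range centre and the nightly capture probability for each such pair
#' under the half-normal detection function.  Pairs beyond the truncation
#' radius carry a probability below `g0 * exp(-truncation^2 / 2)` (under
#' 4e-6 of `g0` at the default 5 sigma) and are dropped; the truncation
#' must be at least 2.45 sigma so the 95% home range is always covered.
#'
#' The table is stored in compressed sparse rows (one row per animal) for
#' the simulation kernels; use [encounter_pairs()] for a per-animal view.
#'
#' @param grid a [build_trap_grid()] object.
#' @param pop a [population_state()].
#' @param params a [detection_params()].
#' @param truncation truncation radius in multiples of sigma (>= 2.45).
#' @return An object of class `encounter_table` with fields `row_ptr`
#'   (0-based offsets, length `n_animals + 1`), `trap` (0-based trap index
#'   per pair), `dist`, `prob`, `hazard` (`-log(1 - prob)`), `n_animals`,
#'   `n_traps` and `truncation_radius`.
#' @export
build_encounter_table <- function(grid, pop, params, truncation = 5) {
  stopifnot(inherits(grid, "trap_grid"), inherits(pop, "population_state"),
            inherits(params, "detection_params"))
  if (!is.numeric(truncation) || length(truncation) != 1L || truncation < 2.45)
    stop("`truncation` must be >= 2.45 so the 95% home range is covered",
         call. = FALSE)
  radius <- truncation * params$sigma
  pr <- .pair_search(pop$centres, grid$positions, radius)
  prob <- capture_probability(pr$dist, params)
  hazard <- -log1p(-pmin(prob, 1 - 1e-12))
  structure(list(row_ptr = pr$row_ptr, trap = pr$trap, dist = pr$dist,
                 prob = prob, hazard = hazard,
                 n_animals = n_animals(pop), n_traps = n_traps(grid),
                 truncation_radius = radius),
            class = "encounter_table")
}

#' Pairs of one animal in an encounter table
#'
#' @param table an [build_encounter_table()] object.
#' @param animal 1-based animal index.
#' @return A data frame with columns `trap` (1-based trap index), `dist`
#'   (metres) and `prob` (nightly capture probability).
#' @export
encounter_pairs <- function(table, animal) {
  stopifnot(inherits(table, "encounter_table"))
  if (animal < 1 || animal > table$n_animals)
    stop("`animal` out of range", call. = FALSE)
  idx <- seq.int(table$row_ptr[animal] + 1, length.out =
                   table$row_ptr[animal + 1] - table$row_ptr[animal])
  data.frame(trap = table$trap[idx] + 1L, dist = table$dist[idx],
             prob = table$prob[idx])
}

#' @export
print.encounter_table <- function(x, ...) {
  cat(sprintf("Encounter table: %d animals x %d traps, %d pairs within %.1f m\n",
              x$n_animals, x$n_traps, length(x$trap), x$truncation_radius))
  invisible(x)
}
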