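#' Resolve one night of trapping
#'
#' Processes the at-large animals in uniformly random order.  Under the
#' default competing-hazards rule each animal is captured that night with
#' probability `1 - exp(-sum(h))` over its currently active traps, where
#' `h = -log(1 - P)` is the per-pair hazard, and conditional on capture the
#' trap is drawn proportional to hazard.  Under `competition = "bernoulli"`
#' each active pair is an independent trial and the capturing trap is drawn
#' uniformly among that night's successes.  A capture decrements the trap's
#' remaining capacity; a trap whose capacity reaches zero is retired
#' immediately, so saturation earlier in the processing order affects the
#' animals handled afterwards.
#'
#' This function is functional: it returns updated copies of the grid and
#' population.  [simulate_replicate()] runs the same per-animal rule inside
#' a compiled whole-replicate loop.
#'
#' @param table an [build_encounter_table()] for `grid` and `pop`.
#' @param grid a [build_trap_grid()] object.
#' @param pop a [population_state()].
#' @param competition `"hazard"` or `"bernoulli"`.
#' @return A list with `captures` (data frame of `animal` and `trap`
#'   1-based indices, in capture order), `grid` and `pop` (updated copies).
#' @export
resolve_night <- function(table, grid, pop,
                          competition = c("hazard", "bernoulli")) {
  stopifnot(inherits(table, "encounter_table"), inherits(grid, "trap_grid"),
            inherits(pop, "population_state"))
  if (table$n_animals != n_animals(pop) || table$n_traps != n_traps(grid))
    stop("encounter table does not match the grid/population", call. = FALSE)
  competition <- match.arg(competition)
  at_large <- which(pop$status == "at-large")
  order <- at_large[sample.int(length(at_large))]
  remaining <- grid$remaining + 0L            # force copies: the kernel
  status <- ifelse(pop$status == "captured", 2L, 1L) + 0L  # mutates in place
  caps <- .night_kernel(table$row_ptr, table$trap, table$hazard, table$prob,
                        remaining, status, order - 1L,
                        if (competition == "hazard") 0L else 1L)
  grid$remaining <- remaining
  grid$active <- remaining > 0L
  pop$status[caps$animal] <- "captured"
  list(captures = data.frame(animal = caps$animal, trap = caps$trap),
       grid = grid, pop = pop)
}

#' Run a single replicate of a trapping scenario
#'
#' Places the resident population, pre-draws any immigrants with their
#' arrival nights (immigrants join the at-large pool at the start of their
#' night, before captures are resolved), builds the encounter table, then
#' iterates the nightly capture process with traps never re-set within the
#' period.
#'
#' @param config a [scenario_config()].
#' @param replicate replicate number; together with the config's base seed
#'   it determines this replicate's independent RNG stream.
#' @param seed explicit integer seed overriding the derived one, or `NA` to
#'   use the current RNG state.
#' @return An object of class `replicate_result` with fields `trap_counts`
#'   (captures per trap), `fates` (data frame: `origin`, `entry_night`,
#'   `night`, `trap`, `NA` for animals never captured), `n_residents`,
#'   `n_immigrants`, `exposed`, `captured` and `capacity`.
#' @export
simulate_replicate <- function(config, replicate = 1L, seed = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  if (is.null(seed)) seed <- replicate_seed(config$seed, replicate)
  if (!is.na(seed)) set.seed(seed)

  pop <- init_population(config$layout, config$density)
  n_res <- n_animals(pop)
  entry <- rep(1L, n_res)
  n_imm <- 0L
  if (!is.null(config$immigration)) {
    spec <- config$immigration
    total <- spec$total %||% n_res
    sched <- immigrant_schedule(total, config$nights)
    n_imm <- sum(sched)
    if (n_imm > 0L) {
      zones <- assign_zones(n_imm, spec)
      imm <- place_immigrants(zones, config$layout, spec)
      pop <- population_state(rbind(pop$centres, imm$centres),
                              origin = c(pop$origin, imm$origin))
      entry <- c(entry, rep(seq_len(config$nights), sched))
    }
  }

  grid <- build_trap_grid(config$layout, config$capacity)
  table <- build_encounter_table(grid, pop, config$detection, config$truncation)
  out <- .run_replicate_kernel(table$row_ptr, table$trap, table$hazard,
                               table$prob, n_traps(grid), config$capacity,
                               entry, config$nights,
                               if (config$competition == "hazard") 0L else 1L)
  structure(list(trap_counts = out$trap_counts,
                 fates = data.frame(origin = pop$origin, entry_night = entry,
                                    night = out$fate_night,
                                    trap = out$fate_trap),
                 n_residents = n_res, n_immigrants = n_imm,
                 exposed = n_res + n_imm,
                 captured = sum(!is.na(out$fate_night)),
                 capacity = config$capacity, seed = seed),
            class = "replicate_result")
}

#' @export
print.replicate_result <- function(x, ...) {
  cat(sprintf("Replicate: %d of %d animals captured (%d residents + %d immigrants); %d/%d traps with a capture\n",
              x$captured, x$exposed, x$n_residents, x$n_immigrants,
              sum(x$trap_counts > 0), length(x$trap_counts)))
  invisible(x)
}

#' Simulate a trapping scenario
#'
#' The package's main function: runs `replicates` independent replicates of
#' a trapping scenario and collects per-trap capture counts and per-animal
#' outcomes.  Replicate `r` runs on a stream derived from the base seed and
#' `r` (see [replicate_seed()]), so results are reproducible and any
#' replicate can be recomputed in isolation.
#'
#' @param config a [scenario_config()] or [species_preset()] result.
#' @param replicates number of replicates; defaults to the config's.
#' @param keep_fates keep the per-animal fate tables of every replicate
#'   (can be large; off by default).
#' @return An object of class `trap_sim` with fields `config`, `counts`
#'   (traps x replicates matrix of capture counts), `captured`, `exposed`,
#'   `n_residents`, `n_immigrants` (per-replicate vectors) and optionally
#'   `fates`.  Methods: `print`, `summary`, `plot`, `simulate`.
#' @examples
#' \donttest{
#' fit <- trap_sim(species_preset("possum", density = 0.5, replicates = 20))
#' summary(fit)
#' }
#' @export
trap_sim <- function(config, replicates = config$replicates,
                     keep_fates = FALSE) {
  stopifnot(inherits(config, "scenario_config"))
  reps <- vector("list", replicates)
  for (r in seq_len(replicates)) reps[[r]] <- simulate_replicate(config, r)
  counts <- vapply(reps, function(x) as.integer(x$trap_counts),
                   integer(length(reps[[1]]$trap_counts)))
  counts <- matrix(counts, ncol = replicates)
  structure(list(config = config, replicates = as.integer(replicates),
                 counts = counts,
                 captured = vapply(reps, `[[`, numeric(1), "captured"),
                 exposed = vapply(reps, `[[`, numeric(1), "exposed"),
                 n_residents = vapply(reps, `[[`, numeric(1), "n_residents"),
                 n_immigrants = vapply(reps, `[[`, numeric(1), "n_immigrants"),
                 fates = if (keep_fates) lapply(reps, `[[`, "fates")),
            class = "trap_sim")
}

#' @export
print.trap_sim <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Trapping simulation%s: density %g/ha, capacity %d, %d nights, %d replicates\n",
              if (is.na(cfg$species)) "" else paste0(" [", cfg$species, "]"),
              cfg$density, cfg$capacity, cfg$nights, x$replicates))
  pc <- population_capture_proportion(x)
  cat(sprintf("  population captured: %.1f%% (sd %.1f)\n",
              100 * pc$mean, 100 * pc$sd))
  cat(sprintf("  traps with >= 1 capture: %.1f%% of %d sites\n",
              100 * mean(colMeans(x$counts > 0)), nrow(x$counts)))
  invisible(x)
}

#' @export
summary.trap_sim <- function(object, ...) {
  structure(list(config = object$config, replicates = object$replicates,
                 distribution = trap_capture_distribution(object),
                 population = population_capture_proportion(object)),
            class = "summary.trap_sim")
}

#' @export
print.summary.trap_sim <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Scenario%s: density %g/ha, capacity %d, %d nights, %d replicates\n",
              if (is.na(cfg$species)) "" else paste0(" [", cfg$species, "]"),
              cfg$density, cfg$capacity, cfg$nights, x$replicates))
  cat("\nProportion of traps by final capture count (mean over replicates):\n")
  print(format(x$distribution, digits = 4), row.names = FALSE)
  p <- x$population
  cat(sprintf("\nPopulation captured: %.1f%% (sd %.1f, 95%% of replicates %.1f-%.1f%%)\n",
              100 * p$mean, 100 * p$sd, 100 * p$lower, 100 * p$upper))
  invisible(x)
}

#' @describeIn trap_sim barplot of the mean per-trap capture-count
#'   distribution.
#' @param x a `trap_sim` object.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.trap_sim <- function(x, ...) {
  d <- trap_capture_distribution(x)
  barplot(d$proportion, names.arg = d$captures,
          xlab = "captures per trap site", ylab = "proportion of traps", ...)
  invisible(x)
}

#' @describeIn trap_sim run `nsim` fresh replicates of the same scenario
#'   (optionally under a new base seed) and return a new `trap_sim`.
#' @param object a `trap_sim` object.
#' @param nsim number of replicates.
#' @param seed base seed for the new run; `NULL` keeps the scenario's.
#' @export
simulate.trap_sim <- function(object, nsim = object$replicates, seed = NULL,
                              ...) {
  cfg <- object$config
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  trap_sim(cfg, replicates = nsim)
}
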