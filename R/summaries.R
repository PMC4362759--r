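## Coerce the various result containers (trap_sim, list of
## replicate_result, bare counts matrix) to a traps x replicates matrix.
counts_matrix <- function(x) {
  if (inherits(x, "trap_sim")) return(x$counts)
  if (inherits(x, "replicate_result")) x <- list(x)
  if (is.list(x) && length(x) && all(vapply(x, inherits, logical(1), "replicate_result")))
    return(vapply(x, function(r) as.integer(r$trap_counts),
                  integer(length(x[[1]]$trap_counts))) |>
             matrix(ncol = length(x)))
  if (is.matrix(x) && is.numeric(x)) return(x)
  stop("expected a trap_sim, replicate_result(s) or a counts matrix",
       call. = FALSE)
}

spread <- function(v) {
  c(sd = sd(v), lower = unname(quantile(v, 0.025)),
    upper = unname(quantile(v, 0.975)))
}

#' Distribution of capture counts per trap site
#'
#' For each capture count `k = 0..capacity`, the proportion of trap sites
#' whose final count equals `k`, averaged over replicates, with the
#' replicate-level spread (sd and 2.5/97.5 percentiles) and the tail mass
#' `k` or more.
#'
#' @param results a [trap_sim()] object, a list of
#'   [simulate_replicate()] results, or a traps x replicates counts matrix.
#' @param capacity largest count to tabulate; defaults to the scenario's
#'   capacity (or the observed maximum).
#' @return A data frame with columns `captures`, `proportion`, `sd`,
#'   `lower`, `upper` and `ge_proportion` (mean proportion of traps with at
#'   least `captures` captures).  The attribute `any_capture` holds the
#'   mean proportion of traps with one or more captures.
#' @export
trap_capture_distribution <- function(results, capacity = NULL) {
  m <- counts_matrix(results)
  if (ncol(m) < 1L) stop("at least one replicate is required", call. = FALSE)
  if (is.null(capacity)) {
    capacity <- if (inherits(results, "trap_sim"))
      results$config$capacity else max(m)
  }
  ks <- 0:capacity
  per_rep <- vapply(ks, function(k) colMeans(m == k), numeric(ncol(m)))
  per_rep <- matrix(per_rep, nrow = ncol(m))     # replicates x counts
  sp <- apply(per_rep, 2, spread)
  out <- data.frame(captures = ks, proportion = colMeans(per_rep),
                    sd = sp["sd", ], lower = sp["lower", ],
                    upper = sp["upper", ])
  out$ge_proportion <- rev(cumsum(rev(out$proportion)))
  attr(out, "any_capture") <- 1 - out$proportion[1]
  rownames(out) <- NULL
  out
}

#' Proportion of the exposed population captured
#'
#' Mean over replicates of captured animals divided by the exposed
#' population (residents plus all immigrants introduced during the run),
#' with the replicate-level spread.
#'
#' @param results a [trap_sim()] object or a list of
#'   [simulate_replicate()] results.
#' @return A one-row data frame with columns `mean`, `sd`, `lower`,
#'   `upper` and `replicates`.
#' @export
population_capture_proportion <- function(results) {
  if (inherits(results, "replicate_result")) results <- list(results)
  if (inherits(results, "trap_sim")) {
    captured <- results$captured
    exposed <- results$exposed
  } else if (is.list(results) && length(results) &&
             all(vapply(results, inherits, logical(1), "replicate_result"))) {
    captured <- vapply(results, `[[`, numeric(1), "captured")
    exposed <- vapply(results, `[[`, numeric(1), "exposed")
  } else {
    stop("expected a trap_sim or replicate_result(s)", call. = FALSE)
  }
  if (length(captured) < 1L) stop("at least one replicate is required", call. = FALSE)
  if (any(exposed == 0))
    stop("capture proportion undefined: a replicate exposed no animals",
         call. = FALSE)
  p <- captured / exposed
  sp <- spread(p)
  data.frame(mean = mean(p), sd = sp["sd"], lower = sp["lower"],
             upper = sp["upper"], replicates = length(p), row.names = NULL)
}

#' Sweep a scenario over densities and capacities
#'
#' Runs one simulation per (density, capacity) cell, each on an independent
#' seed derived from the base seed and the cell indices (see
#' [cell_seed()]), and stacks tidy summary rows: the per-trap capture-count
#' distribution (`metric = "traps_with_k"`), the proportion of traps with
#' at least one capture (`"traps_any"`) and the proportion of the exposed
#' population captured (`"population"`).
#'
#' @param config a template [scenario_config()]; its density and capacity
#'   are replaced cell by cell.
#' @param densities numeric vector of animals per hectare.
#' @param capacities integer vector of per-site capture capacities.
#' @param replicates replicates per cell; defaults to the template's.
#' @return A data frame with columns `species`, `density`, `capacity`,
#'   `metric`, `captures` (`NA` except for `traps_with_k`), `mean`, `sd`,
#'   `lower`, `upper` and `seed`.
#' @export
density_sweep <- function(config, densities, capacities,
                          replicates = config$replicates) {
  stopifnot(inherits(config, "scenario_config"))
  if (!length(densities) || !length(capacities))
    stop("`densities` and `capacities` must be non-empty", call. = FALSE)
  rows <- list()
  for (di in seq_along(densities)) {
    for (ci in seq_along(capacities)) {
      cfg <- config
      cfg$density <- densities[di]
      cfg$capacity <- as.integer(capacities[ci])
      cfg$seed <- cell_seed(config$seed, di, ci)
      fit <- trap_sim(cfg, replicates = replicates)
      d <- trap_capture_distribution(fit)
      p <- population_capture_proportion(fit)
      cell <- function(metric, captures, mean, sd, lower, upper) {
        data.frame(species = cfg$species, density = cfg$density,
                   capacity = cfg$capacity, metric = metric,
                   captures = captures, mean = mean, sd = sd,
                   lower = lower, upper = upper, seed = cfg$seed)
      }
      rows[[length(rows) + 1L]] <- rbind(
        cell("traps_with_k", d$captures, d$proportion, d$sd, d$lower, d$upper),
        cell("traps_any", NA_integer_, attr(d, "any_capture"),
             NA_real_, NA_real_, NA_real_),
        cell("population", NA_integer_, p$mean, p$sd, p$lower, p$upper))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
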