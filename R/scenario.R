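#' Full scenario configuration
#'
#' Everything needed to run one trapping scenario: species detection
#' parameters, trap layout, animal density, per-site capture capacity, the
#' number of nights traps are left unchecked, replicate count, optional
#' immigration, and the base seed from which all replicate streams derive.
#'
#' @param detection a [detection_params()].
#' @param layout a [layout_spec()].
#' @param density mean animals per hectare (>= 0).
#' @param capacity captures per trap site before the trap is retired
#'   (default 1, a single-capture trap).
#' @param nights nights of unchecked trapping (default 30).
#' @param replicates Monte-Carlo replicates (default 100).
#' @param immigration `NULL` for a closed population, or an
#'   [immigration_spec()].
#' @param seed integer base seed.
#' @param truncation encounter-table truncation radius as a multiple of
#'   sigma (default 5; must be at least 2.45 so the 95% home range is
#'   always covered).
#' @param competition within-night resolution rule: `"hazard"` (competing
#'   hazards, the default) or `"bernoulli"` (independent trials per
#'   animal-trap pair, uniform choice among successes) for sensitivity
#'   analysis.
#' @param species optional species tag carried into summaries and outputs.
#' @return An object of class `scenario_config`.
#' @seealso [species_preset()] for ready-made possum/stoat/rat scenarios.
#' @export
scenario_config <- function(detection, layout, density, capacity = 1,
                            nights = 30, replicates = 100,
                            immigration = NULL, seed = 1L, truncation = 5,
                            competition = c("hazard", "bernoulli"),
                            species = NA_character_) {
  stopifnot(inherits(detection, "detection_params"),
            inherits(layout, "layout_spec"))
  if (!is.numeric(density) || length(density) != 1L || is.na(density) || density < 0)
    stop("`density` must be a single non-negative number", call. = FALSE)
  chk_count <- function(x, nm, min) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
        x != round(x))
      stop(sprintf("`%s` must be a whole number >= %d", nm, min), call. = FALSE)
    as.integer(x)
  }
  capacity <- chk_count(capacity, "capacity", 1L)
  nights <- chk_count(nights, "nights", 1L)
  replicates <- chk_count(replicates, "replicates", 1L)
  seed <- chk_count(seed, "seed", 0L)
  if (!is.null(immigration) && !inherits(immigration, "immigration_spec"))
    stop("`immigration` must be NULL or an immigration_spec", call. = FALSE)
  if (!is.numeric(truncation) || length(truncation) != 1L || truncation < 2.45)
    stop("`truncation` must be >= 2.45 (sigma multiples)", call. = FALSE)
  competition <- match.arg(competition)
  structure(list(detection = detection, layout = layout, density = density,
                 capacity = capacity, nights = nights, replicates = replicates,
                 immigration = immigration, seed = seed,
                 truncation = truncation, competition = competition,
                 species = as.character(species)),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("Trapping scenario%s\n",
              if (is.na(x$species)) "" else paste0(" [", x$species, "]")))
  print(x$detection)
  print(x$layout)
  cat(sprintf("  density %g/ha, capacity %d, %d nights, %d replicates, seed %d\n",
              x$density, x$capacity, x$nights, x$replicates, x$seed))
  cat(sprintf("  immigration: %s; competition: %s; truncation %g sigma\n",
              if (is.null(x$immigration)) "none (closed population)" else
                paste0(x$immigration$total %||% "initial population",
                       " over the period"),
              x$competition, x$truncation))
  invisible(x)
}

preset_file <- function(species) {
  path <- system.file("extdata", "presets", paste0(species, ".yaml"),
                      package = "trapsim")
  if (path == "")
    stop(sprintf("no preset for species '%s' (have: %s)", species,
                 paste(list_presets(), collapse = ", ")), call. = FALSE)
  yaml::read_yaml(path)
}

#' Available species presets
#' @return Character vector of preset names.
#' @export
list_presets <- function() {
  dir <- system.file("extdata", "presets", package = "trapsim")
  sub("\\.yaml$", "", list.files(dir, pattern = "\\.yaml$"))
}

#' Ready-made species scenarios
#'
#' Builds a [scenario_config()] from the shipped best-practice presets for
#' brushtail possums, stoats and ship rats: half-normal detection
#' parameters, trap and line spacings, buffer widths and nominal buffered
#' areas.  The default density is the lowest of the preset's typical
#' maintenance range.
#'
#' @param species `"possum"`, `"stoat"` or `"rat"`.
#' @param density animals per hectare; default is the preset's lowest
#'   typical density.
#' @param capacity,nights,replicates,seed,truncation,competition see
#'   [scenario_config()].
#' @param immigration `FALSE` (closed population, the default), `TRUE` for
#'   the preset's immigration block (rats: arrivals totalling the initial
#'   population, 60/30/10 outer/middle/inner), or an [immigration_spec()].
#' @return A `scenario_config`.
#' @examples
#' species_preset("possum", density = 0.5)
#' @export
species_preset <- function(species, density = NULL, capacity = 1, nights = 30,
                           replicates = 100, seed = 1L, immigration = FALSE,
                           truncation = 5,
                           competition = c("hazard", "bernoulli")) {
  p <- preset_file(species)
  det <- detection_params(p$detection$g0, p$detection$sigma)
  lay <- layout_spec(p$layout$trap_spacing, p$layout$line_spacing,
                     p$layout$traps_per_line, p$layout$n_lines,
                     buffer = p$layout$buffer,
                     buffered_area = p$layout$buffered_area)
  if (is.null(density)) density <- p$density_range[[1]]
  imm <- NULL
  if (isTRUE(immigration)) {
    ib <- p$immigration
    if (is.null(ib)) {
      imm <- immigration_spec()
    } else {
      imm <- immigration_spec(total = ib$total,
                              n_zones = length(ib$zone_weights),
                              zone_weights = unlist(ib$zone_weights))
    }
  } else if (inherits(immigration, "immigration_spec")) {
    imm <- immigration
  } else if (!isFALSE(immigration)) {
    stop("`immigration` must be TRUE, FALSE or an immigration_spec", call. = FALSE)
  }
  scenario_config(det, lay, density = density, capacity = capacity,
                  nights = nights, replicates = replicates,
                  immigration = imm, seed = seed, truncation = truncation,
                  competition = match.arg(competition), species = species)
}
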