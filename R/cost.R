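#' Trap hardware cost and field-time specification
#'
#' @param price purchase price per trap, in the analysis currency.
#' @param setup_time minutes to set up one trap.
#' @param check_time minutes to check/reset one trap at each service visit.
#' @param traps_per_site number of traps deployed at each site (>= 1).
#' @param model optional model name for labelling.
#' @return An object of class `trap_cost_spec`.
#' @export
trap_cost_spec <- function(price, setup_time, check_time, traps_per_site = 1,
                           model = NA_character_) {
  for (v in list(price = price, setup_time = setup_time,
                 check_time = check_time)) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop("costs and times must be single non-negative numbers", call. = FALSE)
  }
  if (!is.numeric(traps_per_site) || length(traps_per_site) != 1L ||
      traps_per_site < 1 || traps_per_site != round(traps_per_site))
    stop("`traps_per_site` must be a whole number >= 1", call. = FALSE)
  structure(list(price = price, setup_time = setup_time,
                 check_time = check_time,
                 traps_per_site = as.integer(traps_per_site),
                 model = as.character(model)),
            class = "trap_cost_spec")
}

#' Labour costing specification
#'
#' Labour is costed from trap-handling minutes at a daily contract rate
#' (default $NZ300 over a 480-minute field day).  `n_checks` is the number
#' of service visits within the costing period (default 1, i.e. one check
#' at the end of an unchecked 30-night period) and `exchange_rate` converts
#' the labour currency into the hardware-price currency (default 1; the
#' NZD/USD conversion is deliberately left to the user).
#'
#' @param daily_rate labour cost per field day (> 0).
#' @param minutes_per_day workable minutes per field day (> 0).
#' @param n_checks service visits in the costing period (>= 0).
#' @param exchange_rate multiplier from labour currency to price currency.
#' @return An object of class `labour_spec`.
#' @export
labour_spec <- function(daily_rate = 300, minutes_per_day = 480,
                        n_checks = 1, exchange_rate = 1) {
  if (!is.numeric(daily_rate) || daily_rate < 0)
    stop("`daily_rate` must be non-negative", call. = FALSE)
  if (!is.numeric(minutes_per_day) || minutes_per_day <= 0)
    stop("`minutes_per_day` must be positive", call. = FALSE)
  if (!is.numeric(n_checks) || n_checks < 0)
    stop("`n_checks` must be non-negative", call. = FALSE)
  if (!is.numeric(exchange_rate) || exchange_rate < 0)
    stop("`exchange_rate` must be non-negative", call. = FALSE)
  structure(list(daily_rate = daily_rate, minutes_per_day = minutes_per_day,
                 n_checks = n_checks, exchange_rate = exchange_rate),
            class = "labour_spec")
}

#' Cost per hectare of a trap deployment
#'
#' Itemised cost of servicing `n_sites` trap sites over `area` hectares for
#' one costing period: the hardware component
#' `price * traps_per_site * n_sites / area` and the labour component
#' `(setup_time + n_checks * check_time) * traps_per_site * n_sites /
#' minutes_per_day * daily_rate * exchange_rate / area`.  The two
#' components always sum to the total.
#'
#' @param trap a [trap_cost_spec()].
#' @param labour a [labour_spec()].
#' @param n_sites number of trap sites (>= 1).
#' @param area trapped area in hectares (> 0).
#' @return A one-row data frame with columns `model`, `traps_per_site`,
#'   `hardware`, `labour` and `total` (currency per hectare).
#' @examples
#' cost_per_hectare(trap_cost_spec(140, 5, 3, model = "A24"),
#'                  labour_spec(), n_sites = 84, area = 1040)
#' @export
cost_per_hectare <- function(trap, labour, n_sites, area) {
  stopifnot(inherits(trap, "trap_cost_spec"), inherits(labour, "labour_spec"))
  if (!is.numeric(area) || length(area) != 1L || is.na(area) || area <= 0)
    stop("`area` must be a single positive number of hectares", call. = FALSE)
  if (!is.numeric(n_sites) || length(n_sites) != 1L || n_sites < 1)
    stop("`n_sites` must be >= 1", call. = FALSE)
  traps <- trap$traps_per_site * n_sites
  hardware <- trap$price * traps / area
  minutes <- (trap$setup_time + labour$n_checks * trap$check_time) * traps
  labour_cost <- minutes / labour$minutes_per_day * labour$daily_rate *
    labour$exchange_rate / area
  data.frame(model = trap$model, traps_per_site = trap$traps_per_site,
             hardware = hardware, labour = labour_cost,
             total = hardware + labour_cost)
}

#' Compare single- and multiple-capture trap strategies
#'
#' Costs per hectare of deploying 1 to `max_traps_per_site` single-capture
#' traps at every site versus one multiple-capture trap per site, all over
#' the same `n_sites` and `area`.
#'
#' @param single a [trap_cost_spec()] for the single-capture trap (its
#'   `traps_per_site` is replaced by each value of 1..`max_traps_per_site`).
#' @param multi a [trap_cost_spec()] for the multiple-capture trap.
#' @param labour a [labour_spec()].
#' @param n_sites,area as in [cost_per_hectare()].
#' @param max_traps_per_site largest single-trap count per site (>= 1).
#' @return A data frame, one row per single-trap configuration plus a final
#'   row for the multiple-capture strategy, with columns `strategy`,
#'   `model`, `traps_per_site`, `hardware`, `labour`, `total`.
#' @export
strategy_compare <- function(single, multi, labour, n_sites, area,
                             max_traps_per_site = 6) {
  stopifnot(inherits(single, "trap_cost_spec"), inherits(multi, "trap_cost_spec"))
  if (!is.numeric(max_traps_per_site) || max_traps_per_site < 1)
    stop("`max_traps_per_site` must be >= 1", call. = FALSE)
  rows <- lapply(seq_len(max_traps_per_site), function(k) {
    s <- single
    s$traps_per_site <- as.integer(k)
    cbind(strategy = sprintf("single x %d", k),
          cost_per_hectare(s, labour, n_sites, area))
  })
  rows[[length(rows) + 1L]] <-
    cbind(strategy = "multi", cost_per_hectare(multi, labour, n_sites, area))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Shipped indicative trap costs
#'
#' The trap models, hardware prices and field times used by the cost
#' examples, as a data frame, together with the default labour block.
#'
#' @return A list with `traps` (data frame: `model`, `type`, `price`,
#'   `setup_time`, `check_time`) and `labour` (a [labour_spec()]).
#' @export
trap_cost_presets <- function() {
  p <- yaml::read_yaml(system.file("extdata", "trap_costs.yaml",
                                   package = "trapsim"))
  traps <- do.call(rbind, lapply(p$traps, as.data.frame))
  list(traps = traps,
       labour = labour_spec(daily_rate = p$labour$daily_rate,
                            minutes_per_day = p$labour$minutes_per_day))
}
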