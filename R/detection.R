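#' Half-normal detection parameters
#'
#' Bundles the two parameters of the half-normal detection function used
#' throughout the simulator: `g0`, the probability that an animal is
#' captured on a given night by a trap sitting exactly at its home-range
#' centre, and `sigma`, the spatial scale of the home range in metres.
#' `2.45 * sigma` is the radius within which the animal spends about 95% of
#' its time (see [home_range_radius95()]).
#'
#' @param g0 nightly capture probability at the home-range centre, in
#'   (0, 1].
#' @param sigma home-range spatial scale in metres, > 0.
#' @return An object of class `detection_params`.
#' @examples
#' possum <- detection_params(g0 = 0.05, sigma = 63)
#' capture_probability(c(0, 63, 150), possum)
#' @export
detection_params <- function(g0, sigma) {
  if (!is.numeric(g0) || length(g0) != 1L || is.na(g0) || g0 <= 0 || g0 > 1)
    stop("`g0` must be a single probability in (0, 1]", call. = FALSE)
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma <= 0)
    stop("`sigma` must be a single positive distance in metres", call. = FALSE)
  structure(list(g0 = as.numeric(g0), sigma = as.numeric(sigma)),
            class = "detection_params")
}

#' @export
print.detection_params <- function(x, ...) {
  cat(sprintf("Half-normal detection: g0 = %g, sigma = %g m (95%% radius %.2f m)\n",
              x$g0, x$sigma, home_range_radius95(x)))
  invisible(x)
}

#' Nightly capture probability at a given trap-to-centre distance
#'
#' The half-normal detection function
#' \deqn{P = g_0 \exp(-d^2 / (2\sigma^2))}
#' giving the probability that an animal whose home-range centre lies `d`
#' metres from a trap is captured by that trap on a single night.
#'
#' @param d distance(s) in metres between home-range centre and trap;
#'   non-negative.
#' @param params a [detection_params()] object.
#' @return Numeric vector of probabilities in (0, g0].
#' @export
capture_probability <- function(d, params) {
  stopifnot(inherits(params, "detection_params"))
  if (!is.numeric(d) || any(is.na(d)) || any(d < 0))
    stop("`d` must be non-negative distances in metres", call. = FALSE)
  params$g0 * exp(-d^2 / (2 * params$sigma^2))
}

#' 95% home-range radius
#'
#' The radius `2.45 * sigma` within which an animal following the
#' half-normal activity model is found about 95% of the time.
#'
#' @param params a [detection_params()] object.
#' @return Radius in metres.
#' @export
home_range_radius95 <- function(params) {
  stopifnot(inherits(params, "detection_params"))
  2.45 * params$sigma
}
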