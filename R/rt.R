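#' Draw reaction times from a shifted lognormal distribution
#'
#' RT = shift + Lognormal(meanlog, sdlog). The shifted lognormal gives a
#' realistic right-skewed RT distribution with a hard lower limit (the
#' non-decision floor). With `sdlog = 0` the distribution degenerates to
#' `shift + exp(meanlog)` (the shifted median).
#'
#' @param n number of trials (>= 1).
#' @param dist list with elements `shift` (seconds, >= 0), `meanlog`,
#'   `sdlog` (>= 0).
#' @param seed optional integer; if given, seeds the RNG first. If `NULL`
#'   the current RNG stream is used (so callers that seed once stay
#'   reproducible).
#' @return numeric vector of `n` positive RTs in seconds.
#' @export
draw_rts <- function(n, dist = list(shift = 0.2, meanlog = log(0.6), sdlog = 0.35),
                     seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("'n' must be a positive count")
  if (is.null(dist$shift) || dist$shift < 0 || is.null(dist$sdlog) || dist$sdlog < 0)
    stop("invalid RT distribution: need shift >= 0 and sdlog >= 0")
  if (dist$shift + exp(dist$meanlog) <= 0)
    stop("RT distribution has non-positive support")
  if (!is.null(seed)) set.seed(seed)
  dist$shift + stats::rlnorm(n, meanlog = dist$meanlog, sdlog = dist$sdlog)
}

#' Quantile function of the shifted lognormal RT distribution
#' @param p probabilities.
#' @inheritParams draw_rts
#' @return RT quantiles in seconds.
#' @export
rt_quantile <- function(p, dist = list(shift = 0.2, meanlog = log(0.6), sdlog = 0.35)) {
  dist$shift + stats::qlnorm(p, meanlog = dist$meanlog, sdlog = dist$sdlog)
}
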