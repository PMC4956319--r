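#' Thermal and osmotic response functions
#'
#' Unitless multipliers in (0, 1] describing how polyp population change
#' decays away from the optimal temperature or salinity. Both are
#' asymmetric Gaussian curves: for a covariate value \eqn{x} below the
#' optimum \eqn{x_{opt}} the response is
#' \eqn{\exp[-(x_{opt}-x)^2/\sigma_{low}^2]}, above it
#' \eqn{\exp[-(x_{opt}-x)^2/\sigma_{high}^2]}, and exactly 1 at the
#' optimum. The denominator is the squared width parameter itself, with no
#' factor of 2, so \eqn{\sigma} is the distance at which the response
#' falls to \eqn{e^{-1}}.
#'
#' @param t,s Temperature (degrees Celsius) / salinity (ppt); numeric
#'   vectors, all finite.
#' @param params A [response_params()] object.
#' @return Numeric vector of responses in (0, 1].
#' @examples
#' p <- response_params(11.48, 22.91, 3.47, 5.01, 26.04, 5.19, 31.07)
#' thermal_response(c(18, 22.91, 31), p)
#' @export
thermal_response <- function(t, params) {
  stopifnot(inherits(params, "response_params"))
  if (!is.numeric(t) || any(!is.finite(t)))
    stop("temperature must be finite numeric", call. = FALSE)
  .asym_gauss(t, params$t_opt, params$sigma_t_low, params$sigma_t_high)
}

#' @rdname thermal_response
#' @export
osmotic_response <- function(s, params) {
  stopifnot(inherits(params, "response_params"))
  if (!is.numeric(s) || any(!is.finite(s)))
    stop("salinity must be finite numeric", call. = FALSE)
  .asym_gauss(s, params$s_opt, params$sigma_s_low, params$sigma_s_high)
}

# piecewise asymmetric Gaussian; at x == opt both branches give exp(0) = 1,
# the low branch is evaluated there by convention
.asym_gauss <- function(x, opt, sigma_low, sigma_high) {
  sigma <- ifelse(x > opt, sigma_high, sigma_low)
  exp(-((opt - x)^2) / sigma^2)
}

#' Expected final polyp count
#'
#' The model mean \eqn{a F(T) G(S) P_{initial}}, with the factor excluded
#' by a reduced model variant fixed at 1.
#'
#' @param p_initial Initial polyp count(s), non-negative.
#' @param t,s Temperature (degC) and salinity (ppt), recycled against
#'   `p_initial`.
#' @param params A [response_params()] object.
#' @param variant Model variant; `"temperature_only"` sets the osmotic
#'   factor to 1, `"salinity_only"` the thermal factor.
#' @return Expected final counts (non-negative real).
#' @export
predict_final_mean <- function(p_initial, t, s, params, variant = "full") {
  variant <- match.arg(variant, .variants)
  if (!is.numeric(p_initial) || any(p_initial < 0))
    stop("p_initial must be non-negative", call. = FALSE)
  f <- if (variant == "salinity_only") 1 else thermal_response(t, params)
  g <- if (variant == "temperature_only") 1 else osmotic_response(s, params)
  params$a * f * g * p_initial
}

# mean floor keeping the NB likelihood finite in total-mortality cells where
# F*G underflows to 0
.MU_FLOOR <- 1e-10

#' Negative-binomial log-likelihood of paired counts
#'
#' Sum over wells of the log-probability of the final count under a
#' negative binomial with mean [predict_final_mean()] and size
#' `dispersion_k` (variance \eqn{\mu + \mu^2/k}). Means are floored at
#' 1e-10 so treatments with essentially complete mortality remain
#' numerically finite.
#'
#' @param data A `paired_counts` object from [pair_initial_final()] (or any
#'   data frame with columns `temperature`, `salinity`, `initial_count`,
#'   `final_count`).
#' @param params A [response_params()] object.
#' @param variant Model variant (see [predict_final_mean()]).
#' @return The total log-likelihood; 0 for empty data.
#' @export
negbin_loglik <- function(data, params, variant = "full") {
  variant <- match.arg(variant, .variants)
  if (nrow(data) == 0L) return(0)
  if (any(data$initial_count <= 0))
    stop("all records must have initial_count > 0", call. = FALSE)
  mu <- predict_final_mean(data$initial_count, data$temperature,
                           data$salinity, params, variant)
  mu <- pmax(mu, .MU_FLOOR)
  sum(stats::dnbinom(data$final_count, size = params$dispersion_k,
                     mu = mu, log = TRUE))
}
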