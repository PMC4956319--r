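#' Response-surface parameter set
#'
#' Bundles the seven surface parameters of the multiplicative
#' thermal-osmotic population model together with the negative-binomial
#' dispersion. The model states that the expected final polyp count in a
#' well is \deqn{E[P_{final}] = a \, F(T) \, G(S) \, P_{initial},} where
#' \eqn{a} is the maximum proportional change attained at the joint optimum,
#' and \eqn{F} and \eqn{G} are unitless asymmetric Gaussian response
#' functions of temperature and salinity (see [thermal_response()]).
#'
#' @param a Maximum proportional population change at the joint optimum
#'   (unitless, > 0). Values above 1 mean net proliferation at optimum.
#' @param t_opt Optimal temperature (degrees Celsius).
#' @param sigma_t_low,sigma_t_high Thermal curve-width parameters (degrees
#'   Celsius, > 0) governing the decay below and above `t_opt`.
#' @param s_opt Optimal salinity (parts per thousand).
#' @param sigma_s_low,sigma_s_high Osmotic curve-width parameters (ppt, > 0)
#'   governing the decay below and above `s_opt`.
#' @param dispersion_k Negative-binomial size parameter (> 0); the final
#'   count variance is \eqn{\mu + \mu^2/k}, so large `k` approaches Poisson.
#'
#' @return An object of class `response_params`: a named list of the eight
#'   numeric parameters.
#' @examples
#' # the published point estimates for Carukia barnesi polyps
#' p <- response_params(a = 11.48, t_opt = 22.91,
#'                      sigma_t_low = 3.47, sigma_t_high = 5.01,
#'                      s_opt = 26.04, sigma_s_low = 5.19,
#'                      sigma_s_high = 31.07, dispersion_k = 5)
#' thermal_response(22.91, p)  # 1 at the optimum
#' @export
response_params <- function(a, t_opt, sigma_t_low, sigma_t_high,
                            s_opt, sigma_s_low, sigma_s_high,
                            dispersion_k = 5) {
  p <- list(a = a, t_opt = t_opt,
            sigma_t_low = sigma_t_low, sigma_t_high = sigma_t_high,
            s_opt = s_opt,
            sigma_s_low = sigma_s_low, sigma_s_high = sigma_s_high,
            dispersion_k = dispersion_k)
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]))
      stop("parameter '", nm, "' must be a single finite number", call. = FALSE)
  }
  positive <- c("a", "sigma_t_low", "sigma_t_high",
                "sigma_s_low", "sigma_s_high", "dispersion_k")
  bad <- positive[vapply(positive, function(nm) p[[nm]] <= 0, logical(1))]
  if (length(bad))
    stop("parameter(s) ", paste(sQuote(bad), collapse = ", "),
         " must be strictly positive", call. = FALSE)
  structure(p, class = "response_params")
}

#' @export
print.response_params <- function(x, ...) {
  cat("Thermal-osmotic response parameters\n")
  cat(sprintf("  a (max proportional change): %.4g\n", x$a))
  cat(sprintf("  t_opt: %.4g degC   sigma_t (low/high): %.4g / %.4g degC\n",
              x$t_opt, x$sigma_t_low, x$sigma_t_high))
  cat(sprintf("  s_opt: %.4g ppt    sigma_s (low/high): %.4g / %.4g ppt\n",
              x$s_opt, x$sigma_s_low, x$sigma_s_high))
  cat(sprintf("  NB dispersion k: %.4g\n", x$dispersion_k))
  invisible(x)
}

# model variants: which multiplicative factor is constrained to 1
.variants <- c("full", "temperature_only", "salinity_only")

#' Free parameter names for a model variant
#'
#' The full model estimates all seven surface parameters plus the
#' dispersion. `temperature_only` fixes the osmotic factor at 1 (dropping
#' `s_opt`, `sigma_s_low`, `sigma_s_high`); `salinity_only` fixes the
#' thermal factor at 1 analogously.
#'
#' @param variant One of `"full"`, `"temperature_only"`, `"salinity_only"`.
#' @return Character vector of free parameter names (always includes `a`
#'   and `dispersion_k`).
#' @export
variant_free_params <- function(variant = .variants) {
  variant <- match.arg(variant)
  switch(variant,
    full = c("a", "t_opt", "sigma_t_low", "sigma_t_high",
             "s_opt", "sigma_s_low", "sigma_s_high", "dispersion_k"),
    temperature_only = c("a", "t_opt", "sigma_t_low", "sigma_t_high",
                         "dispersion_k"),
    salinity_only = c("a", "s_opt", "sigma_s_low", "sigma_s_high",
                      "dispersion_k"))
}
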