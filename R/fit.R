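#' Fit the thermal-osmotic population model by maximum likelihood
#'
#' Maximizes the negative-binomial log-likelihood of final polyp counts
#' over the variant's free parameters. Strictly positive parameters (the
#' maximum proportional change `a`, the four curve widths and the
#' dispersion `k`) are optimized on the log scale; the two optima on their
#' natural scale. Starting values are taken from the data (optima at the
#' treatment cell with the largest mean proportional change, `a` at that
#' maximum, widths at half the covariate range, `k = 5`) and the optimizer
#' is restarted from three fixed perturbations of that point to guard
#' against local maxima; the best log-likelihood wins, ties going to the
#' first. The whole procedure is deterministic: identical data, `init`
#' and `control` give an identical fit.
#'
#' @param data A `paired_counts` table from [pair_initial_final()].
#' @param variant `"full"`, `"temperature_only"` (osmotic factor fixed at
#'   1) or `"salinity_only"` (thermal factor fixed at 1).
#' @param init Optional [response_params()] giving starting values;
#'   default is data-driven as described above.
#' @param control List of optimizer settings: `maxit` (default 2000),
#'   `reltol` (1e-10), `multistart` (TRUE).
#' @return A `fit_result`: fitted [response_params()], `log_likelihood`,
#'   `n_params` (free parameters, counting `a` and `dispersion_k`),
#'   `aic = 2 n_params - 2 logLik`, `n_obs`, `converged` flag and an
#'   `optimizer_trace` with per-start diagnostics.
#' @examples
#' truth <- response_params(11.48, 22.91, 3.47, 5.01, 26.04, 5.19, 31.07)
#' tab <- simulate_experiment(synthetic_config(truth, seed = 1))
#' fit <- fit_model(pair_initial_final(tab, 6))
#' fit$params$t_opt
#' @export
fit_model <- function(data, variant = "full", init = NULL, control = list()) {
  variant <- match.arg(variant, .variants)
  stopifnot(is.data.frame(data))
  if (nrow(data) == 0L) stop("no paired observations to fit", call. = FALSE)
  .check_design(data, variant)
  ctl <- utils::modifyList(list(maxit = 2000, reltol = 1e-10,
                                multistart = TRUE), control)
  free <- variant_free_params(variant)
  nll <- .make_nll(data, variant, free)
  starts <- .start_values(data, variant, init, free,
                          multistart = isTRUE(ctl$multistart))
  # coarse pass over all starts, then a full refinement of the best one
  trace <- list()
  coarse <- lapply(seq_along(starts), function(i) {
    o <- stats::optim(starts[[i]], nll, method = "Nelder-Mead",
                      control = list(maxit = 400, reltol = 1e-7))
    trace[[i]] <<- list(start = starts[[i]], coarse_value = o$value)
    o
  })
  vals <- vapply(coarse, `[[`, numeric(1), "value")
  # fully refine the two best coarse candidates (coarse values can misrank
  # nearby basins); ties go to the earlier start
  keep <- order(vals)[seq_len(min(2L, length(vals)))]
  refined <- lapply(coarse[keep], function(cand) {
    o <- stats::optim(cand$par, nll, method = "Nelder-Mead",
                      control = list(maxit = ctl$maxit,
                                     reltol = ctl$reltol))
    polish <- tryCatch(
      stats::optim(o$par, nll, method = "BFGS",
                   control = list(maxit = 500, reltol = ctl$reltol)),
      error = function(e) o)
    if (polish$value <= o$value) polish else o
  })
  rvals <- vapply(refined, `[[`, numeric(1), "value")
  best <- refined[[which.min(rvals)]]
  params <- .theta_to_params(best$par, free)
  ll <- -best$value
  structure(list(
    variant = variant,
    params = params,
    free = free,
    theta = best$par,
    log_likelihood = ll,
    n_params = length(free),
    aic = 2 * length(free) - 2 * ll,
    n_obs = nrow(data),
    converged = best$convergence == 0L,
    optimizer_trace = trace), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Model fit (%s): logLik %.3f, AIC %.3f, n = %d, %s\n",
              x$variant, x$log_likelihood, x$aic, x$n_obs,
              if (x$converged) "converged" else "NOT converged"))
  est <- unlist(x$params[x$free])
  print(round(est, 4))
  invisible(x)
}

# --- parameter transforms -------------------------------------------------

.LOG_SCALE <- c("a", "sigma_t_low", "sigma_t_high",
                "sigma_s_low", "sigma_s_high", "dispersion_k")

.params_to_theta <- function(params, free) {
  th <- vapply(free, function(nm) {
    v <- params[[nm]]
    if (nm %in% .LOG_SCALE) log(v) else v
  }, numeric(1))
  names(th) <- free
  th
}

.theta_to_params <- function(theta, free) {
  # placeholders for factors the variant fixes at 1; never evaluated
  full <- list(a = 1, t_opt = 0, sigma_t_low = 1, sigma_t_high = 1,
               s_opt = 0, sigma_s_low = 1, sigma_s_high = 1,
               dispersion_k = 1)
  for (i in seq_along(free)) {
    nm <- free[i]
    v <- unname(theta[i])
    full[[nm]] <- if (nm %in% .LOG_SCALE) exp(v) else v
  }
  do.call(response_params, full)
}

# negative log-likelihood closure on the transformed scale; inlines the
# model mean to keep each evaluation cheap (the optimizer and the profile
# root-finder call it many thousand times). Agreement with the public
# negbin_loglik() path is asserted in the test suite.
.make_nll <- function(data, variant, free) {
  p0 <- data$initial_count
  tt <- data$temperature
  ss <- data$salinity
  y <- data$final_count
  is_log <- free %in% .LOG_SCALE
  ix <- function(nm) match(nm, free)
  i_a <- ix("a"); i_to <- ix("t_opt")
  i_tl <- ix("sigma_t_low"); i_th <- ix("sigma_t_high")
  i_so <- ix("s_opt"); i_sl <- ix("sigma_s_low"); i_sh <- ix("sigma_s_high")
  i_k <- ix("dispersion_k")
  useF <- variant != "salinity_only"
  useG <- variant != "temperature_only"
  function(theta) {
    if (any(!is.finite(theta)) || any(abs(theta) > 50)) return(1e10)
    v <- theta
    v[is_log] <- exp(v[is_log])
    mu <- v[i_a] * p0
    if (useF) {
      d <- v[i_to] - tt
      sig <- ifelse(tt > v[i_to], v[i_th], v[i_tl])
      mu <- mu * exp(-(d * d) / (sig * sig))
    }
    if (useG) {
      d <- v[i_so] - ss
      sig <- ifelse(ss > v[i_so], v[i_sh], v[i_sl])
      mu <- mu * exp(-(d * d) / (sig * sig))
    }
    ll <- sum(stats::dnbinom(y, size = v[i_k], mu = pmax(mu, .MU_FLOOR),
                             log = TRUE))
    if (!is.finite(ll)) return(1e10)
    -ll
  }
}

.check_design <- function(data, variant) {
  nt <- length(unique(data$temperature))
  ns <- length(unique(data$salinity))
  if (variant %in% c("full", "temperature_only") && nt < 4)
    stop("need at least 4 distinct temperatures to identify the thermal ",
         "curve; got ", nt, call. = FALSE)
  if (variant %in% c("full", "salinity_only") && ns < 4)
    stop("need at least 4 distinct salinities to identify the osmotic ",
         "curve; got ", ns, call. = FALSE)
}

.start_values <- function(data, variant, init, free, multistart = TRUE) {
  if (is.null(init)) {
    ratio <- data$final_count / data$initial_count
    cell <- paste(data$temperature, data$salinity)
    m <- tapply(ratio, cell, mean)
    top <- names(m)[which.max(m)]
    tv <- as.numeric(strsplit(top, " ")[[1]])
    t_rng <- range(data$temperature); s_rng <- range(data$salinity)
    init <- response_params(
      a = max(max(m), 1e-2),
      t_opt = tv[1],
      sigma_t_low = max(diff(t_rng) / 2, 1e-2),
      sigma_t_high = max(diff(t_rng) / 2, 1e-2),
      s_opt = tv[2],
      sigma_s_low = max(diff(s_rng) / 2, 1e-2),
      sigma_s_high = max(diff(s_rng) / 2, 1e-2),
      dispersion_k = 5)
  }
  base <- .params_to_theta(init, free)
  if (!multistart) return(list(base))
  # fixed perturbations: narrower curves, wider curves, shifted optima
  sig <- intersect(free, .LOG_SCALE)
  opt <- intersect(free, c("t_opt", "s_opt"))
  p1 <- base; p1[sig] <- p1[sig] + log(0.5)
  p2 <- base; p2[sig] <- p2[sig] + log(2)
  p3 <- base; p3[opt] <- p3[opt] + 2
  list(base, p1, p2, p3)
}

# --- profile likelihood ----------------------------------------------------

#' Profile-likelihood confidence limits for one parameter
#'
#' Finds the parameter values where the profile deviance
#' \eqn{2[\ell_{max} - \ell_{profile}(\theta)]} reaches the chi-squared(1)
#' quantile for the requested level (3.841 at 95%), re-maximizing all
#' other free parameters at each profiled value. The profile is traced on
#' the optimizer's transformed scale (log for positive parameters) by
#' stepping outward from the MLE in Wald-standard-error units until the
#' threshold is bracketed, then root-finding by bisection to a deviance
#' tolerance of 1e-4; limits are reported on the natural scale. If the
#' deviance never reaches the threshold within the search bounds (10
#' standard errors) the limit is reported as `-Inf`/`Inf`.
#'
#' @param data The `paired_counts` the model was fitted to.
#' @param fit A converged `fit_result` from [fit_model()].
#' @param param_name One of the fit's free parameter names.
#' @param level Confidence level in (0, 1); default 0.95.
#' @return A `profile_ci`: list with `param_name`, `level`, `lower`,
#'   `upper` and `mle`, satisfying `lower <= mle <= upper`.
#' @export
profile_ci <- function(data, fit, param_name, level = 0.95) {
  stopifnot(inherits(fit, "fit_result"))
  if (!fit$converged)
    stop("profile CIs require a converged fit", call. = FALSE)
  if (!param_name %in% fit$free)
    stop("'", param_name, "' is not a free parameter of the ",
         fit$variant, " model", call. = FALSE)
  if (!(is.numeric(level) && level > 0 && level < 1))
    stop("level must be in (0, 1)", call. = FALSE)
  free <- fit$free
  nll <- .make_nll(data, fit$variant, free)
  idx <- match(param_name, free)
  theta_hat <- fit$theta
  nll_min <- -fit$log_likelihood
  se <- .wald_se(nll, theta_hat)[idx]
  if (!is.finite(se) || se <= 0) se <- 0.25 * max(abs(theta_hat[idx]), 1)
  threshold <- stats::qchisq(level, df = 1)

  devfun <- .make_profile_devfun(nll, theta_hat, idx, nll_min)
  lower_t <- .profile_one_side(devfun, theta_hat[idx], se, threshold, -1)
  upper_t <- .profile_one_side(devfun, theta_hat[idx], se, threshold, +1)

  back <- function(v) if (param_name %in% .LOG_SCALE) exp(unname(v)) else unname(v)
  mle <- back(theta_hat[idx])
  lower <- if (is.finite(lower_t)) back(lower_t) else
    if (param_name %in% .LOG_SCALE) 0 else -Inf
  upper <- if (is.finite(upper_t)) back(upper_t) else Inf
  structure(list(param_name = param_name, level = level,
                 lower = lower, upper = upper, mle = mle),
            class = "profile_ci")
}

#' @export
print.profile_ci <- function(x, ...) {
  cat(sprintf("%s: %.4g  [%.4g, %.4g]  (%.0f%% profile likelihood)\n",
              x$param_name, x$mle, x$lower, x$upper, 100 * x$level))
  invisible(x)
}

# Wald SEs on the transformed scale from the numerical Hessian
.wald_se <- function(nll, theta) {
  H <- tryCatch(stats::optimHess(theta, nll), error = function(e) NULL)
  if (is.null(H)) return(rep(NA_real_, length(theta)))
  V <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(V)) return(rep(NA_real_, length(theta)))
  d <- diag(V)
  ifelse(d > 0, sqrt(d), NA_real_)
}

# minimized nll over the remaining parameters with component idx pinned at
# v0, starting from the rest of `start`
.profile_nll_at <- function(nll, start, idx, v0) {
  if (length(start) == 1L) return(nll(v0))
  obj <- function(rest) {
    th <- numeric(length(start))
    th[idx] <- v0
    th[-idx] <- rest
    nll(th)
  }
  o <- tryCatch(stats::optim(start[-idx], obj, method = "BFGS",
                             control = list(maxit = 300, reltol = 1e-10)),
                error = function(e) list(par = start[-idx],
                                         value = obj(start[-idx])))
  o2 <- stats::optim(o$par, obj, method = "Nelder-Mead",
                     control = list(maxit = 500, reltol = 1e-9))
  min(o$value, o2$value)
}

# profile deviance as a function of the profiled (transformed) value,
# re-optimizing the remaining parameters with a warm start
.make_profile_devfun <- function(nll, theta_hat, idx, nll_min) {
  warm <- theta_hat[-idx]
  function(v) {
    if (length(warm) == 0L) return(2 * (nll(v) - nll_min))
    obj <- function(rest) {
      th <- numeric(length(theta_hat))
      th[idx] <- v
      th[-idx] <- rest
      nll(th)
    }
    # warm-started quasi-Newton step, then a short simplex pass in case the
    # piecewise response surface left a kink in the path
    o <- tryCatch(stats::optim(warm, obj, method = "BFGS",
                               control = list(maxit = 200, reltol = 1e-9)),
                  error = function(e) list(par = warm, value = obj(warm)))
    o2 <- stats::optim(o$par, obj, method = "Nelder-Mead",
                       control = list(maxit = 300, reltol = 1e-8))
    if (o2$value < o$value) o <- o2
    warm <<- o$par
    2 * (o$value - nll_min)
  }
}

# walk outward from the MLE in SE-sized steps until the deviance threshold
# is bracketed, then bisect; returns the crossing or +-Inf if none within
# 10 SE. Deviance can be slightly negative near the MLE when the profile
# re-optimization improves on the global fit; it is floored at 0.
.profile_one_side <- function(devfun, mle, se, threshold, direction,
                              max_se = 10, dev_tol = 1e-4) {
  f <- function(v) max(devfun(v), 0) - threshold
  lo <- mle
  flo <- -threshold
  step <- 0.5 * se
  for (i in seq_len(ceiling(max_se / 0.5))) {
    hi <- mle + direction * i * step
    fhi <- f(hi)
    if (fhi >= 0) {
      r <- stats::uniroot(f, lower = min(lo, hi), upper = max(lo, hi),
                          f.lower = if (direction < 0) fhi else flo,
                          f.upper = if (direction < 0) flo else fhi,
                          tol = max(se * 1e-5, dev_tol * se / (2 * sqrt(threshold))))
      return(r$root)
    }
    lo <- hi
    flo <- fhi
  }
  direction * Inf
}

# --- model comparison ------------------------------------------------------

#' Compare nested model fits by AIC
#'
#' @param fit_full,fit_reduced Converged `fit_result`s on the same data.
#' @return List with `delta_aic = AIC(reduced) - AIC(full)`; large positive
#'   values mean the factor removed from the reduced model matters.
#' @export
compare_models <- function(fit_full, fit_reduced) {
  stopifnot(inherits(fit_full, "fit_result"),
            inherits(fit_reduced, "fit_result"))
  if (fit_full$n_obs != fit_reduced$n_obs)
    stop("fits were not made on the same data (n_obs differ)", call. = FALSE)
  if (!fit_full$converged || !fit_reduced$converged)
    warning("comparing fits that did not both converge", call. = FALSE)
  list(delta_aic = fit_reduced$aic - fit_full$aic)
}

# --- prediction surface ----------------------------------------------------

#' Predicted proportional-change surface and stability contour
#'
#' Evaluates the proportional population change \eqn{a F(T) G(S)} on a
#' temperature x salinity grid and locates the stability contour where the
#' predicted change equals 1 (populations neither grow nor shrink). Also
#' returns, in closed form, the stability temperature interval at the
#' optimal salinity: solving \eqn{a F(t) = 1} gives
#' \eqn{t_{opt} - \sigma_{t,low}\sqrt{\ln a}} and
#' \eqn{t_{opt} + \sigma_{t,high}\sqrt{\ln a}}.
#'
#' @param params A [response_params()] object.
#' @param t_grid,s_grid Sorted finite grids of temperatures (degC) and
#'   salinities (ppt).
#' @return A `prediction_surface`: list with `t_grid`, `s_grid`, `surface`
#'   (matrix, temperatures in rows), `contour` (list of data frames with
#'   `temperature`, `salinity` tracing the level-1 curve; empty when
#'   `a < 1`; the single optimum point when `a == 1`) and
#'   `stability_interval` (length-2 vector, `NA` when `a < 1`).
#' @export
prediction_surface <- function(params, t_grid, s_grid) {
  stopifnot(inherits(params, "response_params"))
  if (any(!is.finite(t_grid)) || any(!is.finite(s_grid)))
    stop("grids must be finite", call. = FALSE)
  if (is.unsorted(t_grid, strictly = TRUE) ||
      is.unsorted(s_grid, strictly = TRUE))
    stop("grids must be strictly increasing", call. = FALSE)
  surf <- params$a * outer(thermal_response(t_grid, params),
                           osmotic_response(s_grid, params))
  dimnames(surf) <- list(temperature = t_grid, salinity = s_grid)
  if (params$a < 1) {
    contour <- list()
    stab <- c(NA_real_, NA_real_)
  } else if (params$a == 1) {
    # the surface touches 1 only at the joint optimum
    contour <- list(data.frame(temperature = params$t_opt,
                               salinity = params$s_opt))
    stab <- c(params$t_opt, params$t_opt)
  } else {
    r <- sqrt(log(params$a))
    stab <- c(params$t_opt - params$sigma_t_low * r,
              params$t_opt + params$sigma_t_high * r)
    cl <- grDevices::contourLines(t_grid, s_grid, surf, levels = 1)
    contour <- lapply(cl, function(l)
      data.frame(temperature = l$x, salinity = l$y))
  }
  structure(list(t_grid = t_grid, s_grid = s_grid, surface = surf,
                 contour = contour, stability_interval = stab),
            class = "prediction_surface")
}
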