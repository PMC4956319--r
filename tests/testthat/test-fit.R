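test_that("fitting is deterministic and beats a grid-search oracle", {
  truth <- response_params(a = 2, t_opt = 22, sigma_t_low = 4,
                           sigma_t_high = 6, s_opt = 33, sigma_s_low = 6,
                           sigma_s_high = 12, dispersion_k = 3)
  cfg <- synthetic_config(truth, temperatures = c(16, 20, 24, 28),
                          salinities = 33, replicates = 10, seed = 5)
  paired <- pair_initial_final(simulate_experiment(cfg), 6)
  fit1 <- fit_model(paired, "temperature_only")
  fit2 <- fit_model(paired, "temperature_only")
  expect_identical(fit1$theta, fit2$theta)
  expect_identical(fit1$log_likelihood, fit2$log_likelihood)
  expect_true(fit1$converged)
  expect_equal(fit1$aic, 2 * 5 - 2 * fit1$log_likelihood)
  expect_equal(fit1$n_params, 5L)

  # oracle: exhaustive coarse lattice over all five free parameters can
  # never find a higher likelihood than the optimizer's maximum
  lattice <- expand.grid(a = exp(seq(log(0.5), log(6), length.out = 7)),
                         t_opt = seq(14, 30, length.out = 9),
                         sigma_t_low = c(2, 4, 8, 16),
                         sigma_t_high = c(2, 4, 8, 16),
                         dispersion_k = c(1, 3, 9))
  ll <- apply(lattice, 1, function(g)
    negbin_loglik(paired,
                  response_params(a = g["a"], t_opt = g["t_opt"],
                                  sigma_t_low = g["sigma_t_low"],
                                  sigma_t_high = g["sigma_t_high"],
                                  s_opt = 33, sigma_s_low = 1,
                                  sigma_s_high = 1,
                                  dispersion_k = g["dispersion_k"]),
                  "temperature_only"))
  expect_true(max(ll) <= fit1$log_likelihood + 1e-6)
})

test_that("designs with too few covariate levels are rejected", {
  d <- data.frame(temperature = rep(c(20, 25, 30), each = 4),
                  salinity = 33,
                  initial_count = rep(10, 12), final_count = rep(10, 12))
  expect_error(fit_model(d, "temperature_only"), "4 distinct temperatures")
  expect_error(fit_model(d, "full"), "temperatures|salinities")
  expect_error(fit_model(d[0, ], "full"), "no paired observations")
})

test_that("a no-growth experiment is fitted as a stable population", {
  # every well keeps its initial count across a 4x4 design: the fitted
  # surface must predict (essentially) no change anywhere
  grid <- expand.grid(temperature = c(18, 22, 26, 30),
                      salinity = c(20, 26, 32, 38))
  d <- data.frame(temperature = rep(grid$temperature, each = 2),
                  salinity = rep(grid$salinity, each = 2),
                  initial_count = rep(c(15, 22), 16))
  d$final_count <- d$initial_count
  fit <- fit_model(d, "full")
  mu_hat <- predict_final_mean(d$initial_count, d$temperature, d$salinity,
                               fit$params)
  expect_true(all(abs(mu_hat / d$initial_count - 1) < 0.05))
})

test_that("profile limits reduce to Wald limits for a quadratic likelihood", {
  # one-parameter toy: deviance ((v - m)/se)^2 is exactly quadratic, so the
  # profile crossing of the chi-square threshold must equal m +- z * se
  for (case in list(c(m = 0, se = 1), c(m = 3.7, se = 0.42),
                    c(m = -12, se = 5))) {
    dev <- function(v) ((v - case["m"]) / case["se"])^2
    thr <- qchisq(0.95, 1)
    lo <- polypniche:::.profile_one_side(dev, case[["m"]], case[["se"]], thr, -1)
    hi <- polypniche:::.profile_one_side(dev, case[["m"]], case[["se"]], thr, +1)
    z <- qnorm(0.975)
    expect_equal(lo, case[["m"]] - z * case[["se"]], tolerance = 1e-4)
    expect_equal(hi, case[["m"]] + z * case[["se"]], tolerance = 1e-4)
  }
  # a threshold of ~0 collapses the interval onto the point estimate
  dev <- function(v) v^2
  expect_equal(polypniche:::.profile_one_side(dev, 0, 1,
                                              qchisq(1e-9, 1), +1),
               0, tolerance = 1e-3)
})

test_that("profile intervals bracket the estimate at the stated deviance", {
  sp <- small_paired()
  fit <- fit_model(sp$paired)
  free <- fit$free
  nll <- polypniche:::.make_nll(sp$paired, "full", free)
  thr <- qchisq(0.95, 1)
  for (nm in c("t_opt", "a")) {
    ci <- profile_ci(sp$paired, fit, nm)
    expect_lte(ci$lower, ci$mle)
    expect_gte(ci$upper, ci$mle)
    expect_equal(ci$mle, fit$params[[nm]])
    # independent check: deviance at each reported limit hits the
    # chi-square(1) 95% quantile
    idx <- match(nm, free)
    for (lim in c(ci$lower, ci$upper)) {
      v <- if (nm %in% polypniche:::.LOG_SCALE) log(lim) else lim
      prof <- polypniche:::.profile_nll_at(nll, fit$theta, idx, v)
      expect_equal(2 * (prof + fit$log_likelihood), thr, tolerance = 0.05)
    }
    # shrinking the level collapses the interval towards the MLE
    tiny <- profile_ci(sp$paired, fit, nm, level = 1e-6)
    expect_lt(tiny$upper - tiny$lower, 0.2 * (ci$upper - ci$lower))
  }
  expect_error(profile_ci(sp$paired, fit, "s_opt", level = 2), "level")
  expect_error(profile_ci(sp$paired, fit, "nonesuch"), "free parameter")
  unconv <- fit; unconv$converged <- FALSE
  expect_error(profile_ci(sp$paired, unconv, "a"), "converged")
})

test_that("model comparison orders nested fits consistently", {
  sp <- small_paired()
  fit_full <- fit_model(sp$paired, "full")
  fit_t <- fit_model(sp$paired, "temperature_only")
  fit_s <- fit_model(sp$paired, "salinity_only")
  # the full model can never fit worse than either restriction
  expect_gte(fit_full$log_likelihood, fit_t$log_likelihood)
  expect_gte(fit_full$log_likelihood, fit_s$log_likelihood)
  # delta AIC is bounded below by the parameter-count difference
  expect_gte(compare_models(fit_full, fit_t)$delta_aic, -2 * 3)
  expect_identical(compare_models(fit_full, fit_full)$delta_aic, 0)
  short <- fit_t; short$n_obs <- short$n_obs - 1L
  expect_error(compare_models(fit_full, short), "same data")
})

test_that("the prediction surface locates the stability contour", {
  p <- published_params()
  tg <- seq(11, 34, by = 0.25)
  sg <- seq(16, 46, by = 0.25)
  surf <- prediction_surface(p, tg, sg)
  expect_equal(dim(surf$surface), c(length(tg), length(sg)))
  # the grid maximum approaches a from below (the exact optimum need not
  # be a grid point)
  expect_lte(max(surf$surface), 11.48)
  expect_gt(max(surf$surface), 11.48 * 0.999)
  # frozen closed-form stability interval at the optimal salinity:
  # t_opt -+ sigma * sqrt(ln a)
  expect_equal(surf$stability_interval, c(17.489013, 30.736843),
               tolerance = 1e-6)
  # every contour vertex lies on the level-1 curve of the model
  expect_gt(length(surf$contour), 0)
  for (seg in surf$contour) {
    vals <- predict_final_mean(1, seg$temperature, seg$salinity, p)
    expect_true(all(abs(vals - 1) < 0.02))
  }
  # a == 1: the surface touches 1 only at the joint optimum
  p1 <- response_params(1, 22.91, 3.47, 5.01, 26.04, 5.19, 31.07)
  s1 <- prediction_surface(p1, tg, sg)
  expect_equal(s1$contour,
               list(data.frame(temperature = 22.91, salinity = 26.04)))
  expect_equal(s1$stability_interval, c(22.91, 22.91))
  # a < 1: no stable region exists
  p0 <- response_params(0.6, 22.91, 3.47, 5.01, 26.04, 5.19, 31.07)
  s0 <- prediction_surface(p0, tg, sg)
  expect_length(s0$contour, 0)
  expect_true(all(is.na(s0$stability_interval)))
  expect_error(prediction_surface(p, rev(tg), sg), "increasing")
})
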