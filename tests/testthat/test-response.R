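test_that("response curves equal 1 at the optimum and match direct arithmetic", {
  p <- published_params()
  expect_identical(thermal_response(22.91, p), 1)
  expect_identical(osmotic_response(26.04, p), 1)
  # frozen values computed independently as exp(-(opt - x)^2 / sigma^2)
  expect_equal(thermal_response(18, p), 0.1350400035, tolerance = 1e-9)
  expect_equal(thermal_response(31, p), 0.0737198165, tolerance = 1e-9)
  expect_equal(osmotic_response(16, p), 0.0237007343, tolerance = 1e-9)
  expect_equal(osmotic_response(46, p), 0.6618582335, tolerance = 1e-9)
  # continuity across the branch switch at the optimum
  eps <- 1e-9
  expect_equal(thermal_response(22.91 - eps, p), 1, tolerance = 1e-12)
  expect_equal(thermal_response(22.91 + eps, p), 1, tolerance = 1e-12)
  expect_error(thermal_response(NaN, p), "finite")
  expect_error(osmotic_response(Inf, p), "finite")
})

test_that("response curves are bounded in (0,1], peak only at the optimum and decay monotonically", {
  for (seed in 1:20) {
    set.seed(seed)
    p <- response_params(a = exp(runif(1, -1, 3)),
                         t_opt = runif(1, 10, 35),
                         sigma_t_low = runif(1, 0.5, 10),
                         sigma_t_high = runif(1, 0.5, 10),
                         s_opt = runif(1, 15, 45),
                         sigma_s_low = runif(1, 0.5, 20),
                         sigma_s_high = runif(1, 0.5, 40))
    for (side in c(-1, 1)) {
      d <- sort(runif(25, 0, 15))
      ft <- thermal_response(p$t_opt + side * d, p)
      fs <- osmotic_response(p$s_opt + side * d, p)
      expect_true(all(ft > 0 & ft <= 1))
      expect_true(all(fs > 0 & fs <= 1))
      expect_true(all(diff(ft) < 0))  # strictly decreasing away from optimum
      expect_true(all(diff(fs) < 0))
      expect_true(all(ft[d > 0] < 1))  # 1 attained only at the optimum
    }
  }
})

test_that("predicted means multiply the published factors", {
  p <- published_params()
  expect_equal(predict_final_mean(1, 22.91, 26.04, p), 11.48)
  expect_identical(predict_final_mean(0, 11, 16, p), 0)
  # frozen product 11.48 * F(18) * G(46) * 18.63
  expect_equal(predict_final_mean(18.63, 18, 46, p), 19.11534582,
               tolerance = 1e-8)
  # reduced variants pin the excluded factor at 1
  expect_equal(predict_final_mean(10, 18, 16, p, "temperature_only"),
               10 * 11.48 * thermal_response(18, p))
  expect_equal(predict_final_mean(10, 18, 16, p, "salinity_only"),
               10 * 11.48 * osmotic_response(16, p))
  expect_error(predict_final_mean(-1, 22, 26, p), "non-negative")
})

test_that("negative binomial log-likelihood matches a hand-coded pmf", {
  p <- published_params(k = 2.5)
  # independent oracle: NB pmf written out in log-gamma terms
  nb_oracle <- function(x, mu, k)
    lgamma(x + k) - lgamma(k) - lfactorial(x) +
      k * log(k / (k + mu)) + x * log(mu / (k + mu))
  d <- data.frame(temperature = c(18, 25, 31), salinity = c(26, 33, 46),
                  initial_count = c(12, 20, 17), final_count = c(7, 150, 3))
  mu <- predict_final_mean(d$initial_count, d$temperature, d$salinity, p)
  expect_equal(negbin_loglik(d, p),
               sum(nb_oracle(d$final_count, mu, 2.5)), tolerance = 1e-10)
  # empty data contributes nothing
  expect_identical(negbin_loglik(d[0, ], p), 0)
  # invariant to observation order
  expect_equal(negbin_loglik(d[3:1, ], p), negbin_loglik(d, p))
  expect_error(negbin_loglik(transform(d, initial_count = c(0, 20, 17)), p),
               "initial_count")
})

test_that("the likelihood approaches the Poisson limit as dispersion grows", {
  p <- published_params(k = 1e9)
  set.seed(42)
  d <- data.frame(temperature = rep(c(21, 25), 20),
                  salinity = rep(c(26, 29), each = 20),
                  initial_count = rpois(40, 18) + 1)
  mu <- predict_final_mean(d$initial_count, d$temperature, d$salinity, p)
  d$final_count <- rpois(40, mu)
  pois <- sum(dpois(d$final_count, mu, log = TRUE))
  expect_equal(negbin_loglik(d, p) / nrow(d), pois / nrow(d),
               tolerance = 1e-3)
})

test_that("the optimizer's inlined objective agrees with the public likelihood", {
  sp <- small_paired()
  for (variant in c("full", "temperature_only", "salinity_only")) {
    free <- variant_free_params(variant)
    nll <- polypniche:::.make_nll(sp$paired, variant, free)
    set.seed(3)
    for (r in 1:5) {
      theta <- polypniche:::.params_to_theta(sp$truth, free) +
        rnorm(length(free), 0, 0.3)
      params <- polypniche:::.theta_to_params(theta, free)
      expect_equal(nll(theta), -negbin_loglik(sp$paired, params, variant),
                   tolerance = 1e-10)
    }
  }
})

test_that("parameter sets reject non-positive scales", {
  expect_error(response_params(0, 22, 3, 5, 26, 5, 31), "positive")
  expect_error(response_params(2, 22, -3, 5, 26, 5, 31), "positive")
  expect_error(response_params(2, 22, 3, 5, 26, 5, 31, dispersion_k = 0),
               "positive")
  expect_error(response_params(2, NA, 3, 5, 26, 5, 31), "finite")
})
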