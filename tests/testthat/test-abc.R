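test_that("profile RMSE matches hand arithmetic and its contracts", {
  expect_equal(rmse(c(a = 50, b = 50), c(a = 50, b = 50)), 0)
  expect_equal(rmse(c(a = 50, b = 50), c(a = 40, b = 60)), 10)
  # symmetric on identical support
  expect_equal(rmse(c(a = 30, b = 70), c(a = 40, b = 60)),
               rmse(c(a = 40, b = 60), c(a = 30, b = 70)))
  # missing predicted tags count as zero
  expect_equal(rmse(c(a = 50), c(a = 50, b = 10)), sqrt(mean(c(0, 10)^2)))
  # data-frame profiles concatenate entities
  obs <- data.frame(entity = c("x", "y"), tag = c("t", "t"),
                    percent = c(40, 60))
  pred <- data.frame(entity = c("x", "y"), tag = c("t", "t"),
                     percent = c(50, 50))
  expect_equal(rmse(pred, obs), 10)
  expect_error(rmse(numeric(0), numeric(0)), "empty")
})

test_that("weighted quantiles interpolate like type-7 under equal weights", {
  x <- c(1, 2, 3, 4); w <- rep(1, 4)
  expect_equal(weighted_quantile(x, w, c(0.025, 0.975)), c(1.075, 3.925))
  expect_equal(weighted_quantile(x, w, 0.5), 2.5)
  # agreement with stats::quantile type 7 on a larger equal-weight sample
  set.seed(2); y <- rnorm(31)
  expect_equal(weighted_quantile(y, rep(1, 31), c(0.1, 0.5, 0.9)),
               unname(quantile(y, c(0.1, 0.5, 0.9), type = 7)),
               tolerance = 1e-12)
  # hand computation under the weight-proportional spacing rule:
  # x = (1,2,3), w = (1,2,1) -> positions (0, 1/3, 1)
  expect_equal(weighted_quantile(c(1, 2, 3), c(1, 2, 1), 0.5), 2.25)
  # probabilities outside the end positions clamp to the extremes
  expect_equal(weighted_quantile(c(1, 2, 3), c(1, 2, 1), c(0, 1)), c(1, 3))
})

test_that("ABC-SMC refines a toy linear-map posterior towards the truth", {
  prior <- prior_spec(c(mu = 0), c(mu = 10))
  simulator <- function(theta) c(y = 3 * theta[["mu"]])
  observed <- c(y = 15)     # truth mu = 5
  pops <- abc_smc(prior, simulator, observed,
                  config = list(n = 100, max_generations = 10, seed = 7))
  eps <- vapply(pops, `[[`, numeric(1), "epsilon")
  expect_true(all(diff(eps[-1]) <= 1e-12))       # non-increasing
  for (p in pops) {
    expect_equal(sum(p$weights), 1, tolerance = 1e-9)
    expect_true(all(p$particles >= 0 & p$particles <= 10))
    expect_true(all(p$distances[p$generation > 0] <= p$epsilon))
  }
  final <- pops[[length(pops)]]
  expect_equal(unname(map_estimate(final)["mu"]), 5, tolerance = 0.02 * 5)
  ci <- credible_interval(final)
  expect_true(ci["lo", "mu"] <= 5 && 5 <= ci["hi", "mu"])
})

test_that("ABC-SMC is deterministic under a fixed seed", {
  prior <- prior_spec(c(a = -1, b = -1), c(a = 1, b = 1))
  simulator <- function(theta) c(s = theta[["a"]] + 2 * theta[["b"]])
  cfg <- list(n = 40, max_generations = 4, seed = 123)
  p1 <- abc_smc(prior, simulator, c(s = 0.5), config = cfg)
  p2 <- abc_smc(prior, simulator, c(s = 0.5), config = cfg)
  expect_identical(p1, p2)
})

test_that("failed simulations are rejected without aborting the sampler", {
  prior <- prior_spec(c(mu = 0), c(mu = 1))
  simulator <- function(theta)
    if (theta[["mu"]] > 0.5) NULL else c(y = theta[["mu"]])
  pops <- abc_smc(prior, simulator, c(y = 0.2),
                  config = list(n = 30, max_generations = 3, seed = 11))
  for (p in pops)
    expect_true(all(p$particles[, "mu"] <= 0.5))
})

test_that("MAP lands in the dominant mode and degenerate cases warn", {
  set.seed(31)
  theta <- rbind(matrix(rnorm(160, 0, 0.05), ncol = 2),
                 matrix(rnorm(40, 3, 0.05), ncol = 2))
  w <- c(rep(0.8 / 80, 80), rep(0.2 / 20, 20))
  pop <- structure(list(particles = theta, weights = w,
                        distances = rep(0, 100), epsilon = 1,
                        generation = 1L),
                   class = "particle_population")
  expect_lt(max(abs(map_estimate(pop))), 1)
  one <- structure(list(particles = matrix(2, 1, 1,
                                           dimnames = list(NULL, "p")),
                        weights = 1, distances = 0, epsilon = 1,
                        generation = 1L),
                   class = "particle_population")
  expect_warning(m <- map_estimate(one), "single")
  expect_equal(unname(m), 2)
  expect_warning(ci <- credible_interval(one), "degenerate")
  expect_equal(unname(ci["lo", 1]), 2)
})

test_that("widening the prior never shrinks the credible interval", {
  simulator <- function(theta) c(y = theta[["mu"]])
  cfg <- list(n = 60, max_generations = 5, seed = 17)
  narrow <- abc_smc(prior_spec(c(mu = 4), c(mu = 6)), simulator,
                    c(y = 5), config = cfg)
  wide <- abc_smc(prior_spec(c(mu = 0), c(mu = 10)), simulator,
                  c(y = 5), config = cfg)
  wn <- diff(credible_interval(narrow[[length(narrow)]])[, "mu"])
  ww <- diff(credible_interval(wide[[length(wide)]])[, "mu"])
  expect_gte(ww, wn - 1e-9)
})

test_that("uniform priors sample and evaluate inside their support", {
  pr <- prior_spec(c(a = 1, b = -2), c(a = 3, b = 0))
  set.seed(8)
  draws <- glykin:::.prior_sample(pr, 500)
  expect_true(all(draws[, "a"] >= 1 & draws[, "a"] <= 3))
  expect_true(all(draws[, "b"] >= -2 & draws[, "b"] <= 0))
  expect_equal(glykin:::.prior_density(pr, c(a = 2, b = -1)), 1 / 4)
  expect_equal(glykin:::.prior_density(pr, c(a = 5, b = -1)), 0)
  expect_error(prior_spec(c(a = 1), c(a = 1)), "lo < hi")
})
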