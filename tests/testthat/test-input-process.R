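test_that("input trajectories validate their grid", {
  expect_error(input_trajectory(c(1, 2), c(0, 0)), "start at time 0")
  expect_error(input_trajectory(c(0, 2, 1), c(1, 1, 1)), "strictly increasing")
  expect_error(input_trajectory(c(0, 1), c(1, Inf)), "finite")
  expect_error(input_trajectory(c(0, 1), 1), "equal length")
})

test_that("value_at respects the declared interpolation rule", {
  step <- input_trajectory(c(0, 1, 2), c(10, 20, 5))
  expect_equal(value_at(step, c(0, 0.5, 1, 1.5, 2)), c(10, 10, 20, 20, 5))
  lin <- input_trajectory(c(0, 1, 2), c(10, 20, 5), interpolation = "linear")
  expect_equal(value_at(lin, c(0.5, 1.5)), c(15, 12.5))
  expect_error(value_at(step, 3), "outside")
})

test_that("window_sup is an exact supremum and dominates the path", {
  step <- input_trajectory(c(0, 1, 2, 3), c(1, 5, 2, 8))
  expect_equal(window_sup(step, 0, 0.5), 1)   # value carried from the left
  expect_equal(window_sup(step, 0, 1.5), 5)   # grid point inside window
  expect_equal(window_sup(step, 1.2, 0.5), 5) # left-carried value again
  expect_equal(window_sup(step, 2.5, 10), 8)  # window clipped at horizon
  lin <- input_trajectory(c(0, 1, 2, 3), c(1, 5, 2, 8), interpolation = "linear")
  expect_equal(window_sup(lin, 0, 0.5), 3)    # attained at the open right end
  expect_error(window_sup(step, 0, 0), "positive")

  # property: the window sup dominates the interpolated path inside the window
  set.seed(7)
  ou <- ou_process(2, 1, sigma2 = 1, dt = 0.05, T = 20, seed = 11)
  for (i in 1:50) {
    t0 <- runif(1, 0, 19)
    L <- runif(1, 0.01, 1)
    B <- window_sup(ou, t0, L)
    ts <- seq(t0, min(t0 + L * (1 - 1e-9), 20), length.out = 25)
    expect_true(all(value_at(ou, ts) <= B + 1e-12))
    # and it is monotone in the window length
    expect_lte(B, window_sup(ou, t0, L + 0.5) + 1e-12)
  }
})

test_that("circadian rate has the prescribed values, period and exact average", {
  kdp <- 5
  k <- circadian_rate(kdp, f = 1 / 24, dt = 0.1, T = 48)
  expect_equal(value_at(k, 0), 4 * kdp)
  expect_equal(value_at(k, 6), 8 * kdp)       # sin peak at a quarter period
  expect_equal(value_at(k, 18), 0, tolerance = 1e-12)
  expect_equal(value_at(k, 24), 4 * kdp)      # 24 h period
  # time-average of k(t)/kdp over one full period is exactly 4
  one <- circadian_rate(kdp, f = 1 / 24, dt = 0.1, T = 24)
  avg <- sum(diff(one$times) * (one$values[-length(one$values)] +
                                  one$values[-1]) / 2) / (24 * kdp)
  expect_equal(avg, 4, tolerance = 1e-10)
})

test_that("OU generator is reproducible and recovers its stationary law", {
  a <- ou_process(3, 0.5, sigma2 = 2, dt = 0.01, T = 50, seed = 99)
  b <- ou_process(3, 0.5, sigma2 = 2, dt = 0.01, T = 50, seed = 99)
  expect_identical(a$values, b$values)
  expect_false(identical(
    a$values, ou_process(3, 0.5, sigma2 = 2, dt = 0.01, T = 50, seed = 100)$values))

  long <- ou_process(3, 1, sigma2 = 2, dt = 0.01, T = 2000, seed = 5)
  expect_equal(mean(long$values), 3, tolerance = 0.1)
  v <- stats::var(long$values)
  se <- batch_se(long$values, 40, stats::var)
  expect_lt(abs(v - 2), 3 * se + 1e-9)

  # exact AR(1) discretization agrees with Euler-Maruyama at small dt*gamma
  ex <- ou_process(3, 1, sigma2 = 2, dt = 0.01, T = 2000, seed = 5, scheme = "exact")
  expect_equal(stats::var(ex$values), v, tolerance = 0.1)
})

test_that("OU autocovariance decays exponentially with the prescribed rate", {
  gam <- 0.8
  ou <- ou_process(0, gam, sigma2 = 3, dt = 0.01, T = 3000, seed = 21)
  ac <- sample_autocovariance(ou, lags = c(0, 0.5, 1, 1.5, 2))
  # lag-0 autocovariance is the biased sample variance by construction
  n <- length(ou$values)
  expect_equal(ac$autocov[1], stats::var(ou$values) * (n - 1) / n)
  expect_equal(ac$autocov[2], 3 * exp(-gam * 0.5), tolerance = 0.15)
  # regression of log autocov on lag recovers gamma
  slope <- stats::coef(stats::lm(log(ac$autocov) ~ ac$lag))[2]
  expect_equal(unname(slope), -gam, tolerance = 0.15)
})

test_that("OU argument validation and discretization warning", {
  expect_error(ou_process(1, -1, sigma2 = 1, dt = 0.1, T = 1), "gamma")
  expect_error(ou_process(1, 1, dt = 0.1, T = 1), "sigma2 or cv")
  expect_error(ou_process(-1, 1, cv = 0.5, dt = 0.1, T = 1), "mu > 0")
  expect_warning(ou_process(1, 1, sigma2 = 1, dt = 0.5, T = 10), "dt \\* gamma")
  # cv parameterization means sigma2 = (cv * mu)^2
  ou <- ou_process(10, 1, cv = 0.3, dt = 0.01, T = 1, seed = 1)
  expect_equal(ou$meta$sigma2, 9)
})

test_that("normalized lognormal rate has unit-mean noise factor", {
  # normalization constant <exp(xi)> = exp(sigma2/2), cross-checked Monte Carlo
  set.seed(31)
  mc <- mean(exp(sqrt(5) * rnorm(2e6)))
  expect_equal(mc, exp(2.5), tolerance = 0.05)

  ou <- ou_process(0, 1, sigma2 = 5, dt = 0.01, T = 10, seed = 3)
  k <- lognormal_normalized_rate(ou, k_bar = 7)
  expect_equal(k$values, 7 * exp(-2.5) * exp(ou$values))

  # ergodic check of the stationary mean at moderate log-variance
  ou1 <- ou_process(0, 1, sigma2 = 1, dt = 0.01, T = 3000, seed = 13)
  k1 <- lognormal_normalized_rate(ou1, k_bar = 7)
  expect_equal(mean(k1$values), 7, tolerance = 7 * 0.15)

  expect_error(lognormal_normalized_rate(
    input_trajectory(c(0, 1), c(0, 0)), k_bar = 1), "sigma2")
})

test_that("modulated circadian rate combines amplitude noise and the sinusoid", {
  ou <- ou_process(0, 0.1, sigma2 = 0.125, dt = 0.05, T = 48, seed = 17)
  k <- modulated_circadian_rate(ou, amplitude = 20, f = 1 / 24)
  expect_equal(k$values, 20 * exp(ou$values) * (1 + sin(2 * pi * ou$times / 24)))
  expect_true(all(k$values >= 0))
})

test_that("summed OU processes add their stationary variances", {
  s <- sum_of_ou(list(list(mu = 1, gamma = 1, sigma2 = 1),
                      list(mu = 2, gamma = 0.5, sigma2 = 2)),
                 dt = 0.01, T = 3000, seed = 8)
  expect_equal(mean(s$values), 3, tolerance = 0.25)
  v <- stats::var(s$values)
  se <- batch_se(s$values, 40, stats::var)
  expect_lt(abs(v - 3), 4 * se + 1e-9)
})

test_that("CSV round trip preserves values, interpolation and metadata", {
  ou <- ou_process(2, 1, sigma2 = 0.5, dt = 0.1, T = 5, seed = 4)
  path <- file.path(tempdir(), "input-roundtrip.csv")
  write_input_csv(ou, path)
  back <- read_input_csv(path)
  expect_equal(back$times, ou$times)
  expect_equal(back$values, ou$values)
  expect_identical(back$interpolation, "left-constant")
  expect_identical(back$meta$generator, "ou")
  expect_equal(back$meta$sigma2, 0.5)
  unlink(c(path, paste0(path, ".meta.json")))
})
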