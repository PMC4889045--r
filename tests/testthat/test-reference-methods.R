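test_that("with constant input SIA is a plain SSA and matches Extrande", {
  k <- 5; kd <- 0.5; T <- 30
  net <- birth_death_network(k = k, kd = kd)
  inp <- const_input(1, T)
  n <- 300
  run <- function(method, seed0) vapply(seq_len(n), function(i) {
    r <- if (method == "sia") sia(net, c(X = 0), inp, T, seed = seed0 + i)
         else extrande(net, c(X = 0), inp, T, L = 5, seed = seed0 + i)
    c(first = r$times[match(TRUE, !is.na(r$channel))], final = r$x_final[["X"]])
  }, numeric(2))
  s <- run("sia", 100)
  e <- run("extrande", 9000)
  expect_gt(stats::ks.test(s["first", ], stats::pexp, rate = k)$p.value, 1e-3)
  se <- sqrt(k / kd / n)  # stationary Poisson(10) marginal
  expect_lt(abs(mean(s["final", ]) - 10), 3 * se)
  expect_lt(abs(mean(s["final", ]) - mean(e["final", ])), 3 * sqrt(2) * se)
})

test_that("SIA freezes the input at the last firing and can trap at zero propensity", {
  net <- birth_death_network(k = 2, kd = 1)
  # input is zero at t = 0, positive afterwards; starting from X = 0 the stale
  # propensity is zero forever: SIA emits no events and reports the trap
  inp <- input_trajectory(c(0, 1, 10), c(0, 5, 5))
  expect_warning(tr <- sia(net, c(X = 0), inp, 10, seed = 1), "trapped")
  expect_true(tr$trapped)
  expect_identical(sum(!is.na(tr$channel)), 0L)
  expect_equal(tr$x_final[["X"]], 0)
  # Extrande sees the input rise and simulates events on the same input
  ex <- extrande(net, c(X = 0), inp, 10, seed = 1)
  expect_gt(sum(!is.na(ex$channel)), 0)
})

test_that("SIA overstates zero occupancy under a rising input", {
  # low-copy two-stage system with a transcription rate that starts near zero:
  # the stale-input method lingers in the empty state much longer
  net <- two_stage_network(ks = 1, kdm = 2, kdp = 1)
  zf <- function(method) {
    vals <- vapply(1:30, function(i) {
      inp <- input_trajectory(c(0, 2, 50), c(0.02, 3, 3))
      r <- if (method == "sia")
        suppressWarnings(sia(net, c(M = 0, P = 0), inp, 50, seed = 400 + i))
      else extrande(net, c(M = 0, P = 0), inp, 50, seed = 400 + i)
      zero_occupancy_fraction(r, "M")
    }, numeric(1))
    mean(vals)
  }
  expect_gt(zf("sia"), zf("extrande"))
})

test_that("with constant propensities the integral method is the next-reaction method", {
  k <- 5; kd <- 0.5; T <- 30
  net <- birth_death_network(k = k, kd = kd)
  inp <- const_input(1, T)
  n <- 300
  res <- vapply(seq_len(n), function(i) {
    r <- mn_integral(net, c(X = 0), inp, T, dt_int = 0.05, seed = 2000 + i)
    c(first = r$times[match(TRUE, !is.na(r$channel))], final = r$x_final[["X"]])
  }, numeric(2))
  expect_gt(stats::ks.test(res["first", ], stats::pexp, rate = k)$p.value, 1e-3)
  expect_lt(abs(mean(res["final", ]) - 10), 3 * sqrt(10 / n))
})

test_that("pure-birth counts under a sinusoidal rate match the analytic Poisson mean", {
  # lambda(t) = 4(1 + sin(2 pi t / 24)) integrates to 96 over one day
  net <- birth_death_network(k = 1, kd = 0)
  inp <- circadian_rate(1, dt = 0.01, T = 24)
  n <- 300
  counts <- vapply(seq_len(n), function(i)
    mn_integral(net, c(X = 0), inp, 24, dt_int = 0.01, seed = 3000 + i,
                record_events = FALSE)$x_final[["X"]], numeric(1))
  expect_lt(abs(mean(counts) - 96), 3 * sqrt(96 / n))
})

test_that("coarse integration steps miss propensity transients; fine steps converge", {
  # baseline rate 0.1 plus a sharp triangular spike (height 50, width 0.2 h,
  # area 5) at t = 3: a 2 h integration step whose endpoints straddle the
  # spike never sees it, so the coarse integral method loses ~5 of the 5.6
  # expected events, while steps matching the input grid are exact (the
  # trapezoid rule is exact on a piecewise-linear rate at its breakpoints)
  T <- 6
  tt <- seq(0, T, by = 0.005)
  lam <- 0.1 + pmax(0, 50 * (1 - abs(tt - 3) / 0.1))
  inp <- input_trajectory(tt, lam, interpolation = "linear")
  lambda_int <- 0.1 * 6 + 5  # exact integral of the interpolated rate
  net <- birth_death_network(k = 1, kd = 0)
  n <- 500
  mean_count <- function(dt_int, seed0) {
    counts <- vapply(seq_len(n), function(i)
      suppressWarnings(mn_integral(net, c(X = 0), inp, T, dt_int = dt_int,
                                   seed = seed0 + i,
                                   record_events = FALSE))$x_final[["X"]],
      numeric(1))
    mean(counts)
  }
  coarse <- mean_count(2, 4000)
  fine <- mean_count(0.005, 8000)
  expect_lt(coarse, 2)  # the spike is invisible at the coarse step
  expect_lt(abs(fine - lambda_int), 3 * sqrt(lambda_int / n))
  expect_lt(abs(fine - lambda_int), abs(coarse - lambda_int))
  # a dt_int coarser than the input grid warns that accuracy degrades
  expect_warning(mn_integral(net, c(X = 0), inp, T, dt_int = 2, seed = 1),
                 "coarser")
})

test_that("the direct-integral variant agrees with the per-channel variant", {
  net <- birth_death_network(k = 5, kd = 0.5)
  inp <- circadian_rate(1, dt = 0.01, T = 24)
  n <- 200
  finals <- function(variant, seed0) vapply(seq_len(n), function(i)
    mn_integral(net, c(X = 0), inp, 24, dt_int = 0.01, variant = variant,
                seed = seed0 + i, record_events = FALSE)$x_final[["X"]],
    numeric(1))
  a <- finals("modified-next", 100)
  b <- finals("direct", 7000)
  # both sample the same law; compare marginal means (variance ~ Poisson-like)
  se <- sqrt((stats::var(a) + stats::var(b)) / n)
  expect_lt(abs(mean(a) - mean(b)), 3 * se)
})

test_that("integral method validates its arguments", {
  net <- birth_death_network()
  inp <- const_input(1, 5)
  expect_error(mn_integral(net, c(X = 0), inp, 5, dt_int = 0), "positive")
  cust <- reaction_network("X", list(
    custom_reaction(NULL, c(X = 1), function(x, input, t) 1)))
  expect_error(mn_integral(cust, c(X = 0), inp, 5, dt_int = 0.1), "mass-action")
})
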