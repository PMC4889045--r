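test_that("simulation is reproducible from a seed", {
  net <- two_stage_network(ks = 5, kdm = 2, kdp = 0.5)
  inp <- circadian_rate(0.5, dt = 0.05, T = 24)
  a <- extrande(net, c(M = 0, P = 0), inp, 24, seed = 42)
  b <- extrande(net, c(M = 0, P = 0), inp, 24, seed = 42)
  expect_identical(a$times, b$times)
  expect_identical(a$states, b$states)
  expect_identical(a$stats, b$stats)
  c2 <- extrande(net, c(M = 0, P = 0), inp, 24, seed = 43)
  expect_false(identical(a$times, c2$times))
})

test_that("event statistics satisfy the thinning ledger invariant", {
  net <- two_stage_network(ks = 5, kdm = 2, kdp = 0.5)
  inp <- circadian_rate(0.5, dt = 0.05, T = 24)
  for (L in list(0.5, 6, "horizon")) {
    s <- extrande(net, c(M = 0, P = 0), inp, 24, L = L, seed = 1,
                  record_events = FALSE)$stats
    expect_identical(unname(s["n_exponentials_drawn"]),
                     unname(s["n_accepted"] + s["n_thinned"] + s["n_rejected"]))
  }
})

test_that("compute_bound dominates the total propensity over the window", {
  net <- two_stage_network(ks = 5, kdm = 2, kdp = 0.5)
  x <- c(M = 2, P = 40)
  # constant input: every strategy returns exactly a0
  cst <- const_input(3, 10)
  a0 <- total_propensity(net, x, 3)$a0
  for (s in c("window-max", "monotone-sup", "global"))
    expect_equal(compute_bound(net, x, cst, 2, 1, strategy = s)$B, a0)

  # the effective horizon is clipped at the trajectory end
  expect_equal(compute_bound(net, x, cst, 8, 5)$L_effective, 2)

  # for an input-monotone network window-max and monotone-sup coincide, and
  # the global ceiling dominates both
  ou <- ou_process(4, 1, sigma2 = 1, dt = 0.02, T = 20, seed = 2)
  set.seed(14)
  for (i in 1:30) {
    t0 <- runif(1, 0, 19)
    L <- runif(1, 0.05, 2)
    bw <- compute_bound(net, x, ou, t0, L, strategy = "window-max")$B
    bm <- compute_bound(net, x, ou, t0, L, strategy = "monotone-sup")$B
    bg <- compute_bound(net, x, ou, t0, L, strategy = "global")$B
    expect_equal(bw, bm)
    expect_gte(bg, bw - 1e-12)
    # and the bound dominates a0 sampled inside the window
    ts <- seq(t0, min(t0 + L * (1 - 1e-9), 20), length.out = 10)
    a0s <- vapply(ts, function(tt)
      total_propensity(net, x, value_at(ou, tt))$a0, numeric(1))
    expect_true(all(a0s <= bw + 1e-10))
  }
  expect_error(compute_bound(net, x, cst, 11, 1), "horizon")
})

test_that("constant input recovers the Poisson stationary law (thinning reduces to SSA)", {
  net <- birth_death_network(k = 5, kd = 0.5)
  traj <- extrande(net, c(X = 0), const_input(1, 2000), 2000, L = 10, seed = 3)
  avg <- summary(traj)$time_averages[["X"]]
  # stationary Poisson(10); SE of the time average from the O-U-like
  # autocorrelation of X: sqrt(var * 2 / (kd * T))
  se <- sqrt(10 * 2 / (0.5 * 2000))
  expect_lt(abs(avg - 10), 4 * se)
})

test_that("acceptance fraction matches the thinning identity for a constant bound", {
  # pure birth with a state-independent propensity a0(t) = k(t): with the
  # global bound B = max k, the accepted fraction estimates <k>/B = 1/2
  net <- birth_death_network(k = 1, kd = 0)
  inp <- circadian_rate(1, dt = 0.05, T = 240)
  s <- extrande(net, c(X = 0), inp, 240, L = "horizon", bound = "global",
                seed = 8, record_events = FALSE)$stats
  frac <- s[["n_accepted"]] / s[["n_exponentials_drawn"]]
  se <- sqrt(0.25 / s[["n_exponentials_drawn"]])
  expect_lt(abs(frac - 0.5), 3 * se + 1e-6)
})

test_that("event statistics vs L behave as the look-ahead trade-off predicts", {
  net <- birth_death_network(k = 2, kd = 0.5)
  inp <- circadian_rate(1, dt = 0.05, T = 48)
  tab <- event_stats_vs_L(net, c(X = 0), inp, 48,
                          L_values = c(0.2, 2, 12, 48), seed = 5)
  expect_identical(nrow(tab), 4L)
  expect_equal(tab$pct_accepted + tab$pct_thinned + tab$pct_rejected,
               rep(100, 4), tolerance = 1e-9)
  # L >= T: only terminal clipping can reject
  expect_lte(tab$n_rejected[4], 1)
  # short look-aheads reject far more often
  expect_gt(tab$n_rejected[1], tab$n_rejected[3])
  expect_error(event_stats_vs_L(net, c(X = 0), inp, 48, numeric(0)), "non-empty")
})

test_that("grid sampling of the state path matches the recorded event path", {
  net <- two_stage_network(ks = 5, kdm = 2, kdp = 0.5)
  inp <- circadian_rate(0.5, dt = 0.05, T = 24)
  tt <- seq(0.3, 23.7, length.out = 41)
  traj <- extrande(net, c(M = 0, P = 0), inp, 24, seed = 9, out_times = tt)
  expect_identical(dim(traj$grid_states), c(41L, 2L))
  expect_equal(unname(traj$grid_states), unname(sample_path(traj, tt)))
})

test_that("adaptive look-ahead and pilot-chosen L remain exact", {
  net <- birth_death_network(k = 5, kd = 0.5)
  inp <- circadian_rate(1, dt = 0.05, T = 200)
  for (args in list(list(adaptive_L = TRUE, L = 1), list(L = "auto"))) {
    traj <- do.call(extrande, c(list(net, c(X = 0), inp, 200, seed = 10,
                                     record_events = FALSE), args))
    avg <- traj$x_final[["X"]]  # stationary, mean k<I>/kd = 10 * <1+sin> = ~10
    expect_true(avg >= 0)
    s <- traj$stats
    expect_identical(unname(s["n_exponentials_drawn"]),
                     unname(s["n_accepted"] + s["n_thinned"] + s["n_rejected"]))
  }
})

test_that("compiled and pure-R simulation paths agree in distribution", {
  k <- 2; kd <- 0.5; T <- 8
  net_ma <- birth_death_network(k = k, kd = kd)
  net_cu <- reaction_network("X", list(
    custom_reaction(NULL, c(X = 1),
                    function(x, input, t) k * max(input, 0), name = "birth"),
    custom_reaction(c(X = 1), NULL,
                    function(x, input, t) kd * x[["X"]], name = "death")),
    input_monotone = TRUE)
  inp <- const_input(1, T)
  n <- 150
  run <- function(net, seed0) vapply(seq_len(n), function(i) {
    r <- extrande(net, c(X = 0), inp, T, L = 2, seed = seed0 + i)
    c(first = r$times[match(TRUE, !is.na(r$channel))], final = r$x_final[["X"]])
  }, numeric(2))
  ma <- run(net_ma, 1000)
  cu <- run(net_cu, 5000)
  # first reaction from the empty state is Exp(k) under both paths
  expect_gt(stats::ks.test(ma["first", ], stats::pexp, rate = k)$p.value, 1e-3)
  expect_gt(stats::ks.test(cu["first", ], stats::pexp, rate = k)$p.value, 1e-3)
  m_target <- (k / kd) * (1 - exp(-kd * T))
  se <- sqrt(m_target / n)  # near-Poisson marginal
  expect_lt(abs(mean(ma["final", ]) - m_target), 3 * se)
  expect_lt(abs(mean(cu["final", ]) - m_target), 3 * se)
})

test_that("a misdeclared monotone bound triggers the bound-violation hard failure", {
  # fault injection: the propensity decreases in the input, so declaring the
  # network input-monotone makes the monotone-sup bound invalid
  net <- reaction_network("X", list(
    custom_reaction(NULL, c(X = 1),
                    function(x, input, t) 50 / (1 + max(input, 0)))),
    input_monotone = TRUE)
  ramp <- input_trajectory(c(0, 10), c(9, 0), interpolation = "linear")
  expect_error(
    extrande(net, c(X = 0), ramp, 10, L = 5, bound = "monotone-sup", seed = 6),
    "bound violated")
})

test_that("argument validation rejects malformed simulator calls", {
  net <- birth_death_network()
  inp <- const_input(1, 5)
  expect_error(extrande(net, c(X = 0), inp, 10), "cover")
  expect_error(extrande(net, c(X = 0), inp, 5, safety = 0.5), "safety")
  expect_error(extrande(net, c(X = 0), inp, 5, L = -1), "positive")
  expect_error(extrande(net, c(X = 0), inp, -1), "positive")
  cust <- reaction_network("X", list(
    custom_reaction(NULL, c(X = 1), function(x, input, t) 1)))
  expect_error(extrande(cust, c(X = 0), inp, 5, bound = "monotone-sup"),
               "not declared input-monotone")
})
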