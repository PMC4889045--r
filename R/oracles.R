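#' Conditional moment ODEs for the two-stage model
#'
#' For the two-stage expression network the first moments conditional on the
#' transcription trajectory obey the closed linear system
#' \deqn{d\langle m\rangle/dt = k(t) - k_{dm}\langle m\rangle, \quad
#'       d\langle n\rangle/dt = k_s\langle m\rangle - k_{dp}\langle n\rangle,}
#' which is exact (no moment closure) because all propensities are linear.
#' For a left-constant transcription trajectory the system is integrated
#' *exactly*: on every grid interval `k` is constant and the linear system is
#' advanced by its closed-form solution (decoupled via `w = n + ks m /
#' (kdm - kdp)`), so the only error is floating point. Linearly interpolated
#' inputs use the interval midpoint value (second-order accurate in the grid
#' step). Unconditionally stable for stiff rate constants.
#'
#' @param k_traj transcription-rate [input_trajectory()] (deterministic or one
#'   realization of a stochastic rate).
#' @param ks,kdm,kdp two-stage rate constants (per hour).
#' @param T horizon (hours).
#' @param times output grid; default 1000 points on `[0, T]`.
#' @param m0,n0 initial means (default 0).
#' @return data.frame (`time`, `m`, `n`) with attribute
#'   `provenance = "ode-exact"` (a mean trajectory).
#' @export
conditional_mean_ode <- function(k_traj, ks, kdm, kdp, T,
                                 times = seq(0, T, length.out = 1001),
                                 m0 = 0, n0 = 0) {
  stopifnot(inherits(k_traj, "input_trajectory"))
  if (max(k_traj$times) < T - 1e-9) stop("k trajectory must cover [0, T]")
  for (v in c(ks, kdm, kdp)) if (!is.finite(v) || v <= 0) stop("rates must be positive")
  if (any(times < 0 | times > T)) stop("output times must lie in [0, T]")
  if (abs(kdm - kdp) < 1e-8 * (kdm + kdp)) kdp <- kdp * (1 + 1e-6)  # avoid the
  # degenerate equal-rate eigenvalue (closed form has a t*exp(-kt) term there)

  grid <- sort(unique(c(k_traj$times[k_traj$times <= T], times, T)))
  ng <- length(grid)
  h <- diff(grid)
  kval <- if (k_traj$interpolation == "left-constant")
    value_at(k_traj, grid[-ng]) else value_at(k_traj, grid[-ng] + h / 2)

  cc <- ks / (kdm - kdp)
  em <- exp(-kdm * h)
  ew <- exp(-kdp * h)
  m <- numeric(ng); w <- numeric(ng)
  m[1] <- m0
  w[1] <- n0 + cc * m0
  for (i in seq_len(ng - 1)) {
    ms <- kval[i] / kdm                 # interval fixed point of <m>
    wsv <- cc * kval[i] / kdp           # interval fixed point of w
    m[i + 1] <- ms + (m[i] - ms) * em[i]
    w[i + 1] <- wsv + (w[i] - wsv) * ew[i]
  }
  n <- w - cc * m
  keep <- match(times, grid)
  out <- data.frame(time = times, m = m[keep], n = n[keep])
  attr(out, "provenance") <- "ode-exact"
  out
}

#' Finite-state integration of the master equation with time-varying rates
#'
#' Integrates the chemical master equation
#' \deqn{dP(n,t)/dt = \sum_j a_j[n - \nu_j, I(t)] P(n-\nu_j, t)
#'                    - a_j[n, I(t)] P(n, t)}
#' on a truncated rectangular state space. Because mass-action propensities
#' here are affine in the input, the generator decomposes as
#' \eqn{A(t) = A_0 + I(t) A_1} with two constant sparse matrices. Transitions
#' leaving the truncation are treated as absorbing (finite-state-projection
#' style), so `1 - sum(P)` is the reported truncation leakage.
#'
#' @param net mass-action [reaction_network()].
#' @param x0 initial state.
#' @param input [input_trajectory()].
#' @param T final time (hours).
#' @param truncation named integer vector of per-species upper copy-number
#'   bounds (state space is the product of `0..truncation[s]`).
#' @param leak_tol error if final leakage exceeds this (default `0.01`).
#' @return list of class `cme_distribution`: `prob` (array over the truncated
#'   states, species as dimensions), `states`, `marginals`, `leakage`, `t`.
#' @export
cme_integrate <- function(net, x0, input, T, truncation, leak_tol = 0.01) {
  stopifnot(inherits(net, "reaction_network"))
  if (!is.null(net$custom)) stop("CME oracle requires a mass-action network")
  trunc <- if (is.null(names(truncation))) {
    if (length(truncation) != length(net$species))
      stop("truncation must be named or have one bound per species")
    stats::setNames(as.integer(truncation), net$species)
  } else expand_counts(truncation, net$species)
  sizes <- trunc + 1L
  n_states <- prod(sizes)
  if (n_states > 1e5) stop("truncated state space too large (> 1e5 states)")
  # enumerate states; index = 1 + sum_s x_s * stride_s
  strides <- cumprod(c(1L, sizes[-length(sizes)]))
  grid <- as.matrix(expand.grid(lapply(sizes, function(k) 0:(k - 1L))))
  colnames(grid) <- net$species

  M <- length(net$reaction_names)
  tri <- list(i = integer(0), j = integer(0), x0v = numeric(0), x1v = numeric(0))
  add <- function(i, j, v0, v1) {
    tri$i <<- c(tri$i, i); tri$j <<- c(tri$j, j)
    tri$x0v <<- c(tri$x0v, v0); tri$x1v <<- c(tri$x1v, v1)
  }
  for (j in seq_len(M)) {
    o <- net$orders[, j]
    a <- rep(net$rates[j], n_states)
    for (s in which(o > 0L)) {
      xs <- grid[, s]
      for (k in seq_len(o[s])) a <- a * pmax(xs - k + 1, 0)
    }
    inp <- net$input_scaled[j]
    target <- grid + matrix(net$stoich[, j], n_states, length(sizes), byrow = TRUE)
    inside <- rowSums(target < 0 | target > matrix(trunc, n_states,
                                                   length(sizes), byrow = TRUE)) == 0
    idx_to <- 1L + as.integer(target %*% strides)
    from <- which(a > 0)
    # outflow (diagonal) for every state with a > 0, including leaks
    add(from, from, if (inp) rep(0, length(from)) else -a[from],
        if (inp) -a[from] else rep(0, length(from)))
    keep <- from[inside[from]]
    add(idx_to[keep], keep, if (inp) rep(0, length(keep)) else a[keep],
        if (inp) a[keep] else rep(0, length(keep)))
  }
  A0 <- Matrix::sparseMatrix(i = tri$i, j = tri$j, x = tri$x0v,
                             dims = c(n_states, n_states))
  A1 <- Matrix::sparseMatrix(i = tri$i, j = tri$j, x = tri$x1v,
                             dims = c(n_states, n_states))
  Ifun <- stats::approxfun(input$times, pmax(input$values, 0),
                           method = if (input$interpolation == "linear")
                             "linear" else "constant", rule = 2, f = 0)
  p <- numeric(n_states)
  x0 <- as_state(net, x0)
  p[1L + sum(x0 * strides)] <- 1
  # fixed-step RK4; the generator is A0 + I(t) A1, so the step is capped by
  # the largest total outflow rate (explicit-scheme stability) and by the
  # input grid resolution
  Imax <- max(Ifun(input$times), 0)
  a_max <- max(-Matrix::diag(A0) - Imax * Matrix::diag(A1), 1e-12)
  h <- min(0.5 / a_max, min(diff(input$times)), T / 50)
  n_steps <- ceiling(T / h)
  h <- T / n_steps
  Ap <- function(t, p) as.numeric(A0 %*% p) + Ifun(t) * as.numeric(A1 %*% p)
  t <- 0
  for (i in seq_len(n_steps)) {
    k1 <- Ap(t, p)
    k2 <- Ap(t + h / 2, p + h / 2 * k1)
    k3 <- Ap(t + h / 2, p + h / 2 * k2)
    k4 <- Ap(t + h, p + h * k3)
    p <- p + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + h
  }
  p <- pmax(p, 0)
  leakage <- 1 - sum(p)
  if (leakage > leak_tol)
    stop("truncation leakage ", signif(leakage, 3),
         " exceeds tolerance; enlarge the truncation")
  prob <- array(p, dim = sizes, dimnames = lapply(sizes, function(k) 0:(k - 1L)))
  marg <- lapply(seq_along(sizes), function(s) apply(prob, s, sum))
  names(marg) <- net$species
  structure(list(prob = prob, truncation = trunc, marginals = marg,
                 leakage = leakage, t = T), class = "cme_distribution")
}

#' @export
print.cme_distribution <- function(x, ...) {
  cat(sprintf("<cme_distribution> at t = %g h, %s states, leakage %.2e\n",
              x$t, paste(x$truncation + 1L, collapse = " x "), x$leakage))
  invisible(x)
}

#' Proportional root-mean-square error between mean trajectories
#'
#' \deqn{\left[\frac{1}{T\,\bar n_{ex}^2}\int_0^T
#'   (\langle n(t)\rangle - n_{ex}(t))^2\,dt\right]^{1/2}}
#' where \eqn{\bar n_{ex}} is the time average of the exact trajectory. Both
#' trajectories are linearly interpolated onto the union grid and integrated
#' by the trapezoidal rule. The metric is invariant under joint rescaling of
#' both trajectories.
#'
#' @param est,exact data.frames with columns `time` and the compared variable
#'   (default `n`).
#' @param T horizon; default the common largest time.
#' @param var column name to compare.
#' @export
proportional_rmse <- function(est, exact, T = NULL, var = "n") {
  tt <- sort(unique(c(est$time, exact$time)))
  if (is.null(T)) T <- min(max(est$time), max(exact$time))
  tt <- tt[tt <= T]
  e1 <- stats::approx(est$time, est[[var]], xout = tt, rule = 2)$y
  e2 <- stats::approx(exact$time, exact[[var]], xout = tt, rule = 2)$y
  nbar <- trapz(tt, e2) / T
  if (abs(nbar) < .Machine$double.eps)
    stop("time-averaged exact mean is zero: proportional error undefined")
  sqrt(trapz(tt, (e1 - e2)^2) / (T * nbar^2))
}

trapz <- function(x, y) {
  n <- length(x)
  sum(diff(x) * (y[-n] + y[-1]) / 2)
}

#' Proportional error of a stationary mean
#'
#' `|est - exact| / exact`; `exact` must be positive.
#'
#' @param est_mean estimated stationary mean.
#' @param exact_mean exact stationary mean.
#' @export
stationary_proportional_error <- function(est_mean, exact_mean) {
  if (!is.finite(exact_mean) || exact_mean <= 0)
    stop("exact mean must be positive")
  abs(est_mean - exact_mean) / exact_mean
}

#' Fraction of time a set of species is simultaneously zero
#'
#' Exact time-weighted fraction of `[0, T]` during which every listed species
#' of the piecewise-constant trajectory has copy number 0 (the diagnostic that
#' explains the SIA trapping error).
#'
#' @param traj an `ssa_trajectory` with recorded events.
#' @param species character vector of species names (default all).
#' @export
zero_occupancy_fraction <- function(traj, species = traj$species) {
  stopifnot(inherits(traj, "ssa_trajectory"))
  ev <- which(!is.na(traj$channel))
  ts <- c(0, traj$times[ev], traj$T)
  xs <- rbind(traj$x0[species], traj$states[ev, species, drop = FALSE])
  allzero <- rowSums(xs != 0) == 0
  sum(diff(ts)[allzero]) / traj$T
}
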