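# Pure-R mirrors of the compiled simulation loops. Used for networks with
# arbitrary R propensity functions, and as an independent implementation to
# cross-check the compiled path on small problems.

#' Look-ahead propensity bound
#'
#' Computes `(B, L_effective)` such that `a0(t + u) <= B` for `0 <= u <
#' L_effective` with the state held fixed. `"window-max"` maximizes
#' `a0(X, I(s))` over grid evaluation points in the window (including the
#' value carried in from the left); `"monotone-sup"` evaluates `a0(X, sup I)`
#' and requires the network to be declared input-monotone; `"global"` uses the
#' trajectory ceiling over all of `[0, T]`.
#'
#' @param net a [reaction_network()].
#' @param state current state.
#' @param traj the [input_trajectory()].
#' @param t current time.
#' @param L requested look-ahead (clipped to `T - t`).
#' @param strategy one of `"window-max"`, `"monotone-sup"`, `"global"`.
#' @param safety multiplier `>= 1`.
#' @return list with elements `B` and `L_effective`.
#' @export
compute_bound <- function(net, state, traj, t, L,
                          strategy = c("window-max", "monotone-sup", "global"),
                          safety = 1) {
  strategy <- match.arg(strategy)
  Tmax <- traj$times[length(traj$times)]
  if (t >= Tmax) stop("t must be below the trajectory horizon")
  Leff <- min(L, Tmax - t)
  x <- as_state(net, state)
  a0_at <- function(I, tt) sum(propensities(net, x, I, tt))
  B <- switch(strategy,
    "monotone-sup" = {
      if (!isTRUE(net$input_monotone))
        stop("monotone-sup bound requested for a network not declared input-monotone")
      a0_at(window_sup(traj, t, Leff), t)
    },
    "global" = a0_at(max(traj$values, value_at(traj, 0)), t),
    "window-max" = {
      t1 <- min(t + Leff, Tmax)
      pts <- traj$times[traj$times > t & traj$times < t1]
      Is <- c(value_at(traj, t), traj$values[match(pts, traj$times)],
              if (traj$interpolation == "linear" || t + Leff >= Tmax)
                value_at(traj, t1))
      max(vapply(Is, a0_at, numeric(1), tt = t))
    })
  list(B = safety * B, L_effective = Leff)
}

extrande_r <- function(net, x0, input, T, L, l_policy, bound, safety,
                       out_times, record_events, record_pseudo) {
  x <- x0
  t <- 0
  M <- length(net$reaction_names)
  stats <- c(n_accepted = 0, n_thinned = 0, n_rejected = 0,
             n_propensity_evaluations = 0, n_exponentials_drawn = 0)
  times <- numeric(0); labels <- integer(0); states <- NULL
  out_times <- as.numeric(out_times)
  out_states <- matrix(NA_real_, length(out_times), length(x))
  out_k <- 0L
  flush <- function(t_new) {
    while (out_k < length(out_times) && out_times[out_k + 1] < t_new) {
      out_k <<- out_k + 1L
      out_states[out_k, ] <<- x
    }
  }
  rec <- function(tt, lab) {
    if (!record_events || (lab <= 0 && !record_pseudo)) return()
    times <<- c(times, tt); labels <<- c(labels, lab)
    states <<- rbind(states, x)
  }
  while (t < T) {
    Leff <- if (l_policy == 1L) T - t else min(L, T - t)
    bd <- compute_bound(net, x, input, t, Leff, strategy = bound, safety = safety)
    stats["n_propensity_evaluations"] <- stats["n_propensity_evaluations"] + M
    B <- bd$B
    tau <- if (B > 0) stats::rexp(1, rate = B) else Inf
    stats["n_exponentials_drawn"] <- stats["n_exponentials_drawn"] + 1
    if (tau > Leff) {
      stats["n_rejected"] <- stats["n_rejected"] + 1
      flush(t + Leff); t <- t + Leff; rec(t, -1L)
      next
    }
    flush(t + tau); t <- t + tau
    a <- propensities(net, x, value_at(input, t), t)
    stats["n_propensity_evaluations"] <- stats["n_propensity_evaluations"] + M
    a0 <- sum(a)
    if (a0 > B * (1 + 1e-12) + 1e-12)
      stop(sprintf("Extrande bound violated at t=%g: a0=%g > B=%g", t, a0, B))
    u <- stats::runif(1)
    if (a0 >= B * u) {
      j <- which(cumsum(a) >= B * u)[1]
      x <- x + net$stoich[, j]
      if (any(x < 0)) stop("negative copy number after channel ", j)
      stats["n_accepted"] <- stats["n_accepted"] + 1
      rec(t, j)
    } else {
      stats["n_thinned"] <- stats["n_thinned"] + 1
      rec(t, 0L)
    }
  }
  while (out_k < length(out_times)) {
    out_k <- out_k + 1L
    out_states[out_k, ] <- x
  }
  list(times = times, labels = labels,
       states = if (is.null(states)) matrix(0L, 0, length(x)) else unname(states),
       out_states = out_states, x_final = x, stats = as.list(stats))
}

sia_r <- function(net, x0, input, T, out_times, record_events) {
  x <- x0
  t <- 0
  M <- length(net$reaction_names)
  I_stale <- value_at(input, 0)
  stats <- c(n_accepted = 0, n_propensity_evaluations = 0)
  times <- numeric(0); labels <- integer(0); states <- NULL
  out_times <- as.numeric(out_times)
  out_states <- matrix(NA_real_, length(out_times), length(x))
  out_k <- 0L
  trapped <- FALSE
  flush <- function(t_new) {
    while (out_k < length(out_times) && out_times[out_k + 1] < t_new) {
      out_k <<- out_k + 1L
      out_states[out_k, ] <<- x
    }
  }
  while (t < T) {
    a <- propensities(net, x, I_stale, t)
    stats["n_propensity_evaluations"] <- stats["n_propensity_evaluations"] + M
    a0 <- sum(a)
    if (a0 <= 0) { trapped <- TRUE; break }
    tau <- stats::rexp(1, rate = a0)
    if (t + tau > T) break
    flush(t + tau); t <- t + tau
    j <- which(cumsum(a) >= stats::runif(1) * a0)[1]
    x <- x + net$stoich[, j]
    stats["n_accepted"] <- stats["n_accepted"] + 1
    if (record_events) {
      times <- c(times, t); labels <- c(labels, j); states <- rbind(states, x)
    }
    I_stale <- value_at(input, t)
  }
  while (out_k < length(out_times)) {
    out_k <- out_k + 1L
    out_states[out_k, ] <- x
  }
  list(times = times, labels = labels,
       states = if (is.null(states)) matrix(0L, 0, length(x)) else unname(states),
       out_states = out_states, x_final = x, stats = as.list(stats),
       trapped = trapped)
}

#' Extrande event statistics as a function of the look-ahead horizon
#'
#' Runs the simulator once per fixed `L` and tabulates accepted / thinned /
#' rejected percentages and the propensity-evaluation count.
#'
#' @inheritParams extrande
#' @param L_values numeric vector of fixed look-ahead horizons (hours).
#' @param ... further arguments passed to [extrande()] (e.g. `bound`).
#' @return data.frame with one row per `L`.
#' @export
event_stats_vs_L <- function(net, x0, input, T, L_values, seed = NULL, ...) {
  if (!length(L_values)) stop("L_values must be non-empty")
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(L_values, function(L) {
    r <- extrande(net, x0, input, T, L = L, record_events = FALSE, ...)
    s <- r$stats
    n <- s[["n_exponentials_drawn"]]
    data.frame(L = L,
               n_accepted = s[["n_accepted"]], n_thinned = s[["n_thinned"]],
               n_rejected = s[["n_rejected"]],
               pct_accepted = 100 * s[["n_accepted"]] / n,
               pct_thinned = 100 * s[["n_thinned"]] / n,
               pct_rejected = 100 * s[["n_rejected"]] / n,
               n_propensity_evaluations = s[["n_propensity_evaluations"]],
               n_exponentials_drawn = n)
  })
  do.call(rbind, rows)
}

#' Hardware-independent cost comparison: MN vs Extrande propensity evaluations
#'
#' Runs both methods on the same network and input and returns the ratio of
#' their propensity-evaluation counts (the dominant cost of the integral
#' method), a machine-independent surrogate for CPU-time comparisons.
#'
#' @inheritParams mn_integral
#' @param L Extrande look-ahead (hours or `"horizon"`).
#' @param ... further arguments for the Extrande leg (e.g. `bound`).
#' @return list with `ratio`, `mn_evals`, `extrande_evals`.
#' @export
propensity_eval_ratio <- function(net, x0, input, T, dt_int, L = "horizon",
                                  seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mn <- mn_integral(net, x0, input, T, dt_int = dt_int, record_events = FALSE)
  ex <- extrande(net, x0, input, T, L = L, record_events = FALSE, ...)
  m <- mn$stats[["n_propensity_evaluations"]]
  e <- ex$stats[["n_propensity_evaluations"]]
  list(ratio = m / e, mn_evals = m, extrande_evals = e)
}
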