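#' Extrande: exact simulation under a time-varying exogenous input
#'
#' Thinning-based exact stochastic simulation of a reaction network whose
#' propensities depend on a pre-simulated input trajectory. On each iteration
#' the algorithm chooses a look-ahead horizon `L <= T - t` and a bound `B` on
#' the total propensity over `[t, t + L)` (state held fixed), draws a putative
#' waiting time `tau ~ Exp(B)`, and then either *rejects* (`tau > L`: clock
#' advances by `L`), *accepts* (a uniform `u` with `a0(t) >= B u`: the same
#' `u` selects the firing channel), or *thins* (the virtual extra channel
#' fires; state unchanged). Conditional on the input trajectory the sampled
#' law is exact; the runtime asserts `a0(t) <= B` at every acceptance
#' evaluation and fails hard on violation.
#'
#' @param net a [reaction_network()].
#' @param x0 initial state (named or positional nonnegative integers).
#' @param input an [input_trajectory()] covering `[0, T]`.
#' @param T simulation horizon (hours).
#' @param L look-ahead horizon (hours); a fixed number, `"horizon"` for
#'   `L = T - t`, or `"auto"` to choose a fixed L by a short pilot scan that
#'   minimizes propensity evaluations + exponentials drawn.
#' @param bound bound strategy: `"window-max"` (supremum of `a0(X, I(s))` over
#'   the window; for single-input networks with propensities nondecreasing in
#'   the input this equals `a0(X, sup I)` and is computed from the input
#'   ceiling), `"monotone-sup"` (requires `net$input_monotone`), or
#'   `"global"` (one precomputed input ceiling for all of `[0, T]`).
#' @param adaptive_L experimental: double L after 10 consecutive non-rejected
#'   draws, halve it after a reject.
#' @param safety bound multiplier `>= 1`.
#' @param seed optional integer seed.
#' @param out_times optional grid at which to sample the (right-continuous)
#'   state path, returned as `$grid_states`.
#' @param record_events keep the full labelled event list (disable for large
#'   ensemble runs).
#' @param record_pseudo also record thin / reject-horizon events.
#' @return an object of class `ssa_trajectory`: event `times`, `labels`
#'   (channel name, `"thin"`, or `"reject-horizon"`), `states` (snapshot after
#'   each recorded event), `x0`, `x_final`, `stats` (accepted / thinned /
#'   rejected / propensity-evaluation / exponential counts), and optionally
#'   `grid_states`.
#' @references The bound-and-thin construction follows the standard
#'   augmented-system ("extra reaction") formulation for non-homogeneous
#'   point-process thinning.
#' @export
extrande <- function(net, x0, input, T, L = "horizon",
                     bound = c("window-max", "monotone-sup", "global"),
                     adaptive_L = FALSE, safety = 1, seed = NULL,
                     out_times = numeric(0), record_events = TRUE,
                     record_pseudo = TRUE) {
  bound <- match.arg(bound)
  check_sim_args(net, x0, input, T)
  if (bound == "monotone-sup" && !isTRUE(net$input_monotone))
    stop("monotone-sup bound requested for a network not declared input-monotone")
  if (safety < 1) stop("safety factor must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  if (identical(L, "auto")) L <- pilot_L(net, x0, input, T)
  l_policy <- if (adaptive_L) 2L else if (identical(L, "horizon")) 1L else 0L
  Lnum <- if (is.numeric(L)) as.numeric(L) else T
  if (l_policy != 1L && (Lnum <= 0)) stop("fixed look-ahead L must be positive")
  strategy <- if (bound == "global") 1L else 0L

  if (is.null(net$custom)) {
    res <- .extrande_cpp(net$stoich, net$orders, net$rates, net$input_scaled,
                         as_state(net, x0), input$times, input$values,
                         input$interpolation == "linear", T, Lnum, l_policy,
                         strategy, safety, as.numeric(out_times),
                         record_events, record_pseudo)
  } else {
    res <- extrande_r(net, as_state(net, x0), input, T, Lnum, l_policy,
                      bound, safety, out_times, record_events, record_pseudo)
  }
  make_trajectory(res, net, x0, T, "extrande", out_times,
                  extra = list(L = if (l_policy == 1L) "horizon" else Lnum,
                               bound = bound, adaptive_L = adaptive_L))
}

#' Slow input approximation (SIA) reference method
#'
#' Classic SSA in which the input is frozen at its value at the last reaction
#' firing: propensities (including channel selection) use the stale input
#' value, which only refreshes when some channel fires. When the total
#' propensity hits zero the simulation is trapped and emits no further events
#' up to `T` (the method's characteristic failure; a warning is logged).
#'
#' @inheritParams extrande
#' @return an `ssa_trajectory` (with logical element `trapped`).
#' @export
sia <- function(net, x0, input, T, seed = NULL, out_times = numeric(0),
                record_events = TRUE) {
  check_sim_args(net, x0, input, T)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(net$custom)) {
    res <- .sia_cpp(net$stoich, net$orders, net$rates, net$input_scaled,
                    as_state(net, x0), input$times, input$values,
                    input$interpolation == "linear", T,
                    as.numeric(out_times), record_events)
  } else {
    res <- sia_r(net, as_state(net, x0), input, T, out_times, record_events)
  }
  if (isTRUE(res$trapped))
    warning("SIA trapped: total propensity reached 0 with a stale input; ",
            "no further events simulated up to T", call. = FALSE)
  out <- make_trajectory(res, net, x0, T, "sia", out_times)
  out$trapped <- isTRUE(res$trapped)
  out
}

#' Modified-next integral reference method
#'
#' Next-reaction simulation for time-varying propensities: each channel keeps
#' a unit-exponential target and an internal time \eqn{T_j = \int a_j\,ds}
#' accumulated by trapezoidal integration with step `dt_int`; the next firing
#' is the channel whose target is crossed first, with the within-step firing
#' time solved on the trapezoid's linear interpolant. `variant = "direct"`
#' instead integrates the total propensity to a single target and picks the
#' channel proportionally to the propensities at the firing time.
#'
#' @inheritParams extrande
#' @param dt_int trapezoidal integration step (hours). Accuracy is governed by
#'   the coarser of `dt_int` and the input grid step (a warning is issued when
#'   `dt_int` is the coarser one).
#' @param variant `"modified-next"` (default) or `"direct"`.
#' @return an `ssa_trajectory` with propensity-evaluation counts in `$stats`.
#' @export
mn_integral <- function(net, x0, input, T, dt_int, variant = c("modified-next", "direct"),
                        seed = NULL, out_times = numeric(0), record_events = TRUE) {
  variant <- match.arg(variant)
  check_sim_args(net, x0, input, T)
  if (dt_int <= 0) stop("integration step must be positive")
  grid_dt <- min(diff(input$times))
  if (dt_int > grid_dt * (1 + 1e-9))
    warning("integration step (", dt_int, " h) is coarser than the input grid (",
            signif(grid_dt, 3), " h): accuracy is governed by the coarser step")
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(net$custom)) stop("integral method requires a mass-action network")
  res <- .mn_integral_cpp(net$stoich, net$orders, net$rates, net$input_scaled,
                          as_state(net, x0), input$times, input$values,
                          input$interpolation == "linear", T, dt_int,
                          variant == "direct", as.numeric(out_times), record_events)
  make_trajectory(res, net, x0, T, paste0(variant, "-integral"), out_times,
                  extra = list(dt_int = dt_int))
}

check_sim_args <- function(net, x0, input, T) {
  stopifnot(inherits(net, "reaction_network"), inherits(input, "input_trajectory"))
  if (!is.finite(T) || T <= 0) stop("horizon T must be positive")
  if (max(input$times) < T - 1e-9)
    stop("input trajectory must cover [0, T]")
  invisible(TRUE)
}

# short pilot scan over a log-spaced L grid; picks the L minimizing
# (propensity evaluations + exponentials drawn) on a short run
pilot_L <- function(net, x0, input, T, n_grid = 6, pilot_T = min(T, max(T / 20, 1))) {
  Ls <- exp(seq(log(max(pilot_T / 100, 1e-3)), log(pilot_T), length.out = n_grid))
  cost <- vapply(Ls, function(L) {
    r <- extrande(net, x0, input, pilot_T, L = L, record_events = FALSE,
                  record_pseudo = FALSE)
    unname(r$stats["n_propensity_evaluations"] + r$stats["n_exponentials_drawn"])
  }, numeric(1))
  Ls[which.min(cost)]
}

make_trajectory <- function(res, net, x0, T, method, out_times, extra = list()) {
  lbl <- res$labels
  labels <- character(length(lbl))
  if (length(lbl)) {
    labels[lbl >= 1] <- net$reaction_names[lbl[lbl >= 1]]
    labels[lbl == 0] <- "thin"
    labels[lbl == -1] <- "reject-horizon"
  }
  states <- res$states
  colnames(states) <- net$species
  gs <- NULL
  if (length(out_times)) {
    gs <- res$out_states
    colnames(gs) <- net$species
  }
  xf <- res$x_final
  names(xf) <- net$species
  structure(list(times = res$times, labels = labels, channel = ifelse(lbl >= 1, lbl, NA_integer_),
                 states = states, x0 = as_state(net, x0), x_final = xf, T = T,
                 species = net$species, method = method,
                 stats = unlist(res$stats),
                 grid_times = if (length(out_times)) as.numeric(out_times) else NULL,
                 grid_states = gs, settings = extra),
            class = "ssa_trajectory")
}

#' @export
print.ssa_trajectory <- function(x, ...) {
  cat(sprintf("<ssa_trajectory> method %s, T = %g h, %d recorded events\n",
              x$method, x$T, length(x$times)))
  cat("  final state:", paste(sprintf("%s=%d", x$species, x$x_final), collapse = ", "), "\n")
  if (length(x$stats)) {
    s <- x$stats
    cat("  stats:", paste(sprintf("%s=%g", names(s), s), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.ssa_trajectory <- function(object, ...) {
  n_ch <- sum(!is.na(object$channel))
  out <- list(method = object$method, T = object$T, n_reaction_events = n_ch,
              x_final = object$x_final, stats = object$stats,
              time_averages = path_time_average(object))
  class(out) <- "summary.ssa_trajectory"
  out
}

#' @export
print.summary.ssa_trajectory <- function(x, ...) {
  cat(sprintf("%s trajectory over [0, %g] h: %d reaction events\n",
              x$method, x$T, x$n_reaction_events))
  cat("  time-averaged copy numbers:",
      paste(sprintf("%s=%.3g", names(x$time_averages), x$time_averages),
            collapse = ", "), "\n")
  invisible(x)
}

#' Sample a trajectory's right-continuous state path on a grid
#'
#' @param traj an `ssa_trajectory` with recorded events.
#' @param times query times in `[0, T]`.
#' @return matrix `length(times) x n_species`.
#' @export
sample_path <- function(traj, times) {
  stopifnot(inherits(traj, "ssa_trajectory"))
  ev <- which(!is.na(traj$channel))
  et <- traj$times[ev]
  idx <- findInterval(times, et)
  out <- matrix(0L, length(times), length(traj$species),
                dimnames = list(NULL, traj$species))
  for (i in seq_along(times)) {
    out[i, ] <- if (idx[i] == 0L) traj$x0 else traj$states[ev[idx[i]], ]
  }
  out
}

path_time_average <- function(traj) {
  ev <- which(!is.na(traj$channel))
  ts <- c(0, traj$times[ev], traj$T)
  xs <- rbind(traj$x0, traj$states[ev, , drop = FALSE])
  w <- diff(ts)
  colSums(xs * w) / traj$T
}

#' @export
plot.ssa_trajectory <- function(x, species = x$species, ...) {
  ev <- which(!is.na(x$channel))
  ts <- c(0, x$times[ev], x$T)
  xs <- rbind(x$x0, x$states[ev, , drop = FALSE])
  xs <- rbind(xs, xs[nrow(xs), ])
  cols <- seq_along(species)
  graphics::matplot(ts, xs[, species, drop = FALSE], type = "s", lty = 1,
                    col = cols, xlab = "time (h)", ylab = "copy number", ...)
  graphics::legend("topright", legend = species, col = cols, lty = 1, bty = "n")
  invisible(x)
}
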