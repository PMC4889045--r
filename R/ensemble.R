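#' Simulate an ensemble of cells
#'
#' Runs `n_cells` independent simulations with per-cell RNG streams derived
#' from a master seed, either re-using one pre-generated input realization
#' across all cells (`input` given as a trajectory: conditional-mean designs)
#' or drawing an independent input per cell (`input` given as a factory
#' `function(seed)` returning an [input_trajectory()]: population designs).
#' The population mean is accumulated by sampling each right-continuous path
#' on a fixed output grid.
#'
#' @param n_cells number of cells (`>= 1`).
#' @param net a [reaction_network()].
#' @param input an [input_trajectory()] (shared input) or a
#'   `function(seed)` returning one (independent input per cell).
#' @param method `"extrande"`, `"sia"`, `"mn-integral"` or `"direct-integral"`.
#' @param T horizon (hours).
#' @param x0 initial state; default all species at 0.
#' @param master_seed integer master seed; per-cell sub-seeds are drawn from
#'   it and recorded, making every cell individually reproducible.
#' @param out_times output grid for the population mean (default 400 points).
#' @param fate optional list `list(species =, k_diff =, T_exp =)`: compute a
#'   [progress_to_competence()] outcome per cell (requires event recording).
#' @param ... further arguments passed to the simulator (e.g. `L`, `dt_int`).
#' @return object of class `ensemble_result`: `mean` (data.frame: `time` and
#'   one column per species), `outcomes` (per-cell data.frame when `fate` is
#'   given), `final_states`, `seeds`, `n_trapped` (SIA), `method`, `stats`
#'   (summed event statistics).
#' @export
run_ensemble <- function(n_cells, net, input, method = c("extrande", "sia",
                                                         "mn-integral", "direct-integral"),
                         T, x0 = NULL, master_seed = 1L,
                         out_times = seq(0, T, length.out = 401),
                         fate = NULL, ...) {
  method <- match.arg(method)
  stopifnot(n_cells >= 1)
  if (is.null(x0)) x0 <- stats::setNames(rep(0L, length(net$species)), net$species)
  set.seed(master_seed)
  seeds <- sample.int(.Machine$integer.max, n_cells)
  shared <- inherits(input, "input_trajectory")
  if (!shared && !is.function(input))
    stop("input must be an input_trajectory or a function(seed) returning one")
  input_seeds <- if (shared) rep(NA_integer_, n_cells)
                 else sample.int(.Machine$integer.max, n_cells)

  mean_acc <- matrix(0, length(out_times), length(net$species))
  finals <- matrix(0L, n_cells, length(net$species),
                   dimnames = list(NULL, net$species))
  stats_acc <- NULL
  n_trapped <- 0L
  outcomes <- if (!is.null(fate)) vector("list", n_cells)
  record <- !is.null(fate)

  for (i in seq_len(n_cells)) {
    traj_in <- if (shared) input else input(input_seeds[i])
    r <- tryCatch(
      simulate_one(net, x0, traj_in, T, method, seed = seeds[i],
                   out_times = out_times, record_events = record, ...),
      error = function(e) stop("cell ", i, " (seed ", seeds[i], ") failed: ",
                               conditionMessage(e), call. = FALSE))
    mean_acc <- mean_acc + r$grid_states
    finals[i, ] <- r$x_final
    if (isTRUE(r$trapped)) n_trapped <- n_trapped + 1L
    if (!is.null(r$stats))
      stats_acc <- if (is.null(stats_acc)) r$stats else stats_acc + r$stats
    if (!is.null(fate)) {
      pr <- progress_to_competence(r, fate$species, fate$k_diff)
      T_exp <- fate$T_exp %||% T
      mi <- mean_input_over(traj_in, T_exp)
      outcomes[[i]] <- data.frame(
        cell = i, seed = seeds[i], input_seed = input_seeds[i],
        entry_time = pr$entry_time %||% NA_real_,
        entered = !is.null(pr$entry_time) && pr$entry_time <= T_exp,
        mean_input = mi, final_progress = pr$final_progress)
    }
  }
  structure(list(
    mean = data.frame(time = out_times, mean_acc / n_cells) |>
      stats::setNames(c("time", net$species)),
    outcomes = if (!is.null(fate)) do.call(rbind, outcomes),
    final_states = finals, seeds = seeds, input_seeds = input_seeds,
    n_cells = n_cells, n_trapped = n_trapped, method = method,
    shared_input = shared, stats = stats_acc, T = T,
    master_seed = master_seed
  ), class = "ensemble_result")
}

simulate_one <- function(net, x0, input, T, method, seed, out_times,
                         record_events, ...) {
  switch(method,
    "extrande" = extrande(net, x0, input, T, seed = seed, out_times = out_times,
                          record_events = record_events, record_pseudo = FALSE, ...),
    "sia" = suppressWarnings(
      sia(net, x0, input, T, seed = seed, out_times = out_times,
          record_events = record_events, ...)),
    "mn-integral" = mn_integral(net, x0, input, T, seed = seed,
                                out_times = out_times,
                                record_events = record_events, ...),
    "direct-integral" = mn_integral(net, x0, input, T, variant = "direct",
                                    seed = seed, out_times = out_times,
                                    record_events = record_events, ...))
}

mean_input_over <- function(traj, T_exp) {
  keep <- traj$times <= T_exp
  mean(pmax(traj$values[keep], 0))
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf("<ensemble_result> %d cells, method %s, T = %g h (%s input)\n",
              x$n_cells, x$method, x$T,
              if (x$shared_input) "shared" else "independent"))
  if (x$n_trapped > 0)
    cat("  trapped cells:", x$n_trapped, "\n")
  if (!is.null(x$outcomes))
    cat(sprintf("  competent fraction: %.3f\n", mean(x$outcomes$entered)))
  invisible(x)
}

#' Progress to competence along a trajectory
#'
#' Differentiation progress is the running integral
#' \eqn{\mathrm{Progress}(t) = k \int_0^t \mathrm{ComK}(s)\,ds} of a
#' regulator's copy number; the cell enters competence when progress reaches
#' 1. The copy-number path is piecewise constant, so progress is piecewise
#' linear and the crossing is solved exactly within its segment.
#'
#' @param traj an `ssa_trajectory` with recorded events.
#' @param species name of the regulator species (ComK-like).
#' @param k_diff effective differentiation rate `k` (per molecule per hour).
#' @return list: `progress` (data.frame `time`, `progress`), `entry_time`
#'   (or `NULL` if progress never reaches 1), `final_progress`.
#' @export
progress_to_competence <- function(traj, species, k_diff) {
  stopifnot(inherits(traj, "ssa_trajectory"))
  if (!species %in% traj$species) stop("species not in network: ", species)
  if (!is.finite(k_diff) || k_diff <= 0) stop("k_diff must be positive")
  ev <- which(!is.na(traj$channel))
  ts <- c(0, traj$times[ev], traj$T)
  xs <- c(traj$x0[[species]], traj$states[ev, species])
  seg <- k_diff * xs * diff(ts)
  prog <- c(0, cumsum(seg))
  entry <- NULL
  cross <- which(prog >= 1)[1]
  if (!is.na(cross)) {
    # crossing inside segment cross-1: linear in time there
    i <- cross - 1L
    entry <- ts[i] + (1 - prog[i]) / (k_diff * xs[i])
  }
  list(progress = data.frame(time = ts, progress = prog),
       entry_time = entry,
       final_progress = prog[length(prog)])
}

#' Fraction of cells entering competence
#'
#' @param outcomes per-cell outcome data.frame from [run_ensemble()] (needs
#'   columns `entry_time`).
#' @param T_exp experiment duration (hours).
#' @return list: `fraction`, binomial `se`, `n`.
#' @export
competent_fraction <- function(outcomes, T_exp) {
  entered <- !is.na(outcomes$entry_time) & outcomes$entry_time <= T_exp
  p <- mean(entered)
  list(fraction = p, se = sqrt(p * (1 - p) / nrow(outcomes)), n = nrow(outcomes))
}

#' Logistic model of competence probability vs time-averaged input
#'
#' Fits `entered ~ mean_input` by binomial-family maximum likelihood
#' (two-parameter logistic). Complete separation is detected and reported; in
#' that case a weakly ridge-penalized fit is returned instead, flagged via
#' `separated = TRUE`.
#'
#' @param outcomes per-cell outcomes with columns `entered` and `mean_input`.
#' @return list of class `competence_logistic`: `intercept`, `slope`,
#'   `se` (coefficient standard errors), `fitted` (per-cell probabilities),
#'   `separated`, `converged`, and `curve` (`function(mean_input)`).
#' @export
prob_competence_vs_mean_input <- function(outcomes) {
  stopifnot(all(c("entered", "mean_input") %in% names(outcomes)))
  y <- as.numeric(outcomes$entered)
  if (length(unique(y)) < 2)
    stop("need at least 2 outcomes of each class for a stable fit")
  x <- outcomes$mean_input
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ x, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (sep || !fit$converged) {
    # ridge-penalized logistic log-likelihood, penalty on the slope only
    xs <- scale(x)
    nll <- function(b) {
      eta <- b[1] + b[2] * xs
      sum(log1p(exp(-(2 * y - 1) * eta))) + 1e-2 * b[2]^2
    }
    op <- stats::optim(c(0, 0), nll, method = "BFGS")
    slope <- op$par[2] / attr(xs, "scaled:scale")
    intercept <- op$par[1] - slope * attr(xs, "scaled:center")
    co <- c(intercept, slope)
    se <- c(NA_real_, NA_real_)
    conv <- op$convergence == 0
  } else {
    co <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
    conv <- fit$converged
  }
  co <- unname(co)
  curve <- function(mean_input) stats::plogis(co[1] + co[2] * mean_input)
  structure(list(intercept = unname(co[1]), slope = unname(co[2]),
                 se = unname(se), fitted = curve(x), separated = sep,
                 converged = conv, curve = curve),
            class = "competence_logistic")
}

#' @export
print.competence_logistic <- function(x, ...) {
  cat(sprintf("<competence_logistic> P(competence) = plogis(%.4g + %.4g * <input>)%s\n",
              x$intercept, x$slope,
              if (x$separated) "  [complete separation: ridge fit]" else ""))
  invisible(x)
}

#' Minimal bistable expression toy for exercising the fate pipeline
#'
#' A synthetic stand-in for the (supplement-only) competence networks: a
#' single regulator `K` expressed in input-activated bursts, so that cells
#' under a fluctuating input show heterogeneous windows of `K` expression and
#' heterogeneous progress to "competence". Channels: input-modulated gene
#' activation `G -> G*`, deactivation, transcription-translation lumped
#' production of `K` from the active gene, and first-order decay of `K`.
#'
#' @param k_on gene activation rate constant (per input molecule per hour).
#' @param k_off deactivation rate (per hour).
#' @param k_prod K production rate from the active gene (per hour).
#' @param k_dec K decay rate (per hour).
#' @export
toy_fate_network <- function(k_on = 2e-4, k_off = 2, k_prod = 50, k_dec = 1) {
  reaction_network(
    species = c("G", "Ga", "K"),
    reactions = list(
      mass_action_reaction(c(G = 1), c(Ga = 1), rate = k_on,
                           input_modulated = TRUE, name = "activation"),
      mass_action_reaction(c(Ga = 1), c(G = 1), rate = k_off, name = "deactivation"),
      mass_action_reaction(c(Ga = 1), c(Ga = 1, K = 1), rate = k_prod,
                           name = "K production"),
      mass_action_reaction(c(K = 1), NULL, rate = k_dec, name = "K decay")
    ),
    name = "synthetic fate toy"
  )
}
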