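#' Gridded exogenous input trajectory
#'
#' Container for a pre-simulated input \eqn{I(t)} on a grid covering
#' \eqn{[0, T]}, with a declared deterministic interpolation rule for
#' intermediate times. The default rule is left-constant (a right-continuous
#' step function), which makes [window_sup()] an exact supremum and hence the
#' Extrande look-ahead bound rigorously valid; linear interpolation is also
#' supported (its supremum is attained at grid points or window endpoints).
#'
#' @param times strictly increasing grid, starting at 0, in hours.
#' @param values finite numeric values, one per grid point.
#' @param interpolation `"left-constant"` or `"linear"`.
#' @param meta named list of provenance (generator, parameters, seed, scheme).
#' @return object of class `input_trajectory`.
#' @export
input_trajectory <- function(times, values,
                             interpolation = c("left-constant", "linear"),
                             meta = list()) {
  interpolation <- match.arg(interpolation)
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values)) stop("times and values must have equal length")
  if (length(times) < 1L) stop("empty grid")
  if (times[1] != 0) stop("grid must start at time 0")
  if (is.unsorted(times, strictly = TRUE)) stop("grid times must be strictly increasing")
  if (!all(is.finite(values))) stop("trajectory values must be finite")
  structure(list(times = times, values = values,
                 interpolation = interpolation, meta = meta),
            class = "input_trajectory")
}

#' @export
print.input_trajectory <- function(x, ...) {
  cat(sprintf("<input_trajectory> %s, %d points on [0, %g] h, %s interpolation\n",
              x$meta$generator %||% "user-supplied", length(x$times),
              max(x$times), x$interpolation))
  invisible(x)
}

#' Ornstein-Uhlenbeck input generator
#'
#' Simulates \eqn{dI = -\gamma (I - \mu) dt + \sqrt{2\gamma\sigma^2} dW} on a
#' uniform grid. The stationary law is Gaussian with mean `mu`, variance
#' `sigma2` and autocovariance \eqn{\sigma^2 e^{-\gamma|t-t'|}}; `1/gamma` is
#' the correlation time (input "lifetime"). The default scheme is
#' Euler-Maruyama; `scheme = "exact"` uses the exact AR(1) discretization
#' (useful for validating the default at coarse steps).
#'
#' @param mu stationary mean.
#' @param gamma relaxation rate (per hour); lifetime is `1/gamma`.
#' @param sigma2 stationary variance. Alternatively give `cv` (for `mu > 0`).
#' @param cv coefficient of variation; `sigma2 = (cv * mu)^2`.
#' @param dt grid step (hours); a warning is issued if `dt * gamma > 0.1`.
#' @param T horizon (hours).
#' @param x0 initial value; default drawn from the stationary law.
#' @param seed optional integer seed (sets the RNG locally for this draw).
#' @param scheme `"euler-maruyama"` (default) or `"exact"`.
#' @return an [input_trajectory()] with generator metadata (including
#'   `sigma2`, consumed by [lognormal_normalized_rate()]).
#' @export
ou_process <- function(mu, gamma, sigma2 = NULL, cv = NULL, dt, T,
                       x0 = NULL, seed = NULL,
                       scheme = c("euler-maruyama", "exact")) {
  scheme <- match.arg(scheme)
  if (is.null(sigma2)) {
    if (is.null(cv)) stop("supply sigma2 or cv")
    if (mu <= 0) stop("cv parameterization requires mu > 0")
    sigma2 <- (cv * mu)^2
  }
  if (gamma <= 0) stop("gamma must be positive")
  if (sigma2 < 0) stop("sigma2 must be nonnegative")
  if (dt <= 0 || dt > T) stop("invalid step: need 0 < dt <= T")
  if (dt * gamma > 0.1)
    warning("dt * gamma = ", signif(dt * gamma, 3),
            " > 0.1: Euler-Maruyama discretization error may be noticeable")
  if (!is.null(seed)) set.seed(seed)
  n <- floor(T / dt + 1e-9)
  times <- seq(0, by = dt, length.out = n + 1)
  if (is.null(x0)) x0 <- mu + sqrt(sigma2) * rnorm(1)
  if (sigma2 == 0) {
    vals <- rep(if (is.null(x0)) mu else x0, n + 1)
  } else if (scheme == "euler-maruyama") {
    # x_{i+1} = (1 - gamma dt) x_i + gamma mu dt + sqrt(2 gamma sigma2 dt) Z_i:
    # a linear recursion, evaluated in C via stats::filter
    innov <- gamma * mu * dt + sqrt(2 * gamma * sigma2 * dt) * rnorm(n)
    vals <- c(x0, stats::filter(innov, 1 - gamma * dt,
                                method = "recursive", init = x0))
  } else {
    rho <- exp(-gamma * dt)
    innov <- mu * (1 - rho) + sqrt(sigma2 * (1 - rho^2)) * rnorm(n)
    vals <- c(x0, stats::filter(innov, rho, method = "recursive", init = x0))
  }
  input_trajectory(times, as.numeric(vals), "left-constant",
                   meta = list(generator = "ou", mu = mu, gamma = gamma,
                               sigma2 = sigma2, dt = dt, T = T, seed = seed,
                               scheme = scheme))
}

#' Circadian transcription rate
#'
#' Deterministic rate \eqn{k(t) = 4 k_{dp} (1 + \sin(2\pi f t))} sampled on a
#' uniform grid; the period is `1/f` (24 h by default).
#'
#' @param kdp protein degradation rate (per hour), setting the overall scale.
#' @param f oscillation frequency (per hour).
#' @param dt grid step (hours).
#' @param T horizon (hours).
#' @param interpolation interpolation rule for the trajectory.
#' @export
circadian_rate <- function(kdp, f = 1 / 24, dt, T,
                           interpolation = "left-constant") {
  if (f <= 0) stop("frequency must be positive")
  if (dt <= 0 || dt > T) stop("invalid step: need 0 < dt <= T")
  times <- seq(0, T, by = dt)
  if (times[length(times)] < T) times <- c(times, T)
  vals <- 4 * kdp * (1 + sin(2 * pi * f * times))
  input_trajectory(times, vals, interpolation,
                   meta = list(generator = "circadian", kdp = kdp, f = f, dt = dt, T = T))
}

#' Normalized lognormal transcription rate
#'
#' Exponentiates a zero-mean Gaussian (OU) log-noise \eqn{\xi(t)} and
#' normalizes by the stationary lognormal mean so the rate has stationary mean
#' `k_bar`: \eqn{k(t) = k\_bar\, e^{-\sigma^2/2} e^{\xi(t)}}.
#'
#' @param ou an [ou_process()] trajectory of the log-noise (mean 0).
#' @param k_bar baseline (stationary mean) rate, per hour.
#' @param sigma2 stationary variance of the log-noise; taken from the OU
#'   metadata when available, otherwise required.
#' @export
lognormal_normalized_rate <- function(ou, k_bar, sigma2 = NULL) {
  stopifnot(inherits(ou, "input_trajectory"))
  if (is.null(sigma2)) sigma2 <- ou$meta$sigma2
  if (is.null(sigma2))
    stop("stationary log-variance unknown: supply sigma2 explicitly")
  vals <- k_bar * exp(-sigma2 / 2) * exp(ou$values)
  input_trajectory(ou$times, vals, ou$interpolation,
                   meta = c(list(generator = "lognormal-normalized", k_bar = k_bar,
                                 sigma2 = sigma2), ou$meta["seed"]))
}

#' Circadian rate with lognormal amplitude modulation
#'
#' \eqn{k(t) = A\, e^{\xi(t)} (1 + \sin(2\pi f t))} evaluated pointwise on the
#' OU grid (the amplitude-fluctuation model of noisy circadian expression).
#' Note the amplitude noise is *not* mean-normalized here.
#'
#' @param ou zero-mean OU log-noise trajectory.
#' @param amplitude baseline amplitude `A` (per hour), default 20.
#' @param f oscillation frequency (per hour).
#' @export
modulated_circadian_rate <- function(ou, amplitude = 20, f = 1 / 24) {
  stopifnot(inherits(ou, "input_trajectory"))
  if (f <= 0) stop("frequency must be positive")
  vals <- amplitude * exp(ou$values) * (1 + sin(2 * pi * f * ou$times))
  input_trajectory(ou$times, vals, ou$interpolation,
                   meta = c(list(generator = "modulated-circadian",
                                 amplitude = amplitude, f = f), ou$meta["seed"]))
}

#' Sum of independent OU processes
#'
#' Pointwise sum of independent OU paths on a common grid; used to match
#' multi-exponential autocorrelation functions (two summed OU processes give a
#' weighted two-exponential decay).
#'
#' @param specs list of parameter lists, each with `mu`, `gamma` and `sigma2`
#'   (or `cv`).
#' @param dt,T grid step and horizon (hours).
#' @param seed optional integer seed.
#' @export
sum_of_ou <- function(specs, dt, T, seed = NULL) {
  if (!length(specs)) stop("at least one OU spec is required")
  if (!is.null(seed)) set.seed(seed)
  paths <- lapply(specs, function(s)
    ou_process(mu = s$mu, gamma = s$gamma, sigma2 = s$sigma2, cv = s$cv,
               dt = dt, T = T, scheme = s$scheme %||% "euler-maruyama"))
  vals <- Reduce(`+`, lapply(paths, `[[`, "values"))
  input_trajectory(paths[[1]]$times, vals, "left-constant",
                   meta = list(generator = "sum-of-ou", n_components = length(specs),
                               dt = dt, T = T, seed = seed))
}

#' Evaluate an input trajectory at a time point
#'
#' Left-constant trajectories return the value at the greatest grid point
#' `<= t`; linear trajectories interpolate.
#'
#' @param traj an [input_trajectory()].
#' @param t time(s) in `[0, T]` (vectorized).
#' @export
value_at <- function(traj, t) {
  stopifnot(inherits(traj, "input_trajectory"))
  Tmax <- traj$times[length(traj$times)]
  if (any(t < 0 | t > Tmax)) stop("t outside [0, T]")
  if (traj$interpolation == "left-constant") {
    idx <- findInterval(t, traj$times)
    traj$values[pmax(idx, 1L)]
  } else {
    stats::approx(traj$times, traj$values, xout = t, rule = 2)$y
  }
}

#' Supremum of an input trajectory over a look-ahead window
#'
#' Exact supremum of the interpolated trajectory on `[t, t + L)` under the
#' declared interpolation rule (the window is clipped at the grid horizon).
#' For left-constant trajectories this is the maximum over the value carried
#' into the window from the left and all grid values inside it; for linear
#' trajectories the supremum is attained at the window endpoints or interior
#' grid points.
#'
#' @param traj an [input_trajectory()].
#' @param t window start (hours).
#' @param L window length (hours), `> 0`.
#' @export
window_sup <- function(traj, t, L) {
  stopifnot(inherits(traj, "input_trajectory"))
  if (L <= 0) stop("invalid look-ahead horizon: L must be positive")
  Tmax <- traj$times[length(traj$times)]
  if (t < 0 || t > Tmax) stop("t outside [0, T]")
  t1 <- min(t + L, Tmax)
  m <- value_at(traj, t)
  inside <- traj$times > t & traj$times < t1
  if (any(inside)) m <- max(m, traj$values[inside])
  # the right endpoint belongs to the closure only when the window is clipped
  # at the grid horizon (left-constant windows are otherwise half-open)
  if (traj$interpolation == "linear" || t + L >= Tmax)
    m <- max(m, value_at(traj, t1))
  m
}

#' Sample autocovariance of a gridded trajectory
#'
#' Biased-normalization estimator
#' \eqn{\hat c(k) = n^{-1} \sum_{i} (x_i - \bar x)(x_{i+k} - \bar x)} at the
#' requested integer lags (in grid steps) or time lags.
#'
#' @param traj an [input_trajectory()] (uniform grid assumed).
#' @param lags numeric time lags in hours; rounded to grid steps.
#' @return data.frame with columns `lag` (hours) and `autocov`.
#' @export
sample_autocovariance <- function(traj, lags) {
  stopifnot(inherits(traj, "input_trajectory"))
  x <- traj$values
  n <- length(x)
  dt <- traj$times[2] - traj$times[1]
  ks <- pmin(pmax(round(lags / dt), 0L), n - 1L)
  xc <- x - mean(x)
  ac <- vapply(ks, function(k)
    sum(xc[seq_len(n - k)] * xc[seq_len(n - k) + k]) / n, numeric(1))
  data.frame(lag = ks * dt, autocov = ac)
}

#' Read / write input trajectories as CSV
#'
#' Two-column CSV with header `time_h,value`; generator metadata goes to a
#' JSON sidecar `<path>.meta.json`.
#'
#' @param traj an [input_trajectory()].
#' @param path CSV file path.
#' @param interpolation interpolation rule to declare when reading.
#' @export
write_input_csv <- function(traj, path) {
  stopifnot(inherits(traj, "input_trajectory"))
  utils::write.csv(data.frame(time_h = traj$times, value = traj$values),
                   path, row.names = FALSE)
  meta <- c(traj$meta, list(interpolation = traj$interpolation))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

#' @rdname write_input_csv
#' @export
read_input_csv <- function(path, interpolation = NULL) {
  d <- utils::read.csv(path)
  meta <- list(generator = "csv", source = path)
  side <- paste0(path, ".meta.json")
  if (file.exists(side)) meta <- c(jsonlite::read_json(side), meta["source"])
  if (is.null(interpolation))
    interpolation <- meta$interpolation %||% "left-constant"
  meta$interpolation <- NULL
  input_trajectory(d[[1]], d[[2]], interpolation, meta = meta)
}
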