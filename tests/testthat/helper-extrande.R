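# Shared fixtures for the test suite. All fixtures are generated in code.

# constant input I(t) = value on [0, T]
const_input <- function(value, T) {
  input_trajectory(c(0, T), c(value, value),
                   meta = list(generator = "constant", value = value))
}

# O. tauri-like two-stage rates: slow degradation relative to the 24 h cycle
# (0.008 protein / 0.002 mRNA cycles per lifetime), mean protein ~100
otauri <- function() {
  f <- 1 / 24
  kdp <- f / 0.008
  kdm <- f / 0.002
  list(f = f, kdp = kdp, kdm = kdm, ks = 100 * kdp)
}

# hand-built piecewise-constant trajectory object for exact path-functional
# tests: X jumps 0 -> 1 at t = 1 and 1 -> 0 at t = 3, horizon 4
manual_onoff_traj <- function() {
  structure(list(
    times = c(1, 3), labels = c("birth", "death"), channel = c(1L, 2L),
    states = matrix(c(1L, 0L), 2, 1, dimnames = list(NULL, "X")),
    x0 = c(X = 0L), x_final = c(X = 0L), T = 4, species = "X",
    method = "manual", stats = numeric(0)
  ), class = "ssa_trajectory")
}

# empirical total variation distance between integer samples and a pmf vector
# indexed by 0:(length(pmf) - 1)
tv_against_pmf <- function(samples, pmf) {
  emp <- tabulate(samples + 1L, nbins = length(pmf)) / length(samples)
  0.5 * sum(abs(emp - pmf)) + 0.5 * mean(samples >= length(pmf))
}

# batch-means standard error of a long-trajectory statistic
batch_se <- function(x, n_batches, stat) {
  idx <- cut(seq_along(x), n_batches, labels = FALSE)
  vals <- vapply(split(x, idx), stat, numeric(1))
  stats::sd(vals) / sqrt(n_batches)
}
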