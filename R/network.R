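#' Define a reaction network with input-dependent propensities
#'
#' A network is a set of species and reaction channels. Each channel carries a
#' stoichiometry vector (net change per firing) and a propensity. Two kinds of
#' channel are supported: mass-action channels built with
#' [mass_action_reaction()], whose rate constant may optionally be multiplied
#' by the instantaneous value of an exogenous input \eqn{I(t)} (the fast,
#' compiled simulation path), and fully general channels carrying an arbitrary
#' R propensity `function(x, input, t)` (simulated by the pure-R path).
#'
#' Propensity contract: every propensity must be finite and nonnegative on
#' nonnegative integer states, and must vanish whenever a consumed species has
#' copy number zero, so that populations can never go negative. Mass-action
#' channels satisfy this by construction; custom channels are checked at run
#' time.
#'
#' @param species character vector of species names.
#' @param reactions list of reactions from [mass_action_reaction()] and/or
#'   [custom_reaction()].
#' @param input_monotone logical; declare that every propensity is
#'   nondecreasing in the input value. Mass-action networks are detected
#'   automatically; only needed for custom channels that want the
#'   `"monotone-sup"` bound strategy.
#' @param name optional model name.
#' @return an object of class `reaction_network`.
#' @examples
#' net <- two_stage_network(ks = 2, kdm = 3, kdp = 0.5)
#' propensities(net, state = c(M = 2, P = 5), input = 1)
#' @export
reaction_network <- function(species, reactions, input_monotone = NA, name = NULL) {
  stopifnot(is.character(species), length(species) >= 1L, !anyDuplicated(species))
  if (!length(reactions)) stop("at least one reaction is required")
  n_sp <- length(species)
  M <- length(reactions)
  stoich <- matrix(0L, n_sp, M, dimnames = list(species, NULL))
  orders <- matrix(0L, n_sp, M)
  rates <- numeric(M)
  input_scaled <- logical(M)
  custom <- vector("list", M)
  rnames <- character(M)
  for (j in seq_len(M)) {
    r <- reactions[[j]]
    if (!inherits(r, "extrande_reaction")) stop("reaction ", j, " is not a reaction object")
    if (!is.null(r$propensity)) custom[[j]] <- r$propensity
    sj <- expand_counts(r$reactants, species)
    pj <- expand_counts(r$products, species)
    if (is.null(r$propensity)) {
      if (!is.finite(r$rate) || r$rate <= 0)
        stop("rate constant of reaction ", j, " must be a positive finite number")
      orders[, j] <- sj
      rates[j] <- r$rate
      input_scaled[j] <- isTRUE(r$input_modulated)
    }
    stoich[, j] <- pj - sj
    rnames[j] <- if (!is.null(r$name)) r$name else
      paste0(fmt_side(r$reactants), " -> ", fmt_side(r$products))
  }
  has_custom <- any(!vapply(custom, is.null, logical(1)))
  if (is.na(input_monotone)) input_monotone <- !has_custom
  structure(list(
    species = species, stoich = stoich, orders = orders, rates = rates,
    input_scaled = input_scaled,
    custom = if (has_custom) custom else NULL,
    input_monotone = isTRUE(input_monotone),
    reaction_names = rnames,
    name = name %||% "reaction network"
  ), class = "reaction_network")
}

expand_counts <- function(x, species) {
  out <- integer(length(species))
  names(out) <- species
  if (is.null(x) || !length(x)) return(out)
  if (is.null(names(x))) stop("reactant/product multisets must be named counts")
  unknown <- setdiff(names(x), species)
  if (length(unknown)) stop("unknown species: ", paste(unknown, collapse = ", "))
  out[names(x)] <- as.integer(x)
  if (any(out < 0)) stop("negative multiplicities are not allowed")
  out
}

fmt_side <- function(x) {
  if (is.null(x) || !length(x)) return("0")
  paste(ifelse(x > 1, paste0(x, " "), ""), names(x), sep = "", collapse = " + ")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mass-action reaction channel
#'
#' Propensity is `rate * prod_s X_s (X_s - 1) ... (X_s - r_s + 1)` (falling
#' factorial in the reactant multiplicities `r_s`), optionally multiplied by
#' the exogenous input value at the current time when `input_modulated = TRUE`.
#' Negative input values are clipped to zero at evaluation so the propensity
#' contract holds for Gaussian inputs used as molecular signals.
#'
#' @param reactants,products named integer vectors of species multiplicities
#'   (`NULL` or empty for the empty set).
#' @param rate positive rate constant, per hour.
#' @param input_modulated if `TRUE`, the propensity is additionally
#'   proportional to the input value \eqn{I(t)}.
#' @param name optional label.
#' @export
mass_action_reaction <- function(reactants = NULL, products = NULL, rate,
                                 input_modulated = FALSE, name = NULL) {
  structure(list(reactants = reactants, products = products, rate = rate,
                 input_modulated = input_modulated, propensity = NULL, name = name),
            class = "extrande_reaction")
}

#' General reaction channel with an arbitrary propensity function
#'
#' @param reactants,products named multiplicity vectors (used only for the
#'   stoichiometry; the propensity is whatever `propensity` returns).
#' @param propensity `function(x, input, t)` returning a finite nonnegative
#'   scalar; `x` is the named state vector.
#' @param name optional label.
#' @export
custom_reaction <- function(reactants = NULL, products = NULL, propensity, name = NULL) {
  stopifnot(is.function(propensity))
  structure(list(reactants = reactants, products = products, rate = NA_real_,
                 input_modulated = FALSE, propensity = propensity, name = name),
            class = "extrande_reaction")
}

#' Two-stage gene expression model with time-varying transcription
#'
#' Transcription `0 -> M` fires at the instantaneous input rate \eqn{k(t)}
#' (the input trajectory *is* the transcription propensity), translation
#' `M -> M + P` at `ks * M`, and first-order degradation of mRNA and protein
#' at `kdm * M` and `kdp * P`.
#'
#' @param ks translation rate (per mRNA per hour).
#' @param kdm mRNA degradation rate (per hour).
#' @param kdp protein degradation rate (per hour).
#' @return a `reaction_network` with species `M` (mRNA) and `P` (protein).
#' @export
two_stage_network <- function(ks, kdm, kdp) {
  for (v in c(ks = ks, kdm = kdm, kdp = kdp))
    if (!is.finite(v) || v <= 0) stop("all rates must be positive and finite")
  reaction_network(
    species = c("M", "P"),
    reactions = list(
      mass_action_reaction(NULL, c(M = 1), rate = 1, input_modulated = TRUE,
                           name = "transcription"),
      mass_action_reaction(c(M = 1), c(M = 1, P = 1), rate = ks, name = "translation"),
      mass_action_reaction(c(M = 1), NULL, rate = kdm, name = "mRNA decay"),
      mass_action_reaction(c(P = 1), NULL, rate = kdp, name = "protein decay")
    ),
    name = "two-stage gene expression"
  )
}

#' Birth-death network
#'
#' Birth `0 -> X` at rate `k` (times the input if `input_modulated`), death
#' `X -> 0` at `kd * X`. With `kd = 0` the death channel is omitted
#' (pure-birth process).
#'
#' @param k birth rate constant (per hour).
#' @param kd death rate (per hour); `0` drops the channel.
#' @param input_modulated should the birth propensity be scaled by the input?
#' @export
birth_death_network <- function(k = 1, kd = 1, input_modulated = TRUE) {
  rx <- list(mass_action_reaction(NULL, c(X = 1), rate = k,
                                  input_modulated = input_modulated, name = "birth"))
  if (kd > 0)
    rx <- c(rx, list(mass_action_reaction(c(X = 1), NULL, rate = kd, name = "death")))
  reaction_network("X", rx, name = if (kd > 0) "birth-death" else "pure birth")
}

#' Per-channel propensities and their total
#'
#' @param net a `reaction_network`.
#' @param state named or positional nonnegative integer state vector.
#' @param input scalar input value \eqn{I(t)} (clipped at 0 for modulated
#'   mass-action channels).
#' @param t time, passed to custom propensity functions.
#' @return numeric vector of per-channel propensities (`propensities`) or a
#'   list with elements `a0` (their sum) and `a` (`total_propensity`).
#' @export
propensities <- function(net, state, input = 0, t = 0) {
  stopifnot(inherits(net, "reaction_network"))
  x <- as_state(net, state)
  M <- ncol(net$stoich)
  a <- numeric(M)
  Ieff <- max(input, 0)
  for (j in seq_len(M)) {
    if (!is.null(net$custom) && !is.null(net$custom[[j]])) {
      aj <- net$custom[[j]](x, input, t)
      if (!is.finite(aj) || aj < 0)
        stop("propensity contract violated by channel ", j, " (",
             net$reaction_names[j], "): value ", aj)
      a[j] <- aj
    } else {
      aj <- net$rates[j] * if (net$input_scaled[j]) Ieff else 1
      o <- net$orders[, j]
      for (s in which(o > 0L)) aj <- aj * prod(x[s] - seq_len(o[s]) + 1)
      a[j] <- max(aj, 0)
    }
  }
  names(a) <- net$reaction_names
  a
}

#' @rdname propensities
#' @export
total_propensity <- function(net, state, input = 0, t = 0) {
  a <- propensities(net, state, input, t)
  list(a0 = sum(a), a = a)
}

as_state <- function(net, state) {
  sp <- net$species
  if (!is.null(names(state))) {
    if (!setequal(names(state), sp)) stop("state names must match species")
    state <- state[sp]
  }
  if (length(state) != length(sp)) stop("state must have one entry per species")
  x <- as.integer(round(state))
  if (any(x < 0)) stop("copy numbers must be nonnegative")
  names(x) <- sp
  x
}

#' Apply one reaction to a state
#'
#' @param state state vector (named or positional).
#' @param net a `reaction_network`.
#' @param j channel index, `1..M`.
#' @return the updated named state vector `X + nu_j`.
#' @export
apply_reaction <- function(state, net, j) {
  stopifnot(inherits(net, "reaction_network"))
  j <- as.integer(j)
  if (j < 1L || j > ncol(net$stoich)) stop("channel index out of range")
  x <- as_state(net, state) + net$stoich[, j]
  if (any(x < 0))
    stop("channel ", j, " would drive a copy number negative ",
         "(propensity contract violated upstream)")
  x
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("<reaction_network> ", x$name, "\n", sep = "")
  cat("  species:  ", paste(x$species, collapse = ", "), "\n", sep = "")
  cat("  channels: ", ncol(x$stoich), "\n", sep = "")
  for (j in seq_along(x$reaction_names)) {
    tag <- if (!is.null(x$custom) && !is.null(x$custom[[j]])) "custom"
           else if (x$input_scaled[j]) sprintf("rate %g x I(t)", x$rates[j])
           else sprintf("rate %g", x$rates[j])
    cat(sprintf("   [%d] %-28s %s\n", j, x$reaction_names[j], tag))
  }
  invisible(x)
}
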