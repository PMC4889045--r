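#' Load and validate a run configuration
#'
#' Configurations are YAML (or JSON) with top-level keys `model`, `input`,
#' `method`, `T`, `seed` and optional method settings (`L`, `bound`,
#' `dt_int`), `x0`, and `output`. Unknown keys are a hard error (no silent
#' typo tolerance); method-specific required fields are checked by name.
#' Defaults: left-constant interpolation, `L = "auto"`, method `"extrande"`.
#'
#' Model block: either `type: two-stage` with `ks`, `kdm`, `kdp`, or
#' `type: mass-action` with `species` and a `reactions` list (each reaction:
#' `reactants`/`products` maps, `rate`, optional `input_modulated`).
#' Input block: `generator` (`constant`, `circadian`, `ou`,
#' `lognormal-normalized`, `modulated-circadian`, `sum-of-ou`, `csv`) with its
#' parameters, plus `dt` and optional `seed`.
#'
#' @param path config file (`.yaml`/`.yml`/`.json`).
#' @return validated list of class `run_config` with defaults filled in.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @rdname load_run_config
#' @param cfg configuration list.
#' @export
validate_run_config <- function(cfg) {
  allowed <- c("model", "input", "method", "T", "seed", "L", "bound",
               "safety", "dt_int", "variant", "x0", "output", "n_cells",
               "out_points")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  for (key in c("model", "input", "T"))
    if (is.null(cfg[[key]])) stop("missing required config field: ", key)
  cfg$method <- cfg$method %||% "extrande"
  if (!cfg$method %in% c("extrande", "sia", "mn-integral", "direct-integral"))
    stop("unknown method: ", cfg$method)
  if (cfg$method %in% c("mn-integral", "direct-integral") && is.null(cfg$dt_int))
    stop("missing required config field for integral methods: dt_int")
  if (cfg$method == "extrande") {
    cfg$L <- cfg$L %||% "auto"
    cfg$bound <- cfg$bound %||% "window-max"
    cfg$safety <- cfg$safety %||% 1
  }
  cfg$seed <- cfg$seed %||% 1L
  cfg$input$interpolation <- cfg$input$interpolation %||% "left-constant"
  if (is.null(cfg$input$generator)) stop("missing required config field: input$generator")
  if (is.null(cfg$input$dt) && !cfg$input$generator %in% c("csv"))
    stop("missing required config field: input$dt")
  structure(cfg, class = "run_config")
}

#' @rdname load_run_config
#' @export
save_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

build_model <- function(m) {
  type <- m$type %||% stop("model$type is required")
  if (type == "two-stage") return(two_stage_network(m$ks, m$kdm, m$kdp))
  if (type == "birth-death") return(birth_death_network(m$k %||% 1, m$kd %||% 1))
  if (type == "mass-action") {
    rx <- lapply(m$reactions, function(r)
      mass_action_reaction(unlist(r$reactants), unlist(r$products),
                           rate = r$rate,
                           input_modulated = isTRUE(r$input_modulated),
                           name = r$name))
    return(reaction_network(unlist(m$species), rx, name = m$name))
  }
  stop("unknown model type: ", type)
}

build_input <- function(inp, T) {
  gen <- inp$generator
  dt <- inp$dt
  switch(gen,
    "constant" = input_trajectory(c(0, T), rep(inp$value, 2), inp$interpolation,
                                  meta = list(generator = "constant", value = inp$value)),
    "circadian" = circadian_rate(inp$kdp, inp$f %||% (1 / 24), dt, T,
                                 interpolation = inp$interpolation),
    "ou" = ou_process(inp$mu, inp$gamma, sigma2 = inp$sigma2, cv = inp$cv,
                      dt = dt, T = T, seed = inp$seed,
                      scheme = inp$scheme %||% "euler-maruyama"),
    "lognormal-normalized" = lognormal_normalized_rate(
      ou_process(0, inp$gamma, sigma2 = inp$sigma2, dt = dt, T = T,
                 seed = inp$seed),
      k_bar = inp$k_bar),
    "modulated-circadian" = modulated_circadian_rate(
      ou_process(0, inp$gamma, sigma2 = inp$sigma2, dt = dt, T = T,
                 seed = inp$seed),
      amplitude = inp$amplitude %||% 20, f = inp$f %||% (1 / 24)),
    "sum-of-ou" = sum_of_ou(inp$components, dt, T, seed = inp$seed),
    "csv" = read_input_csv(inp$path, interpolation = inp$interpolation),
    stop("unknown input generator: ", gen))
}

#' Run a configured simulation and write its artifacts
#'
#' Builds the network and input from a [load_run_config()] configuration,
#' runs the requested method, and writes to the output directory: the sampled
#' trajectory (`trajectory.csv`: time, event label, species columns), event
#' statistics and a run summary (`summary.json`), the fully resolved config
#' echo (`config_echo.yaml`) and a log file with seeds and a config hash.
#' Reruns of the same config are byte-identical.
#'
#' @param cfg a `run_config` (or path to one).
#' @param out_dir output directory; default `cfg$output` or a tempdir.
#' @return (invisibly) list with the trajectory object and artifact paths.
#' @export
run_and_report <- function(cfg, out_dir = NULL) {
  if (is.character(cfg)) cfg <- load_run_config(cfg)
  cfg <- validate_run_config(cfg)
  out_dir <- out_dir %||% cfg$output %||% tempfile("extrande_run_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)

  net <- build_model(cfg$model)
  input <- build_input(cfg$input, cfg$T)
  x0 <- if (!is.null(cfg$x0)) unlist(cfg$x0)
        else stats::setNames(rep(0L, length(net$species)), net$species)
  traj <- switch(cfg$method,
    "extrande" = extrande(net, x0, input, cfg$T, L = parse_L(cfg$L),
                          bound = cfg$bound, safety = cfg$safety, seed = cfg$seed),
    "sia" = sia(net, x0, input, cfg$T, seed = cfg$seed),
    "mn-integral" = mn_integral(net, x0, input, cfg$T, dt_int = cfg$dt_int,
                                seed = cfg$seed),
    "direct-integral" = mn_integral(net, x0, input, cfg$T, dt_int = cfg$dt_int,
                                    variant = "direct", seed = cfg$seed))

  traj_path <- file.path(out_dir, "trajectory.csv")
  ev <- data.frame(time_h = traj$times, event = traj$labels)
  ev <- cbind(ev, as.data.frame(traj$states))
  utils::write.csv(ev, traj_path, row.names = FALSE)

  cfg_path <- file.path(out_dir, "config_echo.yaml")
  save_run_config(cfg, cfg_path)
  codes <- utf8ToInt(paste(readLines(cfg_path), collapse = "\n"))
  cfg_hash <- sum(codes * seq_along(codes)) %% 2^31

  summary_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(list(
    method = cfg$method, T = cfg$T, seed = cfg$seed,
    n_reaction_events = sum(!is.na(traj$channel)),
    x_final = as.list(traj$x_final),
    stats = as.list(traj$stats),
    trapped = isTRUE(traj$trapped),
    config_hash = cfg_hash,
    package_version = as.character(utils::packageVersion("extrande"))
  ), summary_path, auto_unbox = TRUE, digits = NA, null = "null")

  log_path <- file.path(out_dir, "run.log")
  writeLines(c(
    sprintf("extrande %s run", as.character(utils::packageVersion("extrande"))),
    sprintf("method=%s T=%g seed=%d config_hash=%.0f", cfg$method, cfg$T,
            cfg$seed, cfg_hash),
    sprintf("events: %s", paste(sprintf("%s=%g", names(traj$stats), traj$stats),
                                collapse = " "))
  ), log_path)

  invisible(list(trajectory = traj,
                 paths = c(trajectory = traj_path, summary = summary_path,
                           config = cfg_path, log = log_path)))
}

parse_L <- function(L) {
  if (is.character(L) && !L %in% c("auto", "horizon"))
    stop("L must be numeric, 'auto' or 'horizon'")
  if (is.character(L)) L else as.numeric(L)
}
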