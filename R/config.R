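#' Default run configuration
#'
#' Flat key-value list of every model, network, integration, and analysis
#' setting, at the study defaults: `eps = 0.01`, `a = 1.1`, `A = 0.14`,
#' `Te = 14`, `g = 0.01`, `N = 100`, `k = 30`, `p = 0.15`, `dt = 0.001`,
#' embedding dimension `d = 3`.
#'
#' @return named list.
#' @export
default_config <- function() {
  list(
    # model
    eps = 0.01, a = 1.1, A = 0.14, Te = 14, g = 0.01, D = 0.08, tau = 0,
    sqrt2_noise = FALSE,
    # network
    N = 100L, k = 30L, p = 0.15, network_seed = 1L,
    # integration
    dt = 0.001, t_total = 500, t_transient = 100, seed = 1L,
    record_stride = 10L,
    # analysis
    d = 3L, threshold = 0, refractory = 1, prominence = 0.05,
    L_target = 2000L, max_realizations = 100L, reps_snr = 30L,
    # output
    out_dir = "results"
  )
}

#' Load and validate a run configuration
#'
#' Reads a flat JSON object, fills unspecified keys with [default_config()]
#' values, rejects unknown keys, and checks the structural invariants
#' (even `k < N`, `p` in `[0, 1]`, positive `dt`, `t_transient < t_total`,
#' `d` in 3..7).
#'
#' @param path JSON file, or a named list already in memory.
#' @return validated named list of class `run_config`.
#' @export
load_config <- function(path) {
  cfg <- default_config()
  user <- if (is.character(path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (is.list(path)) path else stop("path must be a file or a list")
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (nm in names(user)) {
    tgt <- cfg[[nm]]
    val <- user[[nm]]
    if (is.logical(tgt) && !is.logical(val))
      stop(sprintf("config key '%s' must be logical", nm))
    if (is.numeric(tgt) && !is.numeric(val))
      stop(sprintf("config key '%s' must be numeric", nm))
    if (is.character(tgt) && !is.character(val))
      stop(sprintf("config key '%s' must be character", nm))
    cfg[[nm]] <- if (is.integer(tgt) && is.numeric(val)) as.integer(val) else val
  }
  if (cfg$k %% 2L != 0L) stop("config: k must be even")
  if (cfg$k >= cfg$N) stop("config: k must be smaller than N")
  if (cfg$p < 0 || cfg$p > 1) stop("config: p must lie in [0, 1]")
  if (cfg$dt <= 0) stop("config: dt must be positive")
  if (cfg$t_transient >= cfg$t_total)
    stop("config: t_transient must be smaller than t_total")
  if (cfg$d < 3L || cfg$d > 7L) stop("config: d must lie in 3..7")
  if (cfg$D < 0) stop("config: D must be non-negative")
  if (cfg$tau < 0) stop("config: tau must be non-negative")
  structure(cfg, class = c("run_config", "list"))
}

#' @rdname load_config
#' @param cfg a `run_config`.
#' @export
save_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# unpack a run_config into the package's parameter objects
config_objects <- function(cfg) {
  list(
    net = ws_network(cfg$N, cfg$k, cfg$p, seed = cfg$network_seed),
    model = fhn_params(eps = cfg$eps, a = cfg$a, A = cfg$A, Te = cfg$Te,
                       g = cfg$g, D = cfg$D, tau = cfg$tau,
                       sqrt2_noise = cfg$sqrt2_noise),
    control = sim_control(dt = cfg$dt, t_total = cfg$t_total,
                          t_transient = cfg$t_transient, seed = cfg$seed,
                          record_stride = cfg$record_stride)
  )
}

#' Write a run manifest
#'
#' Records the effective configuration, seeds, and package version next to
#' the outputs of an analysis run, so any result file can be regenerated.
#'
#' @param cfg the `run_config` (or plain list) used.
#' @param path output JSON file.
#' @param extra optional named list of additional fields.
#' @export
write_manifest <- function(cfg, path, extra = list()) {
  man <- c(list(package = "fhnsmr",
                version = as.character(utils::packageVersion("fhnsmr")),
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
           list(config = unclass(cfg)), extra)
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
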