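#' Default parameter profile
#'
#' The fitted reference configuration of the yeast public-goods system:
#' growth constants, daily dilution factor 650 and migration rate 0.6.
#'
#' @return A named list with entries `r`, `c`, `K`, `eps`, `kM`, `t_grow`,
#'   `D`, `m`.
#' @export
default_profile <- function() {
  list(r = 0.5, c = 0.07, K = 90000, eps = 14, kM = 26, t_grow = 22,
       D = 650, m = 0.6)
}

config_keys <- list(
  profile = c("r", "c", "K", "eps", "kM", "t_grow", "D", "m"),
  topology = c("kind", "n", "n_side", "m_attach", "k", "p", "file"),
  top = c("profile", "topology", "n_cycles", "extinction_cutoff",
          "initial_fraction", "initial_density", "seed", "out", "log_level")
)

#' Load and validate a run configuration
#'
#' Reads a YAML configuration describing one simulation run: a parameter
#' `profile` (any omitted value falls back to [default_profile()]), a
#' `topology` block, cycle counts, initial condition, the mandatory `seed`,
#' and output settings. Unknown keys anywhere are rejected with an error
#' naming them, so typos cannot silently change a run.
#'
#' @param path Path to a YAML file.
#' @return An object of class `run_config`: validated named list with
#'   complete `profile`, `topology`, `n_cycles`, `extinction_cutoff`,
#'   `initial_fraction`, `initial_density`, `seed` and optional `out`,
#'   `log_level`.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw) || !length(raw))
    stop("empty config: required keys missing: ",
         "topology, seed", call. = FALSE)
  unknown <- setdiff(names(raw), config_keys$top)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  missing_req <- setdiff(c("topology", "seed"), names(raw))
  if (length(missing_req))
    stop("missing required config keys: ",
         paste(missing_req, collapse = ", "), call. = FALSE)
  prof <- utils::modifyList(default_profile(),
                            if (is.null(raw$profile)) list() else raw$profile)
  unknown_p <- setdiff(names(prof), config_keys$profile)
  if (length(unknown_p))
    stop("unknown profile keys: ", paste(unknown_p, collapse = ", "),
         call. = FALSE)
  unknown_t <- setdiff(names(raw$topology), config_keys$topology)
  if (length(unknown_t))
    stop("unknown topology keys: ", paste(unknown_t, collapse = ", "),
         call. = FALSE)
  # validate by construction
  model_params(r = prof$r, c = prof$c, K = prof$K, eps = prof$eps,
               kM = prof$kM, t_grow = prof$t_grow)
  cfg <- list(
    profile = prof,
    topology = raw$topology,
    n_cycles = if (is.null(raw$n_cycles)) 100L else as.integer(raw$n_cycles),
    extinction_cutoff = if (is.null(raw$extinction_cutoff)) 0.005
                        else raw$extinction_cutoff,
    initial_fraction = if (is.null(raw$initial_fraction)) 0.1
                       else raw$initial_fraction,
    initial_density = if (is.null(raw$initial_density)) 75000
                      else raw$initial_density,
    seed = as.integer(raw$seed),
    out = raw$out,
    log_level = if (is.null(raw$log_level)) "info" else raw$log_level
  )
  build_topology(cfg$topology)  # fail fast on an invalid topology spec
  protocol(D = prof$D, m = prof$m,
           params = model_params(r = prof$r, c = prof$c, K = prof$K,
                                 eps = prof$eps, kM = prof$kM,
                                 t_grow = prof$t_grow),
           n_cycles = cfg$n_cycles,
           extinction_cutoff = cfg$extinction_cutoff)
  structure(cfg, class = "run_config")
}

#' Build a topology from a config block
#'
#' @param spec Named list with `kind` (one of `"star"`, `"fully_connected"`,
#'   `"isolated"`, `"barabasi_albert"`, `"watts_strogatz"`, `"file"`) and the
#'   generator arguments it needs (`n`, `n_side`, `m_attach`, `k`, `p`,
#'   `file`); seeded generators take the run seed separately.
#' @param seed Seed forwarded to random generators.
#' @return A [topology()].
#' @export
build_topology <- function(spec, seed = 1L) {
  if (is.null(spec$kind)) stop("topology needs a 'kind'", call. = FALSE)
  switch(spec$kind,
    star = star_topology(spec$n_side %||% 9),
    fully_connected = fully_connected(spec$n %||% 10),
    isolated = isolated_nodes(spec$n %||% 10),
    barabasi_albert = barabasi_albert(spec$n %||% 100,
                                      spec$m_attach %||% 2, seed = seed),
    watts_strogatz = watts_strogatz(spec$n %||% 100, spec$k %||% 4,
                                    spec$p %||% 0.1, seed = seed),
    file = read_edgelist(spec$file, n = spec$n),
    stop("unknown topology kind: ", spec$kind, call. = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a run configuration back to YAML
#'
#' Round-trip companion of [load_config()]: `load_config(write_config(x))`
#' reproduces `x`.
#'
#' @param cfg A `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  yaml::write_yaml(unclass(cfg)[!vapply(unclass(cfg), is.null, logical(1))],
                   path)
  invisible(path)
}

#' Write a run manifest
#'
#' Records everything needed to re-run a simulation bitwise-identically:
#' the full configuration, the package and R versions, and paths of the
#' produced outputs.
#'
#' @param cfg A `run_config` (or plain list of inputs).
#' @param outputs Named list or character vector of output file paths.
#' @param path Manifest destination (JSON).
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(cfg, outputs, path) {
  manifest <- list(
    config = unclass(cfg),
    outputs = as.list(outputs),
    versions = list(
      package = as.character(utils::packageVersion("metapopsim")),
      R = paste(R.version$major, R.version$minor, sep = ".")
    ),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}

#' Migration rate per cell generation
#'
#' Converts the per-cycle migration rate into a per-generation rate using
#' the number of doublings per growth cycle; at equilibrium the within-cycle
#' growth exactly compensates the dilution, so the number of generations per
#' cycle is `log2(D)`.
#'
#' @param m Migration rate per cycle.
#' @param D Daily dilution factor.
#' @return Migration rate per generation.
#' @export
#' @examples
#' per_generation_migration(0.6, 650)  # ~0.06
per_generation_migration <- function(m, D) {
  if (D <= 1) stop("'D' must be > 1", call. = FALSE)
  m / log2(D)
}
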