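#' Serial-dilution protocol
#'
#' Describes the daily regime applied to every well: dilution by a factor
#' `D` into fresh medium, migration at rate `m` along the network, then batch
#' growth for `params$t_grow` hours. An optional one-cycle perturbation
#' substitutes a harsher dilution factor `D' = D * dD` or a reduced growth
#' rate `r' = r - dr` for a single cycle, after which all parameters return
#' to normal.
#'
#' @param D Daily dilution factor (>= 1).
#' @param m Migration rate per cycle, in `[0, 1]`.
#' @param params A [model_params()] object.
#' @param n_cycles Number of daily cycles to simulate.
#' @param perturbation Optional list with elements `cycle` (1-based cycle
#'   index), `kind` (`"dilution_shock"` or `"growth_shock"`) and `magnitude`
#'   (`dD >= 1` for dilution shocks, `0 <= dr <= r` for growth shocks).
#' @param extinction_cutoff Density (cells/uL) below which a node's total
#'   population is set to exactly zero after growth. The default 0.005
#'   cells/uL is about one cell in a 200 uL well.
#' @param rtol,atol,method Integration settings passed to [grow()].
#' @return An object of class `protocol`.
#' @export
#' @examples
#' protocol(D = 650, m = 0.6)
protocol <- function(D = 650, m = 0.6, params = model_params(),
                     n_cycles = 100, perturbation = NULL,
                     extinction_cutoff = 0.005,
                     rtol = 1e-8, atol = 1e-10, method = "lsoda") {
  stopifnot(inherits(params, "model_params"))
  if (length(D) != 1L || !is.finite(D) || D < 1)
    stop("'D' must be a single number >= 1", call. = FALSE)
  if (length(m) != 1L || !is.finite(m) || m < 0 || m > 1)
    stop("'m' must lie in [0, 1]", call. = FALSE)
  if (n_cycles < 1L) stop("'n_cycles' must be >= 1", call. = FALSE)
  if (extinction_cutoff < 0)
    stop("'extinction_cutoff' must be >= 0", call. = FALSE)
  if (!is.null(perturbation)) {
    if (!all(c("cycle", "kind", "magnitude") %in% names(perturbation)))
      stop("perturbation needs 'cycle', 'kind' and 'magnitude'", call. = FALSE)
    kind <- match.arg(perturbation$kind, c("dilution_shock", "growth_shock"))
    perturbation$kind <- kind
    mag <- perturbation$magnitude
    if (kind == "dilution_shock" && (!is.finite(mag) || mag < 1))
      stop("dilution shock magnitude dD must be >= 1", call. = FALSE)
    if (kind == "growth_shock" && (mag < 0 || mag > params$r))
      stop("growth shock magnitude dr must lie in [0, r]", call. = FALSE)
  }
  structure(list(D = D, m = m, params = params,
                 n_cycles = as.integer(n_cycles),
                 perturbation = perturbation,
                 extinction_cutoff = extinction_cutoff,
                 rtol = rtol, atol = atol, method = method),
            class = "protocol")
}

#' @export
print.protocol <- function(x, ...) {
  cat(sprintf("Protocol: D = %g, m = %g, %d cycles, cutoff %g cells/uL\n",
              x$D, x$m, x$n_cycles, x$extinction_cutoff))
  if (!is.null(x$perturbation))
    cat(sprintf("  perturbation at cycle %d: %s, magnitude %g\n",
                x$perturbation$cycle, x$perturbation$kind,
                x$perturbation$magnitude))
  invisible(x)
}

#' Advance the metapopulation by one daily cycle
#'
#' Applies, in order: dilution by `D` (or `D * dD` on a perturbed cycle),
#' migration, batch growth for `t_grow` hours (at rate `r - dr` on a
#' growth-shock cycle), then the extinction cutoff, which zeroes any node
#' whose total density falls below `extinction_cutoff`.
#'
#' @param state n x 2 state matrix holding end-of-growth densities of the
#'   previous cycle.
#' @param op A [migration_matrix()] operator matching the topology.
#' @param proto A [protocol()].
#' @param cycle_index 1-based index of the cycle being run (used to trigger
#'   the perturbation).
#' @return The n x 2 state matrix at the end of this cycle's growth.
#' @export
run_cycle <- function(state, op, proto, cycle_index = 1L) {
  stopifnot(inherits(proto, "protocol"))
  D <- proto$D
  params <- proto$params
  pert <- proto$perturbation
  duration <- params$t_grow
  if (!is.null(pert) && cycle_index == pert$cycle) {
    if (pert$kind == "dilution_shock") {
      D <- D * pert$magnitude
    } else if (pert$magnitude >= params$r) {
      duration <- 0      # growth fully suppressed for this cycle
    } else {
      params <- model_params(r = params$r - pert$magnitude, c = params$c,
                             K = params$K, eps = params$eps, kM = params$kM,
                             t_grow = params$t_grow)
    }
  }
  state <- state / D
  state <- migrate(state, op)
  state <- grow(state, params, duration = duration,
                rtol = proto$rtol, atol = proto$atol, method = proto$method)
  dead <- (state[, 1L] + state[, 2L]) < proto$extinction_cutoff
  state[dead, ] <- 0
  state
}

#' Simulate a metapopulation over many daily cycles
#'
#' Iterates [run_cycle()] for `proto$n_cycles` cycles on the given topology.
#' The initial state is interpreted as an end-of-growth (pre-dilution) state,
#' so cycle 1 starts by diluting it. The run is fully deterministic; it stops
#' early (flagged) once every node is extinct, since extinction is absorbing.
#'
#' @param topo A [topology()].
#' @param proto A [protocol()].
#' @param init n x 2 initial state matrix, or a list with `fraction` and
#'   `density` entries expanded uniformly over nodes via [uniform_state()].
#' @param record If `FALSE`, only the final state is kept (faster for long
#'   scans).
#' @return An object of class `trajectory`: list with `states` (a
#'   cycles x n x 2 array when `record = TRUE`), `final` (n x 2 matrix),
#'   `cycles_run`, `all_extinct`, `extinct_at` (first cycle at which each
#'   node hit zero, `NA` if never), `topology` and `protocol`.
#' @export
#' @examples
#' tr <- simulate_metapopulation(star_topology(9), protocol(n_cycles = 20),
#'                               uniform_state(10, fraction = 0.1))
#' tail(as.data.frame(tr), 3)
simulate_metapopulation <- function(topo, proto, init, record = TRUE) {
  stopifnot(inherits(topo, "topology"), inherits(proto, "protocol"))
  if (is.list(init) && !is.matrix(init))
    init <- uniform_state(topo$n, init$fraction, init$density)
  validate_state(init)
  if (nrow(init) != topo$n)
    stop(sprintf("initial state has %d nodes, topology has %d",
                 nrow(init), topo$n), call. = FALSE)
  op <- migration_matrix(topo, proto$m)
  n <- topo$n
  n_cycles <- proto$n_cycles
  states <- if (record)
    array(NA_real_, dim = c(n_cycles, n, 2L),
          dimnames = list(NULL, NULL, c("Np", "Nnp")))
  extinct_at <- rep(NA_integer_, n)
  state <- init
  cycles_run <- 0L
  all_extinct <- all(state[, 1L] + state[, 2L] == 0)
  if (!all_extinct) {
    for (k in seq_len(n_cycles)) {
      state <- run_cycle(state, op, proto, cycle_index = k)
      cycles_run <- k
      if (record) states[k, , ] <- state
      zero <- (state[, 1L] + state[, 2L]) == 0
      extinct_at[zero & is.na(extinct_at)] <- k
      if (all(zero)) { all_extinct <- TRUE; break }
    }
  }
  if (record && cycles_run < n_cycles)
    states <- states[seq_len(max(cycles_run, 1L)), , , drop = FALSE]
  structure(list(states = states, final = state, cycles_run = cycles_run,
                 all_extinct = all_extinct, extinct_at = extinct_at,
                 topology = topo, protocol = proto),
            class = "trajectory")
}

#' Uniform initial state
#'
#' All nodes start at the same total density and producer fraction. The
#' default emulates an equilibrated overnight culture: density near the
#' end-of-growth scale with a given producer fraction.
#'
#' @param n Number of nodes.
#' @param fraction Producer fraction in `[0, 1]`.
#' @param density Total density per node (cells/uL).
#' @return An n x 2 state matrix.
#' @export
uniform_state <- function(n, fraction = 0.1, density = 75000) {
  if (fraction < 0 || fraction > 1)
    stop("'fraction' must lie in [0, 1]", call. = FALSE)
  node_state(rep(density * fraction, n), rep(density * (1 - fraction), n))
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d nodes, %d cycles run%s\n",
              x$topology$n, x$cycles_run,
              if (x$all_extinct) " (all nodes extinct)" else ""))
  invisible(x)
}

#' Tidy per-cycle, per-node trajectory table
#'
#' @param x A `trajectory` from [simulate_metapopulation()].
#' @param row.names,optional,... Ignored (standard generic arguments).
#' @return A data.frame with columns `cycle`, `node` (0-based), `role`,
#'   `Np`, `Nnp`, `total` and `fraction` (NA where a node is empty).
#' @export
as.data.frame.trajectory <- function(x, row.names = NULL, optional = FALSE,
                                     ...) {
  if (is.null(x$states))
    stop("trajectory was run with record = FALSE", call. = FALSE)
  n_cyc <- dim(x$states)[1L]
  n <- dim(x$states)[2L]
  roles <- x$topology$labels
  if (is.null(roles)) roles <- rep("node", n)
  Np <- as.vector(x$states[, , 1L])
  Nnp <- as.vector(x$states[, , 2L])
  total <- Np + Nnp
  data.frame(
    cycle = rep(seq_len(n_cyc), times = n),
    node = rep(seq_len(n) - 1L, each = n_cyc),
    role = rep(roles, each = n_cyc),
    Np = Np, Nnp = Nnp, total = total,
    fraction = ifelse(total > 0, Np / total, NA_real_)
  )
}

#' Write a trajectory to CSV
#'
#' @param x A `trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
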