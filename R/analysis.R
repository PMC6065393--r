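#' Producer fraction of a state or trajectory
#'
#' The overall producer fraction is the total number of producers divided by
#' the total number of cells across the whole network. For a trajectory the
#' fraction is reported per cycle, both network-wide and per node, plus
#' averaged per node role (center/side) for labelled topologies. Fractions
#' are `NA` where the corresponding population is empty.
#'
#' @param x An n x 2 state matrix or a `trajectory`.
#' @param ... Unused.
#' @return For a state matrix: a single number in `[0, 1]` (or `NA`). For a
#'   trajectory: a list with `overall` (per-cycle vector), `per_node`
#'   (cycles x n matrix) and `by_role` (data.frame `cycle`, `role`,
#'   `fraction`).
#' @export
#' @examples
#' producer_fraction(node_state(c(10, 30), c(90, 70)))  # 40/200 = 0.2
producer_fraction <- function(x, ...) UseMethod("producer_fraction")

#' @export
producer_fraction.matrix <- function(x, ...) {
  validate_state(x)
  tot <- sum(x)
  if (tot == 0) return(NA_real_)
  sum(x[, 1L]) / tot
}

#' @export
producer_fraction.trajectory <- function(x, ...) {
  if (is.null(x$states))
    stop("trajectory was run with record = FALSE", call. = FALSE)
  n_cyc <- dim(x$states)[1L]
  Np <- matrix(x$states[, , 1L], nrow = n_cyc)
  Nnp <- matrix(x$states[, , 2L], nrow = n_cyc)
  tot <- Np + Nnp
  overall_tot <- rowSums(tot)
  overall <- ifelse(overall_tot > 0, rowSums(Np) / overall_tot, NA_real_)
  per_node <- ifelse(tot > 0, Np / tot, NA_real_)
  roles <- x$topology$labels
  by_role <- NULL
  if (!is.null(roles)) {
    by_role <- do.call(rbind, lapply(unique(roles), function(rl) {
      sel <- roles == rl
      rtot <- rowSums(tot[, sel, drop = FALSE])
      data.frame(cycle = seq_along(rtot), role = rl,
                 fraction = ifelse(rtot > 0,
                                   rowSums(Np[, sel, drop = FALSE]) / rtot,
                                   NA_real_))
    }))
  }
  list(overall = overall, per_node = per_node, by_role = by_role)
}

#' Equilibrium producer fraction from a trajectory
#'
#' Mean network-wide producer fraction over the final `window` cycles.
#'
#' @param traj A `trajectory`.
#' @param window Number of final cycles to average over.
#' @return A number in `[0, 1]`, or `NA` if the population is extinct.
#' @export
equilibrium_fraction <- function(traj, window = 10) {
  pf <- producer_fraction(traj)$overall
  idx <- seq.int(max(1L, length(pf) - window + 1L), length(pf))
  mean(pf[idx])
}

# max relative change between two state matrices, on a floor scale
rel_change <- function(a, b, scale_floor = 1e-8) {
  max(abs(a - b) / pmax(abs(b), scale_floor))
}

# smallest lag p (1..max_period) at which `state` recurs within `tol` in the
# ring buffer `buf[1..n_buf]` (most recent state last); NA if none
recurrence_lag <- function(buf, n_buf, state, tol, max_period) {
  for (p in seq_len(min(n_buf, max_period))) {
    if (rel_change(state, buf[[n_buf - p + 1L]]) < tol) return(p)
  }
  NA_integer_
}

#' Long-run state of a metapopulation protocol
#'
#' Iterates daily cycles until the end-of-growth state either converges to a
#' fixed point (maximum relative change of any node density over one cycle
#' below `tol`), recurs periodically (a cycle-to-cycle return within `tol`
#' at some lag up to `max_period`, in which case the minimum-total-density
#' phase of the orbit is identified), or goes extinct. Non-convergence
#' within `max_cycles` is reported as its own outcome.
#'
#' @param topo A [topology()].
#' @param proto A [protocol()] (its `n_cycles` is ignored here).
#' @param init Initial n x 2 state; default [uniform_state()] over `topo$n`.
#' @param max_cycles Cycle budget (default 2000).
#' @param tol Relative recurrence tolerance (default 1e-6).
#' @param max_period Largest oscillation period searched (default 32).
#' @return A list with `outcome` (one of `"converged"`, `"oscillatory"`,
#'   `"extinct"`, `"nonconverged"`), `state` (the converged state, or for an
#'   oscillatory orbit the state at its minimum-density phase), `period`
#'   (1 for converged), `cycles` used, and `min_phase_offset` (cycles from
#'   the detected minimum-density phase to the last simulated cycle).
#' @export
steady_state <- function(topo, proto, init = uniform_state(topo$n),
                         max_cycles = 2000, tol = 1e-6, max_period = 32) {
  stopifnot(inherits(topo, "topology"), inherits(proto, "protocol"))
  if (is.list(init) && !is.matrix(init))
    init <- uniform_state(topo$n, init$fraction, init$density)
  validate_state(init)
  op <- migration_matrix(topo, proto$m)
  buf <- vector("list", max_period + 1L)   # ring buffer of recent states
  buf[[1L]] <- init
  n_buf <- 1L
  state <- init
  for (k in seq_len(max_cycles)) {
    state <- run_cycle(state, op, proto, cycle_index = k)
    if (all(state == 0))
      return(list(outcome = "extinct", state = state, period = NA_integer_,
                  cycles = k, min_phase_offset = NA_integer_))
    hit <- recurrence_lag(buf, n_buf, state, tol, max_period)
    if (!is.na(hit) && hit == 1L)
      return(list(outcome = "converged", state = state, period = 1L,
                  cycles = k, min_phase_offset = 0L))
    if (!is.na(hit)) {
      # orbit of period `hit`: the last `hit` states cover one full period
      orbit <- c(buf[seq.int(n_buf - hit + 2L, n_buf)], list(state))
      totals <- vapply(orbit, sum, numeric(1))
      i_min <- which.min(totals)
      return(list(outcome = "oscillatory", state = orbit[[i_min]],
                  period = hit, cycles = k,
                  min_phase_offset = length(orbit) - i_min))
    }
    if (n_buf == max_period + 1L) {
      buf <- c(buf[-1L], list(state))
    } else {
      n_buf <- n_buf + 1L
      buf[[n_buf]] <- state
    }
  }
  list(outcome = "nonconverged", state = state, period = NA_integer_,
       cycles = max_cycles, min_phase_offset = NA_integer_)
}

#' Does the metapopulation survive the protocol?
#'
#' Runs the full protocol and reports whether at least one node's total
#' density is above the extinction cutoff after `n_cycles` cycles. As the
#' dynamics are deterministic, a run that reaches a fixed point early (max
#' relative change per cycle below `converge_tol`) is classified as surviving
#' without simulating the remaining cycles.
#'
#' @param topo A [topology()].
#' @param proto A [protocol()].
#' @param init Initial n x 2 state matrix.
#' @param converge_tol Early fixed-point tolerance; set to 0 to force the
#'   full cycle count.
#' @return `TRUE` if the metapopulation survives, `FALSE` otherwise.
#' @export
survives <- function(topo, proto, init, converge_tol = 1e-10) {
  stopifnot(inherits(topo, "topology"), inherits(proto, "protocol"))
  validate_state(init)
  op <- migration_matrix(topo, proto$m)
  state <- init
  if (all(state == 0)) return(FALSE)
  has_pert <- !is.null(proto$perturbation)
  for (k in seq_len(proto$n_cycles)) {
    prev <- state
    state <- run_cycle(state, op, proto, cycle_index = k)
    if (all(state == 0)) return(FALSE)
    pert_pending <- has_pert && k < proto$perturbation$cycle
    if (converge_tol > 0 && !pert_pending &&
        rel_change(state, prev) < converge_tol)
      return(TRUE)
  }
  any(state[, 1L] + state[, 2L] > proto$extinction_cutoff)
}

#' Equilibrate a metapopulation at reference conditions
#'
#' Standard initial condition for stability scans: the steady state reached
#' at the reference dilution factor (default 650) with the migration rate of
#' interest. If equilibration fails (extinction or non-convergence), a
#' uniform state of (Np, Nnp) = (1000, 9000) cells/uL per node is returned
#' instead.
#'
#' @param topo A [topology()].
#' @param m Migration rate used in the scan.
#' @param params A [model_params()] object.
#' @param D_ref Reference dilution factor (default 650).
#' @param init Starting state for the equilibration.
#' @return An n x 2 state matrix.
#' @export
equilibrate <- function(topo, m, params = model_params(), D_ref = 650,
                        init = uniform_state(topo$n)) {
  ss <- steady_state(topo, protocol(D = D_ref, m = m, params = params),
                     init = init)
  if (ss$outcome %in% c("converged", "oscillatory")) ss$state
  else node_state(rep(1000, topo$n), rep(9000, topo$n))
}

#' Survival phase diagram over dilution and migration
#'
#' Classifies survival of the metapopulation over a grid of daily dilution
#' factors and migration rates. Each grid point is evaluated independently:
#' the system is first equilibrated at the reference dilution (650) with the
#' scanned migration rate, then run for `n_cycles` cycles at the scanned
#' dilution factor. The `m = 0` row reproduces isolated-node behaviour
#' exactly.
#'
#' @param topo A [topology()].
#' @param D_grid Numeric vector of dilution factors.
#' @param m_grid Numeric vector of migration rates.
#' @param params A [model_params()] object.
#' @param n_cycles Survival horizon in cycles (default 1000).
#' @param extinction_cutoff Passed to [protocol()].
#' @return An object of class `phase_diagram`: list with `D_grid`, `m_grid`,
#'   `survival` (logical matrix, rows = m, cols = D) and `n_cycles`.
#' @export
phase_diagram <- function(topo, D_grid, m_grid, params = model_params(),
                          n_cycles = 1000, extinction_cutoff = 0.005) {
  surv <- matrix(NA, nrow = length(m_grid), ncol = length(D_grid),
                 dimnames = list(m = m_grid, D = D_grid))
  for (i in seq_along(m_grid)) {
    init <- equilibrate(topo, m_grid[i], params)
    for (j in seq_along(D_grid)) {
      proto <- protocol(D = D_grid[j], m = m_grid[i], params = params,
                        n_cycles = n_cycles,
                        extinction_cutoff = extinction_cutoff)
      surv[i, j] <- survives(topo, proto, init)
    }
  }
  structure(list(D_grid = D_grid, m_grid = m_grid, survival = surv,
                 n_cycles = n_cycles),
            class = "phase_diagram")
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat(sprintf("Phase diagram: %d D x %d m grid, %d-cycle horizon; %d%% survive\n",
              length(x$D_grid), length(x$m_grid), x$n_cycles,
              round(100 * mean(x$survival))))
  invisible(x)
}

#' Tidy phase-diagram table
#' @param x A `phase_diagram`.
#' @param row.names,optional,... Ignored.
#' @return data.frame with columns `D`, `m`, `survives`.
#' @export
as.data.frame.phase_diagram <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  data.frame(D = rep(x$D_grid, each = length(x$m_grid)),
             m = rep(x$m_grid, times = length(x$D_grid)),
             survives = as.vector(x$survival))
}

#' Critical dilution factor (tipping point)
#'
#' Bisects the daily dilution factor between a surviving and a collapsing
#' bracket endpoint to locate the survival/collapse boundary over an
#' `n_cycles` horizon, starting every evaluation from the same initial state
#' (by default the equilibrium at dilution 650 with the given migration
#' rate).
#'
#' @param topo A [topology()].
#' @param m Migration rate.
#' @param params A [model_params()] object.
#' @param bracket Length-2 numeric: (surviving D, collapsing D) candidates.
#' @param tol Relative tolerance on the boundary (default 1e-3).
#' @param n_cycles Survival horizon (default 1000).
#' @param init Initial state; default [equilibrate()] at D = 650.
#' @param extinction_cutoff Passed to [protocol()].
#' @return A list with `D_star` (the boundary estimate), `D_survive` and
#'   `D_collapse` (the final bracket, one evaluated surviving and one
#'   collapsing), `tol` and `n_evals`.
#' @export
critical_dilution <- function(topo, m, params = model_params(),
                              bracket = c(400, 2000), tol = 1e-3,
                              n_cycles = 1000, init = NULL,
                              extinction_cutoff = 0.005) {
  if (is.null(init)) init <- equilibrate(topo, m, params)
  eval_D <- function(D)
    survives(topo, protocol(D = D, m = m, params = params,
                            n_cycles = n_cycles,
                            extinction_cutoff = extinction_cutoff), init)
  lo <- min(bracket); hi <- max(bracket)
  n_evals <- 2L
  if (!eval_D(lo))
    stop(sprintf("lower bracket D = %g already collapses; widen the bracket",
                 lo), call. = FALSE)
  if (eval_D(hi))
    stop(sprintf("upper bracket D = %g still survives; widen the bracket",
                 hi), call. = FALSE)
  while ((hi - lo) / lo > tol) {
    mid <- (lo + hi) / 2
    n_evals <- n_evals + 1L
    if (eval_D(mid)) lo <- mid else hi <- mid
  }
  list(D_star = (lo + hi) / 2, D_survive = lo, D_collapse = hi,
       tol = tol, n_evals = n_evals)
}

# shared recovery criterion: network total back within `recovery_tol` of the
# pre-shock steady-state total during the last cycles of the relaxation
relaxes_back <- function(topo, proto, init, ref_total,
                         recovery_tol = 0.05, check_window = 32L) {
  tr <- simulate_metapopulation(topo, proto, init, record = TRUE)
  if (tr$all_extinct) return(FALSE)
  totals <- rowSums(matrix(tr$states, nrow = dim(tr$states)[1L]))
  idx <- seq.int(max(1L, length(totals) - check_window + 1L), length(totals))
  any(abs(totals[idx] - ref_total) / ref_total <= recovery_tol)
}

#' Maximum tolerated one-cycle shock
#'
#' Measures resilience: starting from the steady state of the baseline
#' protocol (at the minimum-density phase if the steady state oscillates), a
#' single perturbed cycle is applied — either an extra dilution factor
#' (`D' = D * dD`) or a reduced growth rate (`r' = r - dr`) — after which the
#' system relaxes under the baseline protocol. The largest magnitude from
#' which the metapopulation still recovers (network total density returning
#' within `recovery_tol` of its pre-shock value) is found by bisection;
#' monotonicity of the outcome in the magnitude is assumed within the
#' bracket and verified at its endpoints, with a grid-scan fallback when the
#' endpoint check fails.
#'
#' @param topo A [topology()].
#' @param proto Baseline [protocol()] (must be survivable).
#' @param kind `"dilution_shock"` or `"growth_shock"`.
#' @param bracket Magnitude bracket: `(recovering, failing)` candidates.
#'   Defaults to `c(1, 64)` for dilution shocks and `c(0, r)` for growth
#'   shocks.
#' @param tol Bisection tolerance on the magnitude: relative for dilution
#'   shocks, absolute (in per-hour units) for growth shocks.
#' @param relax_cycles Post-shock relaxation horizon (default 500).
#' @param recovery_tol Relative band around the pre-shock total density that
#'   counts as recovered (default 0.05).
#' @param grid_n Number of points for the fallback grid scan.
#' @param init Initial state handed to [steady_state()] for the baseline
#'   equilibration (default: the mixed uniform start).
#' @return A list with `kind`, `max_magnitude` (`dD_max` or `dr_max`),
#'   `mag_recover` / `mag_fail` (final evaluated bracket), `baseline_D`,
#'   `oscillatory`, `tol` and `method` (`"bisection"` or `"grid"`).
#' @export
max_shock <- function(topo, proto, kind = c("dilution_shock", "growth_shock"),
                      bracket = NULL, tol = NULL, relax_cycles = 500,
                      recovery_tol = 0.05, grid_n = 33,
                      init = uniform_state(topo$n)) {
  kind <- match.arg(kind)
  ss <- steady_state(topo, proto, init = init)
  if (!(ss$outcome %in% c("converged", "oscillatory")))
    stop("baseline protocol does not reach a surviving steady state",
         call. = FALSE)
  ref_total <- sum(ss$state)
  if (is.null(bracket))
    bracket <- if (kind == "dilution_shock") c(1, 64)
               else c(0, proto$params$r)
  if (is.null(tol)) tol <- if (kind == "dilution_shock") 1e-3 else 1e-4
  recovers <- function(mag) {
    p <- protocol(D = proto$D, m = proto$m, params = proto$params,
                  n_cycles = 1L + relax_cycles,
                  perturbation = list(cycle = 1L, kind = kind,
                                      magnitude = mag),
                  extinction_cutoff = proto$extinction_cutoff,
                  rtol = proto$rtol, atol = proto$atol,
                  method = proto$method)
    relaxes_back(topo, p, ss$state, ref_total, recovery_tol)
  }
  lo <- min(bracket); hi <- max(bracket)
  done <- function(lo, hi)
    if (kind == "dilution_shock") (hi - lo) / lo <= tol else hi - lo <= tol
  method <- "bisection"
  if (!recovers(lo) || recovers(hi)) {
    # endpoint check failed: fall back to a grid scan for the last recovery
    method <- "grid"
    grid <- seq(min(bracket), max(bracket), length.out = grid_n)
    ok <- vapply(grid, recovers, logical(1))
    if (!any(ok))
      stop("no magnitude in the bracket recovers; shrink the bracket",
           call. = FALSE)
    i_max <- max(which(ok))
    lo <- grid[i_max]
    hi <- if (i_max < length(grid)) grid[i_max + 1L] else grid[i_max]
  } else {
    while (!done(lo, hi)) {
      mid <- (lo + hi) / 2
      if (recovers(mid)) lo <- mid else hi <- mid
    }
  }
  list(kind = kind, max_magnitude = (lo + hi) / 2,
       mag_recover = lo, mag_fail = hi, baseline_D = proto$D,
       oscillatory = ss$outcome == "oscillatory", tol = tol, method = method)
}

#' Minimum density from which the metapopulation recovers
#'
#' Locates the basin-of-attraction boundary below the surviving equilibrium:
#' the steady state of the protocol is scaled uniformly (all nodes, both
#' strains) by a factor `s` in (0, 1], and the smallest `s` from which the
#' system relaxes back to the equilibrium is found by bisection.
#'
#' @param topo A [topology()].
#' @param proto Baseline [protocol()] (must be survivable).
#' @param tol Absolute bisection tolerance on `s` (default 1e-3).
#' @param relax_cycles Relaxation horizon (default 500).
#' @param recovery_tol Relative recovery band (default 0.05).
#' @param init Initial state for the baseline equilibration.
#' @return A list with `s_star` (critical scaling), `threshold_density`
#'   (`s_star` times the mean per-node total equilibrium density, cells/uL),
#'   `equilibrium_density` (mean per-node total), and `oscillatory`.
#' @export
recovery_threshold <- function(topo, proto, tol = 1e-3, relax_cycles = 500,
                               recovery_tol = 0.05,
                               init = uniform_state(topo$n)) {
  ss <- steady_state(topo, proto, init = init)
  if (!(ss$outcome %in% c("converged", "oscillatory")))
    stop("baseline protocol does not reach a surviving steady state",
         call. = FALSE)
  ref_total <- sum(ss$state)
  relax_proto <- protocol(D = proto$D, m = proto$m, params = proto$params,
                          n_cycles = relax_cycles,
                          extinction_cutoff = proto$extinction_cutoff,
                          rtol = proto$rtol, atol = proto$atol,
                          method = proto$method)
  recovers <- function(s)
    relaxes_back(topo, relax_proto, ss$state * s, ref_total, recovery_tol)
  lo <- 0; hi <- 1
  if (!recovers(1))
    stop("equilibrium state does not stay recovered; inconsistent protocol",
         call. = FALSE)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (recovers(mid)) hi <- mid else lo <- mid
  }
  s_star <- (lo + hi) / 2
  eq_density <- ref_total / topo$n
  list(s_star = s_star, threshold_density = s_star * eq_density,
       equilibrium_density = eq_density,
       oscillatory = ss$outcome == "oscillatory")
}

#' Constrained grid calibration of the growth model
#'
#' Reconstructs the manual fit of the free model constants under their
#' biological constraint box: cost `c` below 0.1, private benefit expressed
#' as a ratio `eps/kM` between 0.25 and 1, and effective growth duration
#' between 19 and 22 h (lag phase 1-4 h of a 23 h incubation). Every grid
#' point is scored by squared relative error of its isolated-node summaries
#' (equilibrium producer fraction at the reference dilution, and collapse
#' dilution factor) against the supplied targets. This is a coarse
#' convenience search, not a statistical inference method.
#'
#' @param targets List with `eq_fraction` (producer fraction, 0-1 scale)
#'   and/or `D_star` (collapse dilution factor).
#' @param c_grid,ratio_grid,t_grow_grid Grids for cost, eps/kM ratio and
#'   growth duration.
#' @param r,K,kM Fixed constants (measured, not fitted).
#' @param D_ref Reference dilution for the equilibrium-fraction summary.
#' @param n_cycles Survival horizon used in the collapse-boundary summary.
#' @param D_bracket,D_tol Bisection settings for the collapse boundary.
#' @return A data.frame of candidates sorted by score, with columns `c`,
#'   `eps`, `kM`, `t_grow`, `eq_fraction`, `D_star`, `score`.
#' @export
calibrate <- function(targets,
                      c_grid = seq(0.03, 0.09, by = 0.02),
                      ratio_grid = seq(0.25, 1, length.out = 4),
                      t_grow_grid = c(19, 20, 21, 22),
                      r = 0.5, K = 90000, kM = 26, D_ref = 650,
                      n_cycles = 500, D_bracket = c(300, 3000),
                      D_tol = 0.02) {
  if (!any(c("eq_fraction", "D_star") %in% names(targets)))
    stop("'targets' must supply eq_fraction and/or D_star", call. = FALSE)
  combos <- expand.grid(c = c_grid, ratio = ratio_grid,
                        t_grow = t_grow_grid)
  topo <- isolated_nodes(1)
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    pars <- model_params(r = r, c = combos$c[i], K = K,
                         eps = combos$ratio[i] * kM, kM = kM,
                         t_grow = combos$t_grow[i])
    ss <- steady_state(topo, protocol(D = D_ref, m = 0, params = pars),
                       init = uniform_state(1), max_cycles = 500)
    eqf <- if (ss$outcome %in% c("converged", "oscillatory"))
      producer_fraction(ss$state) else NA_real_
    Dst <- NA_real_
    if (!is.null(targets$D_star) && !is.na(eqf)) {
      cd <- tryCatch(
        critical_dilution(topo, m = 0, params = pars, bracket = D_bracket,
                          tol = D_tol, n_cycles = n_cycles, init = ss$state),
        error = function(e) NULL)
      if (!is.null(cd)) Dst <- cd$D_star
    }
    score <- 0
    if (!is.null(targets$eq_fraction))
      score <- score + if (is.na(eqf)) Inf else
        ((eqf - targets$eq_fraction) / targets$eq_fraction)^2
    if (!is.null(targets$D_star))
      score <- score + if (is.na(Dst)) Inf else
        ((Dst - targets$D_star) / targets$D_star)^2
    data.frame(c = combos$c[i], eps = combos$ratio[i] * kM, kM = kM,
               t_grow = combos$t_grow[i], eq_fraction = eqf, D_star = Dst,
               score = score)
  })
  out <- do.call(rbind, rows)
  out[order(out$score), , drop = FALSE]
}
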