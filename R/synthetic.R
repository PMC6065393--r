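#' Measurement-noise model for synthetic plate experiments
#'
#' Describes how the underlying densities are observed: total density is read
#' out as an optical-density-like signal with multiplicative lognormal noise,
#' and the producer fraction is measured by counting a finite number of
#' cytometry events (binomial sampling).
#'
#' @param od_scale Conversion factor from cells/uL to OD-like units.
#' @param od_cv Coefficient of variation of the multiplicative lognormal
#'   density noise (default 0.05, a typical plate-reader scale).
#' @param cytometry_events Number of cells counted per fraction measurement
#'   (default 10000, a typical cytometer sample).
#' @param seed Integer seed; mandatory, so every dataset is reproducible.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(od_scale = 1e-4, od_cv = 0.05,
                        cytometry_events = 10000, seed) {
  if (missing(seed) || !length(seed) || !is.finite(seed))
    stop("'seed' is required", call. = FALSE)
  if (od_cv < 0) stop("'od_cv' must be >= 0", call. = FALSE)
  if (cytometry_events < 1)
    stop("'cytometry_events' must be >= 1", call. = FALSE)
  if (od_scale <= 0) stop("'od_scale' must be > 0", call. = FALSE)
  structure(list(od_scale = od_scale, od_cv = od_cv,
                 cytometry_events = as.integer(cytometry_events),
                 seed = as.integer(seed)),
            class = "noise_model")
}

# lognormal multiplier with mean 1 and coefficient of variation cv
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic plate experiment
#'
#' Simulates replicate metapopulations from several initial producer
#' fractions under one protocol, then overlays measurement noise: per
#' replicate, initial fraction, cycle and node, the observed density is the
#' true total density times `od_scale` times a lognormal multiplier, and the
#' observed producer fraction is a binomial draw over `cytometry_events`
#' cells. The underlying truth is retained alongside the observations, and
#' the whole dataset is reproducible from the noise-model seed. Replicates
#' share the (deterministic) dynamics and differ only in measurement noise.
#'
#' @param topo A [topology()].
#' @param proto A [protocol()].
#' @param initial_fractions Numeric vector of starting producer fractions.
#' @param replicates Number of replicate networks per initial fraction.
#' @param noise A [noise_model()].
#' @param initial_density Starting total density per node (cells/uL).
#' @return A data.frame with columns `replicate`, `initial_fraction`,
#'   `cycle`, `node`, `role`, `Np`, `Nnp`, `total`, `fraction` (the truth)
#'   plus `observed_density` and `observed_fraction`.
#' @export
#' @examples
#' d <- generate_experiment(isolated_nodes(1), protocol(n_cycles = 5),
#'                          initial_fractions = 0.1, replicates = 2,
#'                          noise = noise_model(seed = 1))
#' head(d)
generate_experiment <- function(topo, proto, initial_fractions,
                                replicates = 3, noise,
                                initial_density = 75000) {
  stopifnot(inherits(noise, "noise_model"))
  if (replicates < 1) stop("'replicates' must be >= 1", call. = FALSE)
  if (any(initial_fractions < 0 | initial_fractions > 1))
    stop("initial fractions must lie in [0, 1]", call. = FALSE)
  truth <- do.call(rbind, lapply(initial_fractions, function(f0) {
    tr <- simulate_metapopulation(
      topo, proto, uniform_state(topo$n, f0, initial_density))
    df <- as.data.frame(tr)
    df$initial_fraction <- f0
    df
  }))
  out <- withr::with_seed(noise$seed, {
    do.call(rbind, lapply(seq_len(replicates), function(rep_i) {
      df <- truth
      df$replicate <- rep_i
      nr <- nrow(df)
      df$observed_density <-
        df$total * noise$od_scale * rlnorm_cv(nr, noise$od_cv)
      true_frac <- ifelse(is.na(df$fraction), 0, df$fraction)
      df$observed_fraction <-
        stats::rbinom(nr, noise$cytometry_events, true_frac) /
        noise$cytometry_events
      df
    }))
  })
  cols <- c("replicate", "initial_fraction", "cycle", "node", "role",
            "Np", "Nnp", "total", "fraction",
            "observed_density", "observed_fraction")
  rownames(out) <- NULL
  out[, cols]
}

#' Summarise a synthetic experiment
#'
#' Applies the plate-level analysis to (synthetic) observations: the
#' equilibrium producer fraction is the mean network-wide observed fraction
#' over the final `window` cycles, and the survival call is whether the mean
#' observed density at the final cycle is above a detection floor. On
#' noiseless data these recover the model truth exactly.
#'
#' @param data A data.frame from [generate_experiment()].
#' @param window Number of final cycles averaged for the equilibrium
#'   fraction (default 10).
#' @param detection_floor Observed-density detection limit (default 1e-6
#'   OD-like units).
#' @return A data.frame with one row per `replicate` x `initial_fraction`:
#'   `equilibrium_fraction` (cell-weighted network-wide) and `survived`.
#' @export
estimate_summaries <- function(data, window = 10, detection_floor = 1e-6) {
  needed <- c("replicate", "initial_fraction", "cycle", "observed_density",
              "observed_fraction")
  if (!all(needed %in% names(data)))
    stop("'data' must come from generate_experiment()", call. = FALSE)
  groups <- unique(data[, c("replicate", "initial_fraction")])
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    d <- data[data$replicate == groups$replicate[i] &
                data$initial_fraction == groups$initial_fraction[i], ]
    last <- max(d$cycle)
    w <- d[d$cycle > last - window, ]
    # cell-weighted network fraction per cycle, then averaged over the window
    per_cycle <- vapply(split(w, w$cycle), function(dc) {
      tot <- sum(dc$observed_density)
      if (tot == 0) NA_real_
      else sum(dc$observed_fraction * dc$observed_density) / tot
    }, numeric(1))
    fin <- d[d$cycle == last, ]
    data.frame(replicate = groups$replicate[i],
               initial_fraction = groups$initial_fraction[i],
               equilibrium_fraction = mean(per_cycle),
               survived = mean(fin$observed_density) > detection_floor)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
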