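#' Growth-model parameters
#'
#' Bundles the constants of the within-cycle growth model of the two-strain
#' public-goods system: producers secrete an enzyme whose products (the public
#' good) any cell can import, so the per-capita growth rate of both strains
#' saturates with producer density following Michaelis-Menten kinetics, on top
#' of logistic competition for a shared carrying capacity.
#'
#' @param r Maximum per-capita growth rate (per hour).
#' @param c Cost of public-good production, as a fraction of the growth rate
#'   paid only by producers. Must lie in `[0, 1)`.
#' @param K Carrying capacity shared by both strains (cells/uL).
#' @param eps Private benefit of producers: the amount of public good a
#'   producer captures before the rest diffuses away, expressed as an
#'   equivalent producer density (cells/uL).
#' @param kM Half-saturation constant: the producer density at which the
#'   non-producer growth rate reaches half its maximum (cells/uL).
#' @param t_grow Effective growth duration of one daily cycle (hours). The
#'   default, 22 h, corresponds to a 23 h incubation with a 1 h lag phase
#'   absorbed implicitly.
#'
#' @return An object of class `model_params` (a named list).
#' @details The default values are the fitted constants for the budding-yeast
#'   sucrose (invertase) system: `r = 0.5` per hour, `K = 90000` cells/uL,
#'   `c = 0.07`, `eps = 14` cells/uL, `kM = 26` cells/uL, `t_grow = 22` h.
#' @seealso [growth_derivatives()], [grow()], [protocol()]
#' @export
#' @examples
#' p <- model_params()
#' p$K
model_params <- function(r = 0.5, c = 0.07, K = 90000, eps = 14, kM = 26,
                         t_grow = 22) {
  vals <- c(r = r, c = c, K = K, eps = eps, kM = kM, t_grow = t_grow)
  if (!all(is.finite(vals)))
    stop("model parameters must be finite numbers", call. = FALSE)
  if (r <= 0) stop("'r' must be > 0", call. = FALSE)
  if (c < 0 || c >= 1) stop("'c' must lie in [0, 1)", call. = FALSE)
  if (K <= 0) stop("'K' must be > 0", call. = FALSE)
  if (eps < 0) stop("'eps' must be >= 0", call. = FALSE)
  if (kM <= 0) stop("'kM' must be > 0", call. = FALSE)
  if (t_grow <= 0) stop("'t_grow' must be > 0", call. = FALSE)
  structure(list(r = r, c = c, K = K, eps = eps, kM = kM, t_grow = t_grow),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Growth-model parameters:\n")
  cat(sprintf("  r = %g /h, c = %g, K = %g cells/uL\n", x$r, x$c, x$K))
  cat(sprintf("  eps = %g cells/uL, kM = %g cells/uL, t_grow = %g h\n",
              x$eps, x$kM, x$t_grow))
  invisible(x)
}

#' Per-node population state
#'
#' Builds the canonical state representation used throughout the package: a
#' numeric matrix with one row per subpopulation (node) and two columns,
#' `Np` (producer density) and `Nnp` (non-producer density), in cells/uL.
#'
#' @param Np Numeric vector of producer densities (cells/uL).
#' @param Nnp Numeric vector of non-producer densities, same length.
#' @return An n x 2 matrix with columns `Np` and `Nnp`.
#' @export
#' @examples
#' node_state(Np = c(100, 50), Nnp = c(900, 950))
node_state <- function(Np, Nnp) {
  if (length(Np) != length(Nnp))
    stop("'Np' and 'Nnp' must have the same length", call. = FALSE)
  s <- cbind(Np = as.numeric(Np), Nnp = as.numeric(Nnp))
  validate_state(s)
  s
}

validate_state <- function(state) {
  if (!is.matrix(state) || ncol(state) != 2)
    stop("state must be an n x 2 matrix with columns Np, Nnp", call. = FALSE)
  if (any(!is.finite(state)))
    stop("state densities must be finite", call. = FALSE)
  if (any(state < 0))
    stop("state densities must be non-negative", call. = FALSE)
  invisible(state)
}

#' Instantaneous growth rates of producers and non-producers
#'
#' Right-hand side of the within-cycle growth dynamics. Both strains grow
#' logistically towards the common carrying capacity `K`, modulated by a
#' Michaelis-Menten factor in the producer density (the proxy for public-good
#' concentration). Producers additionally benefit from a privately captured
#' amount `eps` of public good and pay the production cost `c`:
#'
#' \deqn{dN_{np}/dt = r N_{np} (1 - (N_p+N_{np})/K) \frac{N_p}{N_p + k_M}}
#' \deqn{dN_p/dt = r (1-c) N_p (1 - (N_p+N_{np})/K)
#'   \frac{N_p + \epsilon}{N_p + \epsilon + k_M}}
#'
#' @param state n x 2 state matrix (see [node_state()]); nodes are independent.
#' @param params A [model_params()] object.
#' @return An n x 2 matrix of time derivatives (cells/uL/h), columns
#'   `Np`, `Nnp`.
#' @export
#' @examples
#' growth_derivatives(node_state(100, 900), model_params())
growth_derivatives <- function(state, params) {
  validate_state(state)
  stopifnot(inherits(params, "model_params"))
  Np <- state[, 1L]
  Nnp <- state[, 2L]
  logistic <- 1 - (Np + Nnp) / params$K
  dNp <- params$r * (1 - params$c) * Np * logistic *
    (Np + params$eps) / (Np + params$eps + params$kM)
  dNnp <- params$r * Nnp * logistic * Np / (Np + params$kM)
  cbind(Np = dNp, Nnp = dNnp)
}

# deSolve right-hand side over the flattened state c(Np, Nnp).
growth_rhs <- function(t, y, parms) {
  n <- length(y) %/% 2L
  Np <- y[seq_len(n)]
  Nnp <- y[n + seq_len(n)]
  logistic <- 1 - (Np + Nnp) / parms$K
  dNp <- parms$r * (1 - parms$c) * Np * logistic *
    (Np + parms$eps) / (Np + parms$eps + parms$kM)
  dNnp <- parms$r * Nnp * logistic * Np / (Np + parms$kM)
  list(c(dNp, dNnp))
}

#' Integrate one batch-growth period
#'
#' Numerically integrates the growth dynamics of [growth_derivatives()] for a
#' fixed duration using an adaptive-step solver, for all nodes at once (within
#' a cycle the nodes are uncoupled, so a single joint integration is exact).
#' Densities below `atol` after integration are clipped to exactly zero, and a
#' strain absent at the start remains exactly absent.
#'
#' @param state n x 2 state matrix.
#' @param params A [model_params()] object.
#' @param duration Growth time in hours; `duration = 0` returns the input.
#'   Defaults to `params$t_grow`.
#' @param rtol,atol Relative and absolute integration tolerances.
#' @param method deSolve integration method; default `"lsoda"`.
#' @return The n x 2 state matrix after `duration` hours of growth.
#' @export
#' @examples
#' grow(node_state(100, 100), model_params())
grow <- function(state, params, duration = params$t_grow,
                 rtol = 1e-8, atol = 1e-10, method = "lsoda") {
  validate_state(state)
  stopifnot(inherits(params, "model_params"))
  if (length(duration) != 1L || !is.finite(duration) || duration < 0)
    stop("'duration' must be a single non-negative number", call. = FALSE)
  if (duration == 0 || all(state == 0))
    return(state)
  y0 <- c(state[, 1L], state[, 2L])
  out <- deSolve::ode(y = y0, times = c(0, duration), func = growth_rhs,
                      parms = params, method = method,
                      rtol = rtol, atol = atol)
  istate <- attr(out, "istate")
  if (!is.null(istate) && istate[1L] < 0)
    stop(sprintf(
      "growth integration failed (istate = %d) for duration %g h; %s",
      istate[1L], duration,
      "try a looser tolerance or a different method"), call. = FALSE)
  if (nrow(out) < 2L || any(!is.finite(out[nrow(out), -1L])))
    stop("growth integration did not reach the requested duration",
         call. = FALSE)
  y1 <- as.numeric(out[nrow(out), -1L])
  y1[y1 < atol] <- 0          # clip integrator round-off; keeps zeros absorbing
  y1[y0 == 0] <- 0            # absent strains stay exactly absent
  n <- nrow(state)
  cbind(Np = y1[seq_len(n)], Nnp = y1[n + seq_len(n)])
}
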