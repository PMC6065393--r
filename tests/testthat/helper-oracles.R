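# Independent fixed-step RK4 integrator of the two-strain growth equations,
# used as a brute-force oracle for grow(). One node only; plain arithmetic,
# no shared code with the package's solver path.
rk4_grow <- function(Np, Nnp, params, duration, dt = 0.001) {
  f <- function(y) {
    logistic <- 1 - (y[1] + y[2]) / params$K
    c(params$r * (1 - params$c) * y[1] * logistic *
        (y[1] + params$eps) / (y[1] + params$eps + params$kM),
      params$r * y[2] * logistic * y[1] / (y[1] + params$kM))
  }
  y <- c(Np, Nnp)
  n_steps <- round(duration / dt)
  for (i in seq_len(n_steps)) {
    k1 <- f(y)
    k2 <- f(y + dt / 2 * k1)
    k3 <- f(y + dt / 2 * k2)
    k4 <- f(y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  y
}

# random admissible state matrices for property loops
random_state <- function(n, K = 90000) {
  node_state(stats::runif(n, 0, K / 2), stats::runif(n, 0, K / 2))
}

default_params <- model_params()
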