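test_that("producer fraction is the cell-weighted network total", {
  expect_equal(producer_fraction(node_state(c(10, 30), c(90, 70))), 0.2)
  expect_equal(producer_fraction(node_state(c(5, 5), c(0, 0))), 1)
  expect_true(is.na(producer_fraction(node_state(0, 0))))

  tr <- simulate_metapopulation(star_topology(9),
                                protocol(D = 650, m = 0.6, n_cycles = 15),
                                uniform_state(10, 0.1, 75000))
  pf <- producer_fraction(tr)
  expect_length(pf$overall, 15L)
  expect_true(all(pf$overall >= 0 & pf$overall <= 1))
  expect_equal(dim(pf$per_node), c(15L, 10L))
  # overall equals the hand-computed total over the recorded states
  k <- 7L
  expect_equal(pf$overall[k],
               sum(tr$states[k, , 1]) / sum(tr$states[k, , ]))
  expect_equal(sort(unique(pf$by_role$role)), c("center", "side"))
})

test_that("recurrence detection finds the smallest matching lag", {
  s <- function(x) node_state(x, x)
  # constructed period-2 alternation
  buf <- list(s(1), s(5), s(1), s(5))
  expect_equal(metapopsim:::recurrence_lag(buf, 4L, s(1), 1e-6, 32L), 2L)
  # converged sequence: lag 1
  expect_equal(metapopsim:::recurrence_lag(buf, 4L, s(5), 1e-6, 32L), 1L)
  # nothing recurs
  expect_true(is.na(metapopsim:::recurrence_lag(buf, 4L, s(2), 1e-6, 32L)))
  # period longer than the search window is not claimed
  buf3 <- list(s(1), s(2), s(3))
  expect_true(is.na(metapopsim:::recurrence_lag(buf3, 3L, s(1), 1e-6, 2L)))
})

test_that("steady state converges below collapse and reports extinction
           above it", {
  topo <- isolated_nodes(1)
  ss <- steady_state(topo, protocol(D = 650, m = 0),
                     init = uniform_state(1, 0.05))
  expect_equal(ss$outcome, "converged")
  expect_equal(ss$period, 1L)
  # the converged state is a fixed point of the daily cycle
  op <- migration_matrix(topo, 0)
  nxt <- run_cycle(ss$state, op, protocol(D = 650, m = 0), 1L)
  expect_equal(nxt, ss$state, tolerance = 1e-5)

  ss_dead <- steady_state(topo, protocol(D = 1e5, m = 0),
                          init = uniform_state(1, 0.05))
  expect_equal(ss_dead$outcome, "extinct")
  expect_true(all(ss_dead$state == 0))
})

test_that("frequency dependence: starting fractions 0.05 and 0.9 converge to
           the same equilibrium within 1%", {
  topo <- isolated_nodes(1)
  proto <- protocol(D = 650, m = 0)
  f <- vapply(c(0.05, 0.9), function(f0) {
    producer_fraction(steady_state(topo, proto,
                                   init = uniform_state(1, f0))$state)
  }, numeric(1))
  expect_lt(abs(f[1] - f[2]) / f[2], 0.01)
})

test_that("denser protocols (lower D) carry fewer producers: equilibrium
           fraction is non-decreasing in D below collapse", {
  topo <- isolated_nodes(1)
  fr <- vapply(c(200, 400, 650, 900, 1100), function(D) {
    producer_fraction(steady_state(topo, protocol(D = D, m = 0),
                                   init = uniform_state(1, 0.1))$state)
  }, numeric(1))
  expect_true(all(diff(fr) >= -1e-9))
  expect_gt(fr[5], fr[1])
})

test_that("survival classification matches the full-horizon definition", {
  topo <- isolated_nodes(1)
  init <- equilibrate(topo, 0)
  expect_true(survives(topo, protocol(D = 650, m = 0, n_cycles = 200), init))
  expect_false(survives(topo, protocol(D = 1500, m = 0, n_cycles = 200),
                        init))
  # early fixed-point shortcut agrees with the exhaustive run
  expect_identical(
    survives(topo, protocol(D = 1200, m = 0, n_cycles = 400), init),
    survives(topo, protocol(D = 1200, m = 0, n_cycles = 400), init,
             converge_tol = 0))
})

test_that("phase diagram scans the grid and its m = 0 row equals isolated
           nodes", {
  topo <- star_topology(4)
  D_grid <- c(650, 1150, 1500)
  pd <- phase_diagram(topo, D_grid, m_grid = c(0, 0.6), n_cycles = 300)
  expect_equal(dim(pd$survival), c(2L, 3L))
  pd_iso <- phase_diagram(isolated_nodes(5), D_grid, m_grid = 0,
                          n_cycles = 300)
  expect_equal(pd$survival[1, ], pd_iso$survival[1, ])
  # survival is monotone in D on this grid: once lost it stays lost
  for (i in 1:2) expect_true(all(diff(pd$survival[i, ]) <= 0))
  df <- as.data.frame(pd)
  expect_equal(nrow(df), 6L)
  expect_equal(df$survives[df$D == 650 & df$m == 0.6], TRUE)
})

test_that("critical dilution is bracketed and equals isolated at m = 0", {
  topo <- isolated_nodes(1)
  cd <- critical_dilution(topo, m = 0, bracket = c(600, 2000), tol = 5e-3,
                          n_cycles = 400)
  expect_true(cd$D_survive < cd$D_star && cd$D_star < cd$D_collapse)
  expect_lt((cd$D_collapse - cd$D_survive) / cd$D_survive, 5.1e-3)
  init <- equilibrate(topo, 0)
  expect_true(survives(topo, protocol(D = cd$D_survive, m = 0,
                                      n_cycles = 400), init))
  expect_false(survives(topo, protocol(D = cd$D_collapse, m = 0,
                                       n_cycles = 400), init))
  # a star with m = 0 is dynamically a set of isolated nodes
  cd_star0 <- critical_dilution(star_topology(9), m = 0,
                                bracket = c(600, 2000), tol = 5e-3,
                                n_cycles = 400)
  expect_equal(cd_star0$D_star, cd$D_star, tolerance = 1e-12)
  expect_error(critical_dilution(topo, 0, bracket = c(1500, 2000),
                                 n_cycles = 300), "lower bracket")
})

test_that("max_shock finds the recovery/extinction boundary by bisection", {
  topo <- isolated_nodes(1)
  proto <- protocol(D = 750, m = 0, n_cycles = 100)
  ms <- max_shock(topo, proto, "dilution_shock", relax_cycles = 300)
  expect_equal(ms$method, "bisection")
  expect_gt(ms$max_magnitude, 1)         # a trivial shock always recovers
  expect_true(ms$mag_recover <= ms$max_magnitude &&
                ms$max_magnitude <= ms$mag_fail)
  # growth shocks, checked against a direct simulation oracle on both sides
  # of the boundary (dr = r is one cycle of pure dilution without growth)
  gs <- max_shock(topo, proto, "growth_shock", relax_cycles = 300)
  expect_true(gs$max_magnitude >= 0 && gs$max_magnitude <= proto$params$r)
  ss <- steady_state(topo, proto)
  outcome_at <- function(dr) {
    p <- protocol(D = 750, m = 0, n_cycles = 301,
                  perturbation = list(cycle = 1L, kind = "growth_shock",
                                      magnitude = dr))
    tr <- simulate_metapopulation(topo, p, ss$state)
    !tr$all_extinct &&
      abs(sum(tr$final) - sum(ss$state)) / sum(ss$state) < 0.05
  }
  expect_true(outcome_at(gs$mag_recover))
  expect_false(outcome_at(gs$mag_fail))
})

test_that("recovery threshold locates the basin boundary below equilibrium", {
  topo <- isolated_nodes(1)
  proto <- protocol(D = 750, m = 0, n_cycles = 100)
  rt <- recovery_threshold(topo, proto, relax_cycles = 300)
  expect_true(rt$s_star > 0 && rt$s_star < 1)
  expect_equal(rt$threshold_density, rt$s_star * rt$equilibrium_density)
  # states just above the boundary recover; just below, they collapse
  ss <- steady_state(topo, proto)
  relax <- protocol(D = 750, m = 0, n_cycles = 300)
  above <- simulate_metapopulation(topo, relax, ss$state * (rt$s_star * 1.2))
  below <- simulate_metapopulation(topo, relax, ss$state * (rt$s_star * 0.8))
  expect_false(above$all_extinct)
  expect_true(below$all_extinct)
})

test_that("calibration ranks constrained parameter candidates by fit", {
  got <- calibrate(targets = list(eq_fraction = 0.073),
                   c_grid = c(0.03, 0.07), ratio_grid = c(14 / 26, 1),
                   t_grow_grid = 22, n_cycles = 200,
                   D_bracket = c(300, 3000))
  expect_equal(nrow(got), 4L)
  expect_true(!is.unsorted(got$score))
  # the true constants sit at the top of the ranking
  expect_equal(got$c[1], 0.07)
  expect_equal(got$eps[1], 14)
  expect_error(calibrate(targets = list()), "targets")
})
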