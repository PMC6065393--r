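test_that("a cycle with D = 1, m = 0 and suppressed growth is the identity", {
  topo <- isolated_nodes(2)
  op <- migration_matrix(topo, 0)
  # a full-strength growth shock turns off growth for the cycle
  proto <- protocol(D = 1, m = 0, n_cycles = 1,
                    perturbation = list(cycle = 1L, kind = "growth_shock",
                                        magnitude = model_params()$r))
  s <- node_state(c(100, 5), c(900, 40))
  expect_equal(run_cycle(s, op, proto, cycle_index = 1L), s)
})

test_that("the daily cycle applies dilution, migration and growth in order", {
  topo <- star_topology(9)
  op <- migration_matrix(topo, 0.6)
  proto <- protocol(D = 650, m = 0.6, n_cycles = 1)
  s <- uniform_state(10, 0.1, 75000)
  out <- run_cycle(s, op, proto, 1L)
  # oracle: the same three steps composed from the primitive operations
  ref <- grow(migrate(s / 650, op), proto$params)
  expect_equal(out, ref)
})

test_that("perturbed cycles substitute D' = D*dD or r' = r - dr once", {
  topo <- isolated_nodes(1)
  op <- migration_matrix(topo, 0)
  base <- protocol(D = 650, m = 0, n_cycles = 3)
  shock <- protocol(D = 650, m = 0, n_cycles = 3,
                    perturbation = list(cycle = 2L, kind = "dilution_shock",
                                        magnitude = 4))
  s <- uniform_state(1, 0.1, 75000)
  # cycle 1 identical, cycle 2 equals an unperturbed cycle at D = 2600
  expect_equal(run_cycle(s, op, shock, 1L), run_cycle(s, op, base, 1L))
  harsh <- protocol(D = 2600, m = 0, n_cycles = 1)
  expect_equal(run_cycle(s, op, shock, 2L), run_cycle(s, op, harsh, 1L))

  gshock <- protocol(D = 650, m = 0, n_cycles = 3,
                     perturbation = list(cycle = 1L, kind = "growth_shock",
                                         magnitude = 0.2))
  slow <- protocol(D = 650, m = 0, n_cycles = 1,
                   params = model_params(r = 0.3))
  expect_equal(run_cycle(s, op, gshock, 1L), run_cycle(s, op, slow, 1L))
  expect_error(protocol(D = 650, m = 0,
                        perturbation = list(cycle = 1, kind = "dilution_shock",
                                            magnitude = 0.5)), "dD")
})

test_that("simulation is deterministic and records end-of-growth states", {
  topo <- star_topology(9)
  proto <- protocol(D = 650, m = 0.6, n_cycles = 30)
  init <- uniform_state(10, 0.1, 75000)
  tr1 <- simulate_metapopulation(topo, proto, init)
  tr2 <- simulate_metapopulation(topo, proto, init)
  expect_identical(tr1$states, tr2$states)       # bitwise reproducible
  expect_equal(dim(tr1$states), c(30L, 10L, 2L))
  expect_equal(tr1$final, tr1$states[30, , ], ignore_attr = TRUE)
  df <- as.data.frame(tr1)
  expect_equal(nrow(df), 300L)
  expect_equal(unique(df$role), c("center", "side"))
  expect_equal(df$total, df$Np + df$Nnp)
})

test_that("an all-extinct start stays extinct and is flagged immediately", {
  topo <- isolated_nodes(3)
  tr <- simulate_metapopulation(topo, protocol(D = 650, m = 0, n_cycles = 10),
                                node_state(rep(0, 3), rep(0, 3)))
  expect_true(tr$all_extinct)
  expect_equal(tr$cycles_run, 0L)
  expect_true(all(tr$final == 0))
})

test_that("extinction below the cutoff is absorbing", {
  topo <- isolated_nodes(1)
  # huge dilution drives the node under the cutoff within a few cycles
  proto <- protocol(D = 1e5, m = 0, n_cycles = 50)
  tr <- simulate_metapopulation(topo, proto, uniform_state(1, 0.1, 75000))
  expect_true(tr$all_extinct)
  expect_lt(tr$cycles_run, 50L)
  k <- tr$extinct_at[1]
  expect_true(all(tr$states[k:tr$cycles_run, 1, ] == 0))
})

test_that("fully connected and isolated networks overlap exactly from a
           uniform start", {
  init <- uniform_state(10, 0.1, 75000)
  proto <- protocol(D = 650, m = 0.6, n_cycles = 40)
  proto0 <- protocol(D = 650, m = 0, n_cycles = 40)
  tr_fc <- simulate_metapopulation(fully_connected(10), proto, init)
  tr_iso <- simulate_metapopulation(isolated_nodes(10), proto0, init)
  expect_equal(tr_fc$states, tr_iso$states, tolerance = 1e-12)
})

test_that("a producer-only metapopulation never gains non-producers", {
  topo <- star_topology(9)
  proto <- protocol(D = 650, m = 0.6, n_cycles = 25)
  tr <- simulate_metapopulation(topo, proto,
                                node_state(rep(7500, 10), rep(0, 10)))
  expect_true(all(tr$states[, , 2L] == 0))
  expect_false(tr$all_extinct)
})

test_that("trajectories export to tidy CSV", {
  path <- withr::local_tempfile(fileext = ".csv")
  tr <- simulate_metapopulation(star_topology(2),
                                protocol(D = 650, m = 0.6, n_cycles = 5),
                                uniform_state(3, 0.1, 75000))
  write_trajectory_csv(tr, path)
  back <- utils::read.csv(path)
  expect_equal(names(back),
               c("cycle", "node", "role", "Np", "Nnp", "total", "fraction"))
  expect_equal(nrow(back), 15L)
  expect_equal(back$Np, as.data.frame(tr)$Np, tolerance = 1e-12)
})
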