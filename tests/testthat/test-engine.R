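ff <- ff_params()
kT <- ff$kB * ff$temperature

test_that("same seed gives a bit-identical trajectory; different seed does not", {
  topo <- assemble_system(5, 0)
  spec <- system_spec(5, lipid_concentration_mM = 50)
  packed <- random_pack(spec, topology = topo, seed = 2)
  st <- minimize(packed$state, topo, ff, max_steps = 500)
  cfg <- engine_config(seed = 77, snapshot_every = 250)
  t1 <- run_langevin(st, topo, ff, cfg, 1000)
  t2 <- run_langevin(st, topo, ff, cfg, 1000)
  expect_identical(t1$frames[[4]]$positions, t2$frames[[4]]$positions)
  expect_identical(t1$final_state$velocities, t2$final_state$velocities)
  cfg$seed <- 78L
  t3 <- run_langevin(st, topo, ff, cfg, 1000)
  expect_false(identical(t1$final_state$positions, t3$final_state$positions))
})

test_that("minimization reduces energy, separates overlaps, and is a fixed point", {
  # two overlapping beads
  topo <- free_bead_topology(2)
  st <- new_system_state(rbind(c(5, 5, 5), c(5.2, 5, 5)), 10)
  stm <- minimize(st, topo, ff, max_steps = 2000, ftol = 1e-3)
  sep <- sqrt(sum((stm$positions[1, ] - stm$positions[2, ])^2))
  expect_gte(sep + 1e-4, 2^(1/6) * ff$b_HH)
  expect_lte(attr(stm, "energy"), total_energy_forces(st, topo, ff)$energy)
  # already-minimized state: energy unchanged
  stm2 <- minimize(stm, topo, ff, max_steps = 500, ftol = 1e-3)
  expect_lt(abs(attr(stm2, "energy") - attr(stm, "energy")), 1e-8)

  # overlap-packed random lipid box relaxes to finite energy without
  # FENE overextension
  spec <- system_spec(10, lipid_concentration_mM = 100)
  packed <- random_pack(spec, seed = 5, floor_nm = 0.3)
  stm3 <- minimize(packed$state, packed$topology, ff)
  expect_true(is.finite(attr(stm3, "energy")))
  dvec <- stm3$positions[packed$topology$fene_bonds$i, ] -
    stm3$positions[packed$topology$fene_bonds$j, ]
  dvec <- dvec - stm3$box_edge * round(dvec / stm3$box_edge)
  expect_true(all(sqrt(rowSums(dvec^2)) < ff$r_inf))
})

test_that("ramped equilibration runs its stage ladder and thermalizes", {
  spec <- system_spec(30, lipid_concentration_mM = 20)
  packed <- random_pack(spec, seed = 8)
  st <- minimize(packed$state, packed$topology, ff)
  eq <- equilibrate(st, packed$topology, ff, seed = 8, stage_steps = 2000)
  expect_equal(attr(eq, "stage_dt_fs"), c(0.01, 0.1, 1, 10))
  # same seed, same result
  eq2 <- equilibrate(st, packed$topology, ff, seed = 8, stage_steps = 2000)
  expect_identical(eq$positions, eq2$positions)
})

test_that("kinetic temperature settles near 310 K on a 1000-bead system", {
  # 1000 free beads: temperature statistics depend only on the thermostat
  n <- 1000
  topo <- free_bead_topology(n)
  # overlap-free cubic lattice start
  g <- as.matrix(expand.grid(x = 1:10, y = 1:10, z = 1:10)) * 3 - 1.5
  st <- new_system_state(g, 30)
  cfg <- engine_config(seed = 21, snapshot_every = 100)
  tr <- run_langevin(st, topo, ff, cfg, 5000)
  temps <- 2 * tr$kinetic_energy / (3 * n * ff$kB)
  tbar <- mean(temps[-(1:10)])
  expect_lt(abs(tbar - 310) / 310, 0.05)
})

test_that("velocity-component variance matches Maxwell-Boltzmann within 3 SE", {
  topo <- free_bead_topology(1)
  st <- new_system_state(matrix(3, 1, 3), 6)
  cfg <- engine_config(seed = 42, snapshot_every = 200)
  tr <- run_langevin(st, topo, ff, cfg, 1e6)
  # snapshots 200 steps apart are decorrelated (gamma*dt*200 ~ 2)
  v2 <- 2 * tr$kinetic_energy / cfg$mass_amu  # sum over 3 components of v^2
  nsamp <- 3 * length(v2)
  est <- mean(v2) / 3
  se <- sqrt(2 / nsamp) * kT / cfg$mass_amu
  expect_lt(abs(est - kT / cfg$mass_amu), 3 * se)
})

test_that("elastic-dimer potential energy matches the radial Boltzmann oracle within 3 SE", {
  r0 <- 0.57
  topo <- elastic_dimer_topology(r0)
  st <- new_system_state(rbind(c(3, 3, 3), c(3 + r0, 3, 3)), 6)
  cfg <- engine_config(seed = 13, snapshot_every = 500)
  tr <- run_langevin(st, topo, ff, cfg, 1e6)
  drop <- 50  # discard thermalization
  pe <- tr$potential_energy[-(1:drop)]
  expected <- harmonic_dimer_mean_V(ff$k_elastic, r0, kT)
  se <- sd(pe) / sqrt(length(pe))
  expect_lt(abs(mean(pe) - expected), 3 * se + 1e-4)
  # and the naive equipartition value kT/2 is close to the oracle
  expect_lt(abs(expected - kT / 2), 0.05 * kT)
})

test_that("with the thermostat off the integrator conserves energy", {
  topo <- assemble_system(2, 0)
  lip <- build_lipid()
  pos <- rbind(sweep(lip$reference_coords, 2, c(2, 2, 2), "+"),
               sweep(lip$reference_coords, 2, c(3.2, 2, 2), "+"))
  st <- minimize(new_system_state(pos, 8), topo, ff, max_steps = 2000,
                 ftol = 1e-4)
  set.seed(9)
  st$velocities <- maxwell_velocities(6, 310, 100)
  cfg <- engine_config(timestep_fs = 0.1, friction_ps = 0, seed = 1,
                       snapshot_every = 100)
  tr <- run_langevin(st, topo, ff, cfg, 1e4)
  etot <- tr$potential_energy + tr$kinetic_energy
  expect_lt(max(abs(etot - etot[1])), 1e-4 * ff$epsilon)
})

test_that("FENE overextension during dynamics is a fatal diagnostic", {
  topo <- assemble_system(1, 0)
  st <- new_system_state(sweep(topo$reference_coords, 2, c(3, 3, 3), "+"), 6)
  # absurd velocities rip the bond apart
  st$velocities <- matrix(c(5, 0, 0, -5, 0, 0, 0, 0, 0), 3, 3, byrow = TRUE)
  cfg <- engine_config(timestep_fs = 10, friction_ps = 0, seed = 1,
                       snapshot_every = 0)
  expect_error(run_langevin(st, topo, ff, cfg, 100), "overextended")
})

test_that("neighbor list is a superset of interacting pairs and sees periodic images", {
  cutoff <- 1.3
  st <- new_system_state(rbind(c(1, 1, 1), c(1 + 0.99 * cutoff, 1, 1)), 10)
  nl <- neighbor_list(st, cutoff)
  expect_equal(nrow(nl), 1)
  # pair across the boundary: separation along x is box - 0.5*cutoff
  st2 <- new_system_state(rbind(c(0.2, 5, 5), c(10 - 0.5 * cutoff + 0.2, 5, 5)),
                          10)
  nl2 <- neighbor_list(st2, cutoff)
  expect_equal(nrow(nl2), 1)
  # 100 random beads: candidate set contains every within-cutoff pair
  set.seed(33)
  pos <- matrix(runif(300, 0, 8), ncol = 3)
  st3 <- new_system_state(pos, 8)
  nl3 <- neighbor_list(st3, cutoff)
  key <- paste(nl3[, 1], nl3[, 2])
  d <- min_image_dist(pos, 8)
  for (i in 1:99) for (j in (i + 1):100)
    if (d[i, j] <= cutoff) expect_true(paste(i, j) %in% key)
  # small box falls back to all-pairs with a warning
  st4 <- new_system_state(matrix(runif(30, 0, 3), ncol = 3), 3)
  expect_warning(neighbor_list(st4, 1.3), "all-pairs")
})
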