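test_that("screened Coulomb energy matches the closed form", {
  # frozen hand evaluation: 138.935458 * exp(-1) / 15
  expect_equal(screened_coulomb_energy(1, 1, 1, debye_length = 1,
                                       dielectric = 15),
               3.40743324319589, tolerance = 1e-12)
  expect_equal(screened_coulomb_energy(0, 5, 0.7), 0)
  expect_equal(screened_coulomb_energy(2, -3, 0.8),
               screened_coulomb_energy(-3, 2, 0.8))
  expect_error(screened_coulomb_energy(1, 1, 0), "r must be")
})

test_that("group interaction energy matches the brute-force oracle", {
  set.seed(7)
  params <- sim_params()
  for (rep in 1:3) {
    n <- 20
    coords <- matrix(runif(3 * n, 0, 4), ncol = 3)
    q <- sample(c(-5, 0, 1, 3), n, replace = TRUE)
    top <- bead_topology(data.frame(
      bead_id = 0:(n - 1L), bead_name = "X", residue_id = 1:n,
      residue_name = "GLY", molecule_id = 1:n,
      molecule_class = "protein", charge = q, is_phosphate = FALSE,
      leaflet = NA_character_))
    fr <- frame(coords, c(5, 5, 5))
    ia <- 0:9; ib <- 10:19
    e <- total_interaction_energy(top, fr, ia, ib, params)
    o <- oracle_energy(coords, q, ia, ib, fr$box, params)
    expect_equal(e$electrostatic, o$electrostatic, tolerance = 1e-10)
    expect_equal(e$van_der_waals, o$van_der_waals, tolerance = 1e-10)
    # symmetry under group swap
    e2 <- total_interaction_energy(top, fr, ib, ia, params)
    expect_equal(e$electrostatic, e2$electrostatic, tolerance = 1e-12)
    expect_equal(e$van_der_waals, e2$van_der_waals, tolerance = 1e-12)
  }
  # far-separated groups have (exactly, by truncation) zero interaction
  far <- frame(rbind(c(1, 1, 1), c(1, 1, 9)), c(20, 20, 20))
  ftop <- bead_topology(data.frame(
    bead_id = 0:1, bead_name = "X", residue_id = 1:2, residue_name = "GLY",
    molecule_id = 1:2, molecule_class = "protein", charge = c(1, -5),
    is_phosphate = FALSE, leaflet = NA_character_))
  ef <- total_interaction_energy(ftop, far, 0, 1, sim_params())
  expect_equal(ef$electrostatic, 0)
  expect_equal(ef$van_der_waals, 0)
  # single close pair decomposes into the two closed forms
  near <- frame(rbind(c(1, 1, 1), c(1, 1, 1.6)), c(20, 20, 20))
  en <- total_interaction_energy(ftop, near, 0, 1, sim_params())
  p <- sim_params()
  expect_equal(en$electrostatic,
               screened_coulomb_energy(1, -5, 0.6, p$debye_length,
                                       p$dielectric), tolerance = 1e-12)
  expect_error(total_interaction_energy(ftop, near, 0:1, 1), "disjoint")
})

test_that("zero temperature and zero charges leave a separated system fixed", {
  cfg <- toy_config(seed = 3, "system.protein.basic_charge" = 0,
                    "simulation.temperature" = 0)
  b <- run_build(cfg)
  p <- pipbind:::config_sim_params(cfg)
  f2 <- bd_step(b$system$topology, b$system$frame, params = p)
  expect_equal(f2$coords, b$system$frame$coords, tolerance = 1e-12)
  expect_equal(f2$time, b$system$frame$time + p$timestep)
})

test_that("the protein moves as an exactly rigid body", {
  cfg <- toy_config(seed = 2, "simulation.n_steps" = 800)
  b <- run_build(cfg)
  traj <- bd_run(b$system$topology, b$system$frame,
                 pipbind:::config_sim_params(cfg), elastic = b$elastic)
  prows <- protein_beads(b$system$topology) + 1L
  d0 <- dist(b$system$frame$coords[prows, ])
  dT <- dist(traj$frames[[length(traj$frames)]]$coords[prows, ])
  expect_equal(as.numeric(dT), as.numeric(d0), tolerance = 1e-6)
  # elastic-network rest lengths audit the same rigidity
  net <- b$elastic
  fr <- traj$frames[[length(traj$frames)]]
  dd <- sqrt(rowSums((fr$coords[net$i + 1L, ] - fr$coords[net$j + 1L, ])^2))
  expect_equal(dd, net$rest_length, tolerance = 1e-6)
})

test_that("free lipid head beads obey 2-D diffusion statistics", {
  # bilayer only, no protein: heads are free in x-y under pure noise
  cfg <- toy_config(seed = 6, "simulation.n_steps" = 400,
                    "simulation.save_interval" = 1)
  sy <- cfg$system
  b <- build_bilayer(sy$n_per_leaflet, sy$area_per_lipid, sy$z_separation,
                     sy$box_z, z_center = sy$z_center)
  p <- pipbind:::config_sim_params(cfg)
  traj <- bd_run(b$topology, b$frame, p)
  # unwrap frame-to-frame displacements through the periodic boundary
  nf <- length(traj$frames)
  box <- traj$frames[[1]]$box
  disp <- 0
  for (k in 2:nf) {
    d <- min_image(traj$frames[[k]]$coords - traj$frames[[k - 1]]$coords, box)
    disp <- disp + d
  }
  t_tot <- traj$frames[[nf]]$time - traj$frames[[1]]$time
  msd_xy <- mean(rowSums(disp[, 1:2]^2))
  D <- 0.0083144621 * p$temperature / p$friction[["lipid"]]
  # ~10% sampling error from 98 beads; 3 sigma band
  expect_equal(msd_xy, 4 * D * t_tot, tolerance = 0.3)
  # mean displacement ~ 0 (no drift)
  expect_lt(abs(mean(disp[, 1])), 3 * sqrt(2 * D * t_tot / nrow(disp)))
})

test_that("trajectories are reproducible and respect save bookkeeping", {
  cfg <- toy_config(seed = 5, "simulation.n_steps" = 300)
  b <- run_build(cfg)
  p <- pipbind:::config_sim_params(cfg)
  t1 <- bd_run(b$system$topology, b$system$frame, p)
  t2 <- bd_run(b$system$topology, b$system$frame, p)
  expect_identical(t1, t2)
  times <- vapply(t1$frames, function(f) f$time, numeric(1))
  expect_equal(times, seq(0, 300 * p$timestep, by = p$save_interval * p$timestep))

  p0 <- p; p0$n_steps <- 0L
  t0 <- bd_run(b$system$topology, b$system$frame, p0)
  expect_length(t0$frames, 1)
  expect_equal(t0$frames[[1]]$coords, b$system$frame$coords)
})

test_that("binding under the packaged conditions is transient and dynamic", {
  r <- std_run(1)
  tl <- r$timeline
  expect_gt(mean(tl$bound), 0.05)          # bound states occur
  expect_gt(mean(!tl$bound), 0.05)         # ... and so do unbound states
  expect_gte(sum(diff(tl$bound) != 0), 4)  # multiple association/dissociation
  expect_gte(max(tl$n_P), 2)               # simultaneous multi-PIP2 contact
  expect_true(all(tl$n_P <= n_molecules(r$trajectory$topology, "PIP2")))
})
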