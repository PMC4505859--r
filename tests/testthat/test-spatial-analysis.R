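test_that("RDF matches the longhand per-pair oracle", {
  set.seed(21)
  n <- 24
  frames <- lapply(1:3, function(k) {
    frame(matrix(runif(3 * n, 0, 6), ncol = 3), c(6, 6, 6), k - 1)
  })
  top <- bead_topology(data.frame(
    bead_id = 0:(n - 1L), bead_name = "NA+", residue_id = 1:n,
    residue_name = "ION", molecule_id = 1:n, molecule_class = "ion",
    charge = 1, is_phosphate = FALSE, leaflet = NA_character_))
  tr <- trajectory(top, frames)
  for (mode in c("3d", "lateral")) {
    prof <- rdf(tr, 0:(n - 1L), 0:(n - 1L), r_max = 2.5, n_bins = 10,
                mode = mode)
    expect_equal(prof$g,
                 oracle_rdf(tr, 0:(n - 1L), 0:(n - 1L), 2.5, 10, mode),
                 tolerance = 1e-10)
  }
  # disjoint reference/target as well
  prof2 <- rdf(tr, 0:9, 10:(n - 1L), r_max = 2, n_bins = 8)
  expect_equal(prof2$g, oracle_rdf(tr, 0:9, 10:(n - 1L), 2, 8, "3d"),
               tolerance = 1e-10)
})

test_that("RDF of a uniform ideal-gas target is flat at 1", {
  set.seed(31)
  n <- 150
  frames <- lapply(1:40, function(k) {
    frame(matrix(runif(3 * n, 0, 8), ncol = 3), c(8, 8, 8), k - 1)
  })
  top <- bead_topology(data.frame(
    bead_id = 0:(n - 1L), bead_name = "NA+", residue_id = 1:n,
    residue_name = "ION", molecule_id = 1:n, molecule_class = "ion",
    charge = 0, is_phosphate = FALSE, leaflet = NA_character_))
  tr <- trajectory(top, frames)
  prof <- rdf(tr, 0:(n - 1L), 0:(n - 1L), r_max = 3.5, n_bins = 14)
  # identical ref/target sets double-count each pair, so bin variance is
  # twice Poisson: band is 3.5 * sqrt(2 / expected count)
  expected <- prof$counts / pmax(prof$g, 1e-12)
  bins <- which(prof$r > 0.5)   # beyond the (empty-ish) core bins
  expect_true(all(abs(prof$g[bins] - 1) < 3.5 * sqrt(2 / expected[bins])))
  expect_lt(abs(mean(prof$g[bins]) - 1), 0.02)
})

test_that("RDF input validation guards minimum-image validity", {
  tr <- static_traj(list(rbind(c(1, 1, 1), c(1, 1, 2))), 1, 1,
                    box = c(6, 6, 6))
  expect_error(rdf(tr, 0, 1, r_max = 4), "minimum image")
  # two fixed beads at 1 nm: single occupied bin at r = 1
  prof <- rdf(tr, 0, 1, r_max = 2, n_bins = 10)
  expect_equal(which(prof$counts > 0), 5L)
})

test_that("principal axis matches covariance eigenanalysis and conventions", {
  # beads along x: axis is (1, 0, 0) after sign fixing
  line <- frame(cbind(seq(0, 2, length.out = 11), 0, 0) +
                  matrix(rep(c(1, 1, 1), each = 11), ncol = 3),
                c(10, 10, 10))
  v <- principal_axis(line, 0:10)
  expect_equal(abs(as.numeric(v)), c(1, 0, 0), tolerance = 1e-12)
  expect_gte(v[1], 0)

  # random cloud: agrees with a direct eigendecomposition of the covariance
  set.seed(8)
  cloud <- matrix(rnorm(60, sd = c(0.4, 1.5, 0.2)), ncol = 3, byrow = TRUE)
  fr <- frame(cloud + 5, c(20, 20, 20))
  v2 <- principal_axis(fr, 0:19)
  ev <- eigen(cov(cloud + 5))$vectors[, 1]
  if (ev[3] < 0) ev <- -ev
  expect_equal(as.numeric(v2), as.numeric(ev), tolerance = 1e-10)

  # equivariance: rotating the cloud rotates the axis (up to sign)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  frR <- frame(cloud %*% t(R) + 5, c(20, 20, 20))
  vR <- principal_axis(frR, 0:19)
  expect_equal(abs(sum(vR * (R %*% as.numeric(v2)))), 1, tolerance = 1e-9)

  # degenerate cloud is flagged
  coincident <- frame(matrix(1, nrow = 4, ncol = 3), c(10, 10, 10))
  vd <- principal_axis(coincident, 0:3)
  expect_true(attr(vd, "degenerate"))
})

test_that("orientation histogram is a probability distribution over V_z", {
  p <- build_toy_protein(30, 1.2, seed = 3)
  # fixed rigid pose in every frame: a single occupied bin
  tr <- trajectory(p$topology,
                   lapply(0:4, function(k) frame(p$frame$coords + 2,
                                                 p$frame$box, k)))
  h <- orientation_distribution(tr, protein_beads(p$topology), n_bins = 20)
  expect_equal(sum(h$p), 1)
  expect_equal(sum(h$p > 0), 1L)

  # folded variant lives in [0, 1]
  hf <- orientation_distribution(tr, protein_beads(p$topology), n_bins = 20,
                                 variant = "folded")
  expect_true(all(hf$v_z >= 0))
  expect_equal(sum(hf$p), 1)
})

test_that("isotropically tumbling bodies give a flat V_z distribution", {
  p <- build_toy_protein(40, 1.5, seed = 2)
  set.seed(17)
  frames <- lapply(1:600, function(k) {
    R <- pipbind:::random_rotation()
    frame(p$frame$coords %*% t(R) + 5, c(12, 12, 12), k - 1)
  })
  tr <- trajectory(p$topology, frames)
  h <- orientation_distribution(tr, protein_beads(p$topology), n_bins = 10)
  chi <- suppressWarnings(stats::chisq.test(h$p * length(h$v_z)))
  expect_gt(chi$p.value, 0.01)
})

test_that("COM axis points between residue-set centroids", {
  tr <- static_traj(list(rbind(c(2, 2, 2), c(2, 2, 5), c(5, 5, 5))), 2, 1,
                    box = c(10, 10, 10))
  v <- com_axis(tr$frames[[1]], tr$topology, 1, 2)
  expect_equal(as.numeric(v), c(0, 0, 1))
  expect_equal(as.numeric(com_axis(tr$frames[[1]], tr$topology, 2, 1)),
               c(0, 0, -1))

  # multi-residue unions: hand-computed centroid difference
  tr2 <- static_traj(list(rbind(c(1, 1, 1), c(3, 1, 1), c(2, 4, 1),
                                c(2, 2, 6), c(9, 9, 9))), 4, 1,
                     box = c(20, 20, 20))
  v2 <- com_axis(tr2$frames[[1]], tr2$topology, c(1, 2), c(3, 4))
  expected <- c(mean(c(2, 2)) - mean(c(1, 3)),
                mean(c(4, 2)) - mean(c(1, 1)),
                mean(c(1, 6)) - mean(c(1, 1)))
  expect_equal(as.numeric(v2), expected / sqrt(sum(expected^2)),
               tolerance = 1e-12)
})

test_that("pose classification labels site contacts of bound frames", {
  sI <- site_definition("Site I", c(1, 2))
  sII <- site_definition("Site II", c(3))
  base <- rbind(c(5, 5, 5.4),    # residue 1
                c(5, 7, 7),      # residue 2
                c(7, 5, 5.4),    # residue 3
                c(7, 7, 7))      # residue 4 (in neither site)
  pip1 <- c(5, 5, 5)             # under residue 1
  pip2_ <- c(7, 5, 5)            # under residue 3
  far <- c(1, 1, 1)

  tr <- static_traj(list(rbind(base, pip1, far)), 4, 2)
  expect_equal(classify_pose(tr$frames[[1]], tr$topology, sI, sII), "I_only")

  tr2 <- static_traj(list(rbind(base, pip1, pip2_)), 4, 2)
  expect_equal(classify_pose(tr2$frames[[1]], tr2$topology, sI, sII), "both")

  tr3 <- static_traj(list(rbind(base, far, pip2_)), 4, 2)
  expect_equal(classify_pose(tr3$frames[[1]], tr3$topology, sI, sII),
               "II_only")

  # bound only through residue 4: neither site
  base4 <- base; base4[1, ] <- c(1, 9, 9); base4[3, ] <- c(9, 1, 9)
  pip4 <- c(7, 7, 6.55)
  tr4 <- static_traj(list(rbind(base4, pip4, far)), 4, 2)
  expect_equal(classify_pose(tr4$frames[[1]], tr4$topology, sI, sII),
               "neither")

  # unbound frame is a classification error
  allfar <- sweep(base, 2, c(0, 0, 4), "+")
  tr5 <- static_traj(list(rbind(allfar, pip1, far)), 4, 2)
  expect_error(classify_pose(tr5$frames[[1]], tr5$topology, sI, sII),
               "unbound")
  # overlapping sites are rejected
  expect_error(classify_pose(tr$frames[[1]], tr$topology, sI,
                             site_definition("x", c(2, 5))), "overlap")
})

test_that("pose classification is invariant to box translation", {
  sI <- site_definition("Site I", c(1, 2))
  sII <- site_definition("Site II", c(3))
  base <- rbind(c(5, 5, 5.4), c(5, 7, 7), c(7, 5, 5.4), c(7, 7, 7))
  pip <- rbind(c(5, 5, 5), c(7, 5, 5))
  tr <- static_traj(list(rbind(base, pip)), 4, 2)
  lab0 <- classify_pose(tr$frames[[1]], tr$topology, sI, sII)
  for (shift in list(c(3, 0, 0), c(0, -4, 2), c(9.5, 9.5, 9.5))) {
    coords <- sweep(rbind(base, pip), 2, shift, "+")
    trS <- static_traj(list(coords), 4, 2)
    expect_equal(classify_pose(trS$frames[[1]], trS$topology, sI, sII), lab0)
  }
})

test_that("pose percentages partition bound frames", {
  r <- std_run(1)
  po <- aggregate_poses(r$timeline)
  expect_equal(sum(po$pct), 100, tolerance = 1e-9)
  expect_setequal(po$pose, c("I_only", "II_only", "both", "neither"))

  # all-I_only timeline
  sI <- site_definition("Site I", 1)
  sII <- site_definition("Site II", 2)
  base <- rbind(c(5, 5, 5.4), c(5, 8, 8))
  tr <- static_traj(rep(list(rbind(base, c(5, 5, 5))), 3), 2, 1)
  tl <- binding_timeline(tr, sites = list(sI, sII))
  p1 <- aggregate_poses(tl)
  expect_equal(p1$pct, c(100, 0, 0, 0))

  # empty (never bound) case is flagged, not NaN
  trn <- static_traj(list(rbind(sweep(base, 2, c(0, 0, 3), "+"),
                                c(5, 5, 5))), 2, 1)
  pe <- aggregate_poses(binding_timeline(trn, sites = list(sI, sII)))
  expect_true(attr(pe, "empty"))
})
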