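test_that("minimal distance uses the minimum-image convention", {
  tr <- static_traj(list(rbind(c(0, 0, 0), c(0, 0, 1))), 1, 1)
  fr <- tr$frames[[1]]
  expect_equal(min_distance(fr, tr$topology, 0, 1), 1.0)

  wrap <- static_traj(list(rbind(c(0, 0, 0.2), c(0, 0, 9.9))), 1, 1)
  expect_equal(min_distance(wrap$frames[[1]], wrap$topology, 0, 1), 0.3,
               tolerance = 1e-12)
  expect_error(min_distance(fr, tr$topology, integer(0), 1), "nonempty")
})

test_that("minimal distance agrees with the brute-force double loop", {
  set.seed(11)
  for (rep in 1:3) {
    a <- matrix(runif(150, 0, 12), ncol = 3)
    b <- matrix(runif(150, 0, 12), ncol = 3)
    box <- c(12, 12, 12)
    tr <- static_traj(list(rbind(a, b)), 50, 50, box = box)
    got <- min_distance(tr$frames[[1]], tr$topology, 0:49, 50:99)
    expect_equal(got, oracle_min_distance(a, b, box), tolerance = 1e-10)
  }
})

test_that("the binding criterion is strictly less-than the cutoff", {
  # one protein bead at the origin; one phosphate at 0.51, then exactly
  # 0.52, then far (origin-based so the separations are exact doubles)
  mk <- function(d) rbind(c(0, 0, 0), c(0, 0, d))
  tr <- static_traj(list(mk(0.51), mk(0.52), mk(3)), 1, 1)
  tl <- binding_timeline(tr)
  expect_equal(tl$min_dist, c(0.51, 0.52, 3))
  expect_equal(tl$bound, c(TRUE, FALSE, FALSE))
  expect_equal(tl$n_P, c(1L, 0L, 0L))
})

test_that("n_P counts distinct PIP2 molecules within the cutoff", {
  # 3 PIP2 within cutoff, 30 beyond
  prot <- c(5, 5, 5)
  close <- t(sapply(1:3, function(k) c(5 + 0.4 * cos(k), 5 + 0.4 * sin(k), 5)))
  far <- cbind(runif(30, 0, 10), runif(30, 0, 10), rep(9, 30))
  tr <- static_traj(list(rbind(prot, close, far)), 1, 33)
  tl <- binding_timeline(tr)
  expect_equal(tl$n_P, 3L)
  expect_true(tl$bound)
})

test_that("binding fraction and bound-distance summaries behave", {
  mk <- function(d) rbind(c(5, 5, 5), c(5, 5, 5 + d))
  tr <- static_traj(as.list(rep(list(mk(0.4), mk(2)), 5)), 1, 1)
  tl <- binding_timeline(tr)
  expect_equal(binding_fraction(tl), 50.0)

  tr2 <- static_traj(list(mk(0.4), mk(0.5)), 1, 1)
  tl2 <- binding_timeline(tr2)
  expect_equal(mean_bound_distance(tl2)$mean, 0.45, tolerance = 1e-12)
  expect_lte(mean_bound_distance(tl2)$mean, 0.52)

  tr3 <- static_traj(list(mk(0.5), mk(0.5)), 1, 1)
  expect_equal(mean_bound_distance(binding_timeline(tr3)),
               list(mean = 0.5, sd = 0))

  never <- static_traj(list(mk(2), mk(2)), 1, 1)
  mbd <- mean_bound_distance(binding_timeline(never))
  expect_true(is.na(mbd$mean))
  expect_true(attr(mbd, "no_bound_frames"))
})

test_that("first binding time is the earliest bound frame or NA", {
  mk <- function(d) rbind(c(5, 5, 5), c(5, 5, 5 + d))
  bound0 <- static_traj(list(mk(0.3), mk(2)), 1, 1, times = c(0, 1))
  expect_equal(first_binding_time(binding_timeline(bound0)), 0)
  late <- static_traj(list(mk(2), mk(2), mk(0.3)), 1, 1, times = c(0, 1, 2))
  expect_equal(first_binding_time(binding_timeline(late)), 2)
  never <- static_traj(list(mk(2)), 1, 1)
  expect_true(is.na(first_binding_time(binding_timeline(never))))
})

test_that("stoichiometry classes partition bound frames", {
  prot <- c(5, 5, 5)
  pip_at <- function(k) {
    # k molecules within cutoff, rest far
    ang <- seq_len(5) * 2.39
    r <- ifelse(seq_len(5) <= k, 0.42, 4)
    cbind(5 + r * cos(ang), 5 + r * sin(ang), 5)
  }
  frames <- lapply(c(1, 1, 2, 3, 5, 0), function(k) rbind(prot, pip_at(k)))
  tr <- static_traj(frames, 1, 5)
  tl <- binding_timeline(tr)
  sd_ <- stoichiometry_distribution(tl, max_n = 6)
  expect_equal(sum(sd_$pct), 100, tolerance = 1e-9)
  expect_equal(sd_$pct[sd_$n_P == "1"], 40)   # 2 of 5 bound frames
  expect_equal(sd_$pct[sd_$n_P == "4-6"], 20)
  expect_equal(attr(sd_, "n_bound"), 5L)

  all1 <- static_traj(lapply(1:4, function(i) rbind(prot, pip_at(1))), 1, 5)
  s1 <- stoichiometry_distribution(binding_timeline(all1))
  expect_equal(s1$pct, c(100, 0, 0, 0))

  unbound <- static_traj(list(rbind(prot, pip_at(0))), 1, 5)
  se <- stoichiometry_distribution(binding_timeline(unbound))
  expect_true(attr(se, "empty"))
  expect_equal(nrow(se), 0)
  expect_false(any(is.nan(se$pct)))
})

test_that("residue occupancies x_i = n_i / N with frame-count convention", {
  # 3-residue protein glued so only residue 2 is ever in range
  prot <- rbind(c(5, 5, 6.5), c(5, 5, 5.4), c(5, 6, 6.5))
  pip <- c(5, 5, 5)
  tr <- static_traj(rep(list(rbind(prot, pip)), 4), 3, 1)
  tab <- residue_contact_fraction(tr)
  expect_equal(attr(tab, "N"), 4)
  expect_equal(tab$x_i, c(0, 1, 0))
  expect_equal(tab$n_i, c(0L, 4L, 0L))
  expect_equal(tab$x_i * attr(tab, "N"), tab$n_i)

  # never-bound trajectory: N = 0 is flagged, x_i undefined
  farp <- sweep(prot, 2, c(0, 0, 3), "+")
  tr0 <- static_traj(rep(list(rbind(farp, pip)), 2), 3, 1)
  tab0 <- residue_contact_fraction(tr0)
  expect_true(attr(tab0, "undefined"))
  expect_true(all(is.na(tab0$x_i)))
})

test_that("x_i is invariant to frame-order permutation", {
  r <- quick_run(seed = 4, n_steps = 1500)
  tab <- residue_contact_fraction(r)
  set.seed(1)
  perm <- sample(length(r$frames))
  shuffled <- trajectory(r$topology,
                         Map(function(fr, t) frame(fr$coords, fr$box, t),
                             r$frames[perm], seq_along(perm)))
  tab2 <- residue_contact_fraction(shuffled)
  expect_equal(tab2$x_i, tab$x_i)
  expect_equal(attr(tab2, "N"), attr(tab, "N"))
})

test_that("the selection rule reproduces the printed residue list exactly", {
  fx <- load_contact_fixture()
  sel <- select_binding_residues(fx)
  expect_equal(sel, c("K191", "K216", "K218", "R221", "K222", "R229", "R508",
                      "R514", "K515", "K578", "K621", "K627", "R640", "K657",
                      "R665"))
  expect_equal(max(fx$values), 53.1)
})

test_that("selection thresholds are strict inequalities", {
  m <- rbind(sim1 = c(a = 0.050, b = 0.101, c = 0.050),
             sim2 = c(a = 0.050, b = 0.000, c = 0.051),
             sim3 = c(a = 0.000, b = 0.000, c = 0.051))
  sel <- select_binding_residues(m)
  expect_false("a" %in% sel)  # exactly 5% twice: excluded
  expect_true("b" %in% sel)   # >10% once: included
  expect_true("c" %in% sel)   # >5% twice: included
})

test_that("lipid censuses nest across thresholds and count per class", {
  # one PIP2 in contact every frame, one DOPC in contact half the time
  prot <- c(5, 5, 5)
  pip <- c(5, 5, 5.45)
  dopc_near <- c(5, 5, 4.55)
  dopc_far <- c(2, 2, 5)
  f_both <- rbind(prot, pip, dopc_near, dopc_far)
  f_pip <- rbind(prot, pip, c(2, 8, 5), dopc_far)
  tr <- static_traj(list(f_both, f_pip, f_both, f_pip), 1, 1, n_dopc = 2)
  cen <- lipid_contact_census(tr)
  pip_rows <- cen$census[cen$census$class == "PIP2", ]
  expect_equal(pip_rows$N_L, c(1, 1))   # that lipid is included at both
  dopc_rows <- cen$census[cen$census$class == "DOPC", ]
  expect_true(all(dopc_rows$N_L[dopc_rows$threshold == 0.10] <=
                    dopc_rows$N_L[dopc_rows$threshold == 0.05]))
  expect_equal(cen$pct_time_binding[["PIP2"]], 100)
  expect_equal(cen$pct_time_binding[["DOPC"]], 50)
  per_pip <- cen$per_lipid[cen$per_lipid$class == "PIP2", ]
  expect_equal(per_pip$x_L, 1)

  # zero-contact trajectory: all censuses zero
  far <- rbind(c(5, 5, 9), pip - c(0, 0, 3), dopc_near - c(0, 0, 3),
               dopc_far)
  tr0 <- static_traj(list(far, far), 1, 1, n_dopc = 2)
  cen0 <- lipid_contact_census(tr0)
  expect_true(all(cen0$census$N_L == 0))
})

test_that("occupancy grows monotonically with the cutoff", {
  r <- std_run(1)
  cutoffs <- c(0.42, 0.47, 0.52, 0.57, 0.62)
  sweep_ <- cutoff_sweep(r$trajectory, cutoffs)
  expect_equal(dim(sweep_), c(30L, 5L))
  for (i in seq_len(nrow(sweep_))) {
    expect_true(all(diff(sweep_[i, ]) >= 0))
  }
  # column at the binding cutoff agrees with the per-run contact table
  tb <- residue_contact_fraction(r$trajectory)
  expect_equal(unname(sweep_[, "0.52"]),
               tb$n_i / attr(sweep_, "n_frames"))
  # cutoff 0 wipes out every contact
  z <- cutoff_sweep(r$trajectory, c(0, 0.52))
  expect_true(all(z[, 1] == 0))
})

test_that("leaflet distance series separates contact from bilayer scale", {
  # protein bead touching the upper (PIP2) leaflet plane
  prot <- c(2.8, 2.8, 6.55)
  upper_pip <- c(2.8, 2.8, 6.0)
  upper_dopc <- c(1.5, 1.5, 6.0)
  lower <- rbind(c(1, 1, 2), c(3, 3, 2))
  coords <- rbind(prot, upper_pip, upper_dopc, lower)
  top <- bead_topology(data.frame(
    bead_id = 0:4,
    bead_name = c("BB", "P1", "NC3", "NC3", "NC3"),
    residue_id = 1:5,
    residue_name = c("GLY", "PIP2", "DOPC", "DOPC", "DOPC"),
    molecule_id = 1:5,
    molecule_class = c("protein", "PIP2", "DOPC", "DOPC", "DOPC"),
    charge = c(0, -5, 0, 0, 0),
    is_phosphate = c(FALSE, TRUE, FALSE, FALSE, FALSE),
    leaflet = c(NA, "upper", "upper", "lower", "lower")))
  tr <- trajectory(top, list(frame(coords, c(8, 8, 12), 0)))
  ls <- leaflet_min_distance_series(tr)
  expect_equal(ls$dist_pip2_leaflet, 0.55, tolerance = 1e-12)
  expect_gt(ls$dist_bare_leaflet, 3.5)   # on the bilayer-thickness scale
})

test_that("equilibration skip drops early frames from the analysis", {
  mk <- function(d) rbind(c(5, 5, 5), c(5, 5, 5 + d))
  tr <- static_traj(list(mk(0.3), mk(2), mk(2), mk(2)), 1, 1,
                    times = 0:3)
  p <- analysis_params(equilibration_skip = 1)
  tl <- binding_timeline(tr, p)
  expect_equal(nrow(tl), 3)
  expect_equal(binding_fraction(tl), 0)
})
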