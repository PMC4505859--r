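# Shared fixtures for the test suite. Expensive standard runs (the packaged
# 80-ns toy conditions) are memoised per seed so several test files can share
# them without re-simulating.

.run_cache <- new.env(parent = emptyenv())

# packaged toy configuration with optional dotted-path overrides
toy_config <- function(seed = 1, ...) {
  ov <- list(...)
  load_run_config(seed = seed,
                  overrides = if (length(ov)) ov else NULL)
}

toy_planted_ids <- function() c(1L, 3L, 4L, 10L, 15L, 23L)

# standard 80-ns run under the packaged conditions; `charge` 0 gives the
# zero-charge control for the same seed (paired design: identical system
# geometry and noise stream).
std_run <- function(seed, charge = 3) {
  key <- sprintf("s%d_q%g", seed, charge)
  if (!is.null(.run_cache[[key]])) return(.run_cache[[key]])
  cfg <- toy_config(seed = seed, "system.protein.basic_charge" = charge)
  sim <- run_simulate(cfg)
  res <- list(config = cfg, trajectory = sim$trajectory,
              timeline = binding_timeline(sim$trajectory,
                                          sites = config_sites_for_tests(cfg)))
  .run_cache[[key]] <- res
  res
}

config_sites_for_tests <- function(cfg) {
  nms <- names(cfg$sites)
  out <- lapply(seq_along(nms),
                function(i) site_definition(nms[i], unlist(cfg$sites[[i]])))
  names(out) <- nms
  out
}

# short run for structural checks that only need some binding activity
quick_run <- function(seed = 1, n_steps = 3000, ...) {
  cfg <- toy_config(seed = seed, "simulation.n_steps" = n_steps, ...)
  run_simulate(cfg)$trajectory
}

# hand-built static "trajectory": one protein residue per bead at given
# coordinates, `n_pip` single-bead PIP2 lipids at given coordinates, box L.
# `frames_coords` is a list of coordinate matrices (protein rows first).
static_traj <- function(frames_coords, n_prot, n_pip, box = c(10, 10, 10),
                        n_dopc = 0, basic = integer(), times = NULL) {
  n <- n_prot + n_pip + n_dopc
  lip_leaflet <- rep("upper", n_pip + n_dopc)
  top <- bead_topology(data.frame(
    bead_id = 0:(n - 1L),
    bead_name = c(rep("BB", n_prot), rep("P1", n_pip), rep("NC3", n_dopc)),
    residue_id = c(seq_len(n_prot), n_prot + seq_len(n_pip + n_dopc)),
    residue_name = c(ifelse(seq_len(n_prot) %in% basic, "LYS", "GLY"),
                     rep("PIP2", n_pip), rep("DOPC", n_dopc)),
    molecule_id = c(rep(1L, n_prot), 1L + seq_len(n_pip + n_dopc)),
    molecule_class = c(rep("protein", n_prot), rep("PIP2", n_pip),
                       rep("DOPC", n_dopc)),
    charge = c(ifelse(seq_len(n_prot) %in% basic, 1, 0), rep(-5, n_pip),
               rep(0, n_dopc)),
    is_phosphate = c(rep(FALSE, n_prot), rep(TRUE, n_pip), rep(FALSE, n_dopc)),
    leaflet = c(rep(NA_character_, n_prot), lip_leaflet),
    stringsAsFactors = FALSE
  ))
  if (is.null(times)) times <- seq_along(frames_coords) - 1
  trajectory(top, Map(function(xy, t) frame(xy, box, t), frames_coords,
                      times))
}

# brute-force O(n^2) minimum-image distance oracle
oracle_min_distance <- function(a, b, box) {
  best <- Inf
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      d <- a[i, ] - b[j, ]
      d <- d - box * round(d / box)
      best <- min(best, sqrt(sum(d^2)))
    }
  }
  best
}

# brute-force pairwise screened-Coulomb + LJ energy oracle
oracle_energy <- function(coords, q, ia, ib, box, params) {
  elec <- 0; vdw <- 0
  for (i in ia) {
    for (j in ib) {
      d <- coords[i + 1L, ] - coords[j + 1L, ]
      d <- d - box * round(d / box)
      r <- sqrt(sum(d^2))
      if (r < params$nonbond_cutoff) {
        elec <- elec + 138.935458 * q[i + 1L] * q[j + 1L] *
          exp(-r / params$debye_length) / (params$dielectric * r)
        s6 <- (params$lj_sigma / r)^6
        vdw <- vdw + 4 * params$lj_epsilon * (s6^2 - s6)
      }
    }
  }
  list(electrostatic = elec, van_der_waals = vdw)
}

# brute-force elastic-network oracle
oracle_elastic <- function(coords, ids, box, cutoff, k) {
  rows <- list()
  for (a in seq_along(ids)) {
    for (b in seq_along(ids)) {
      if (a < b) {
        d <- coords[ids[a] + 1L, ] - coords[ids[b] + 1L, ]
        d <- d - box * round(d / box)
        r <- sqrt(sum(d^2))
        if (r < cutoff) {
          rows[[length(rows) + 1L]] <-
            data.frame(i = ids[a], j = ids[b], rest_length = r,
                       force_constant = k)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$i, out$j), ]
}

# brute-force RDF oracle (per-frame double loop, same binning/normalisation
# definition written out longhand)
oracle_rdf <- function(traj, ref, tgt, r_max, n_bins, mode = "3d") {
  box <- traj$frames[[1]]$box
  breaks <- seq(0, r_max, length.out = n_bins + 1)
  counts <- numeric(n_bins)
  n_self <- 0
  for (a in ref) for (b in tgt) if (a == b) n_self <- n_self + 1
  for (fr in traj$frames) {
    for (a in ref) {
      for (b in tgt) {
        if (a == b) next
        d <- fr$coords[a + 1L, ] - fr$coords[b + 1L, ]
        d <- d - box * round(d / box)
        r <- if (mode == "3d") sqrt(sum(d^2)) else sqrt(sum(d[1:2]^2))
        if (r < r_max) {
          bin <- findInterval(r, breaks, left.open = TRUE,
                              rightmost.closed = TRUE)
          counts[bin] <- counts[bin] + 1
        }
      }
    }
  }
  n_pairs <- length(ref) * length(tgt) - n_self
  if (mode == "3d") {
    vol <- prod(box); shell <- 4 / 3 * pi * diff(breaks^3)
  } else {
    vol <- box[1] * box[2]; shell <- pi * diff(breaks^2)
  }
  expected <- length(traj$frames) * n_pairs * shell / vol
  ifelse(expected > 0, counts / expected, 0)
}
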