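# Overdamped (Brownian) dynamics of a rigid charged protein over a fluid
# bilayer with screened electrostatics and truncated Lennard-Jones
# interactions. Units: nm, ns, kJ/mol, elementary charges, K.
#
# Interaction set: protein-lipid, protein-ion and ion-lipid pairs. Lipid-lipid
# and ion-ion nonbonded terms are omitted: lipid heads diffuse as an ideal 2-D
# gas restrained to their leaflet plane, which keeps the head-group
# distribution an exact uniform null in the absence of a protein.

COULOMB_K <- 138.935458   # kJ mol^-1 nm e^-2
KB <- 0.0083144621        # kJ mol^-1 K^-1

#' Simulation parameters for the Brownian membrane-association simulator
#'
#' Defaults describe the package's standard toy conditions: 320 K, aqueous
#' screening (dielectric 78, Debye length 0.78 nm ~ 150 mM monovalent salt),
#' MARTINI-sized beads (LJ sigma 0.47 nm) with a weak epsilon, plain
#' truncation of all nonbonded terms at 1.2 nm, and per-class translational
#' drag coefficients sized so that association happens on tens of
#' nanoseconds.
#'
#' @param timestep integration step in ns.
#' @param n_steps number of steps.
#' @param save_interval save a frame every this many steps.
#' @param temperature K.
#' @param friction named vector of translational drag coefficients
#'   (kJ mol^-1 ns nm^-2) for `protein`, `lipid`, `ion` beads; bead diffusion
#'   coefficient is `kB T / friction`.
#' @param debye_length electrostatic screening length in nm.
#' @param dielectric relative dielectric constant.
#' @param lj_sigma,lj_epsilon Lennard-Jones parameters (nm, kJ/mol).
#' @param nonbond_cutoff plain truncation distance in nm.
#' @param leaflet_restraint_k harmonic z-restraint on lipid heads
#'   (kJ mol^-1 nm^-2).
#' @param max_drift cap on the deterministic displacement per bead per step
#'   (nm); limits integration error in steep LJ cores.
#' @param seed integer seed; all randomness of a run flows from it.
#' @return list of class `sim_params`.
#' @export
sim_params <- function(timestep = 0.005, n_steps = 16000, save_interval = 40,
                       temperature = 320,
                       friction = c(protein = 1.5, lipid = 30, ion = 5),
                       debye_length = 0.78, dielectric = 78,
                       lj_sigma = 0.47, lj_epsilon = 2.0,
                       nonbond_cutoff = 1.2, leaflet_restraint_k = 100,
                       max_drift = 0.08, seed = 1) {
  stopifnot(timestep > 0, debye_length > 0, dielectric > 0,
            nonbond_cutoff > 0, all(friction > 0))
  p <- list(timestep = timestep, n_steps = as.integer(n_steps),
            save_interval = as.integer(save_interval),
            temperature = temperature, friction = friction,
            debye_length = debye_length, dielectric = dielectric,
            lj_sigma = lj_sigma, lj_epsilon = lj_epsilon,
            nonbond_cutoff = nonbond_cutoff,
            leaflet_restraint_k = leaflet_restraint_k,
            max_drift = max_drift, seed = as.integer(seed))
  class(p) <- "sim_params"
  p
}

#' Screened Coulomb (Yukawa) pair energy
#'
#' `k q1 q2 exp(-r / debye_length) / (dielectric * r)` with `k` the Coulomb
#' constant in kJ mol^-1 nm e^-2. Models salt-screened electrostatics in an
#' implicit solvent.
#'
#' @param q1,q2 charges in e.
#' @param r separation in nm (> 0); vectorised.
#' @param debye_length screening length in nm.
#' @param dielectric relative dielectric constant.
#' @return energy in kJ/mol.
#' @export
screened_coulomb_energy <- function(q1, q2, r, debye_length = 0.78,
                                    dielectric = 78) {
  if (any(r <= 0)) stop("r must be > 0", call. = FALSE)
  COULOMB_K * q1 * q2 * exp(-r / debye_length) / (dielectric * r)
}

# Truncated 12-6 Lennard-Jones energy; vectorised over r.
lj_energy <- function(r, sigma, epsilon, cutoff) {
  s6 <- (sigma / r)^6
  ifelse(r < cutoff, 4 * epsilon * (s6 * s6 - s6), 0)
}

#' Pairwise interaction energy between two bead groups
#'
#' Sums screened-Coulomb and Lennard-Jones terms over all cross pairs under
#' the minimum-image convention, with plain truncation at the nonbond cutoff.
#'
#' @param topology a [bead_topology()].
#' @param fr a [frame()].
#' @param group_a,group_b disjoint bead-id sets (0-based).
#' @param params a [sim_params()].
#' @return list of class `energy_breakdown` with elements `electrostatic`,
#'   `van_der_waals` (kJ/mol) and `time` (ns).
#' @export
total_interaction_energy <- function(topology, fr, group_a, group_b,
                                     params = sim_params()) {
  if (length(group_a) == 0 || length(group_b) == 0) {
    stop("bead groups must be nonempty", call. = FALSE)
  }
  if (length(intersect(group_a, group_b)) > 0) {
    stop("bead groups must be disjoint", call. = FALSE)
  }
  ra <- bead_rows(group_a); rb <- bead_rows(group_b)
  d <- pair_distances(fr$coords[ra, , drop = FALSE],
                      fr$coords[rb, , drop = FALSE], fr$box)
  qa <- topology$charge[ra]; qb <- topology$charge[rb]
  qq <- outer(qa, qb)
  within <- d < params$nonbond_cutoff
  elec <- sum(COULOMB_K * qq[within] *
                exp(-d[within] / params$debye_length) /
                (params$dielectric * d[within]))
  s6 <- (params$lj_sigma / d[within])^6
  vdw <- sum(4 * params$lj_epsilon * (s6 * s6 - s6))
  structure(list(electrostatic = elec, van_der_waals = vdw, time = fr$time),
            class = "energy_breakdown")
}

# Forces between two coordinate groups (na x 3, nb x 3) with charges qa, qb.
# Returns force matrices on each group (kJ mol^-1 nm^-1). Screened Coulomb +
# truncated LJ, minimum image.
pair_forces <- function(xa, xb, qa, qb, box, params) {
  dx <- outer(xa[, 1], xb[, 1], "-"); dx <- dx - box[1] * round(dx / box[1])
  dy <- outer(xa[, 2], xb[, 2], "-"); dy <- dy - box[2] * round(dy / box[2])
  dz <- outer(xa[, 3], xb[, 3], "-"); dz <- dz - box[3] * round(dz / box[3])
  r2 <- dx * dx + dy * dy + dz * dz
  r <- sqrt(r2)
  within <- r < params$nonbond_cutoff & r > 1e-9
  if (!any(within)) {
    return(list(fa = matrix(0, nrow(xa), 3), fb = matrix(0, nrow(xb), 3)))
  }
  # magnitude of -dE/dr (positive = repulsive), zero outside the cutoff
  mag <- matrix(0, nrow(xa), nrow(xb))
  rw <- r[within]
  qq <- outer(qa, qb)[within]
  ce <- COULOMB_K * qq * exp(-rw / params$debye_length) / params$dielectric
  mag_el <- ce * (1 / (rw * rw) + 1 / (params$debye_length * rw))
  s6 <- (params$lj_sigma / rw)^6
  mag_lj <- 4 * params$lj_epsilon * (12 * s6 * s6 - 6 * s6) / rw
  mag[within] <- mag_el + mag_lj
  fx <- mag * dx / pmax(r, 1e-9)
  fy <- mag * dy / pmax(r, 1e-9)
  fz <- mag * dz / pmax(r, 1e-9)
  list(fa = cbind(rowSums(fx), rowSums(fy), rowSums(fz)),
       fb = -cbind(colSums(fx), colSums(fy), colSums(fz)))
}

# Rodrigues rotation matrix for rotation vector w (axis * angle).
rotation_matrix <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-14) return(diag(3))
  k <- w / th
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0),
              nrow = 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Precompute the per-run context shared by every step.
make_dyn_context <- function(topology, fr, params) {
  prot <- bead_rows(protein_beads(topology))
  lip <- bead_rows(c(class_beads(topology, "DOPC"), class_beads(topology, "PIP2")))
  ion <- bead_rows(class_beads(topology, "ion"))
  kT <- KB * params$temperature
  zeta_p <- params$friction[["protein"]]
  # lipid leaflet rest planes from the starting frame
  z0 <- rep(NA_real_, nrow(topology))
  for (lf in c("upper", "lower")) {
    rows <- bead_rows(leaflet_beads(topology, lf))
    if (length(rows)) z0[rows] <- mean(fr$coords[rows, 3])
  }
  list(
    prot = prot, lip = lip, ion = ion,
    q = topology$charge,
    kT = kT,
    mu_lip = 1 / params$friction[["lipid"]],
    mu_ion = 1 / params$friction[["ion"]],
    mu_t = if (length(prot)) 1 / (zeta_p * length(prot)) else 0,
    zeta_p = zeta_p,
    z0 = z0
  )
}

# One Brownian step over the full system. `noise = FALSE` gives the
# deterministic (drift-only) map, used at temperature 0.
dyn_step_core <- function(ctx, coords, box, params) {
  dt <- params$timestep
  kT <- ctx$kT
  nb <- nrow(coords)
  f <- matrix(0, nb, 3)
  if (length(ctx$prot) && length(ctx$lip)) {
    pf <- pair_forces(coords[ctx$prot, , drop = FALSE],
                      coords[ctx$lip, , drop = FALSE],
                      ctx$q[ctx$prot], ctx$q[ctx$lip], box, params)
    f[ctx$prot, ] <- f[ctx$prot, ] + pf$fa
    f[ctx$lip, ] <- f[ctx$lip, ] + pf$fb
  }
  if (length(ctx$prot) && length(ctx$ion)) {
    pf <- pair_forces(coords[ctx$prot, , drop = FALSE],
                      coords[ctx$ion, , drop = FALSE],
                      ctx$q[ctx$prot], ctx$q[ctx$ion], box, params)
    f[ctx$prot, ] <- f[ctx$prot, ] + pf$fa
    f[ctx$ion, ] <- f[ctx$ion, ] + pf$fb
  }
  if (length(ctx$ion) && length(ctx$lip)) {
    pf <- pair_forces(coords[ctx$ion, , drop = FALSE],
                      coords[ctx$lip, , drop = FALSE],
                      ctx$q[ctx$ion], ctx$q[ctx$lip], box, params)
    f[ctx$ion, ] <- f[ctx$ion, ] + pf$fa
    f[ctx$lip, ] <- f[ctx$lip, ] + pf$fb
  }
  if (any(!is.finite(f))) {
    bad <- which(!is.finite(rowSums(f)))[1]
    stop("non-finite force on bead ", bad - 1L, call. = FALSE)
  }
  # lipid z-restraints to their leaflet plane
  if (length(ctx$lip)) {
    f[ctx$lip, 3] <- f[ctx$lip, 3] -
      params$leaflet_restraint_k * (coords[ctx$lip, 3] - ctx$z0[ctx$lip])
  }

  cap_drift <- function(d) {
    nrm <- sqrt(rowSums(d * d))
    over <- nrm > params$max_drift
    if (any(over)) d[over, ] <- d[over, ] * (params$max_drift / nrm[over])
    d
  }

  # --- protein: rigid-body translation + rotation ---
  if (length(ctx$prot)) {
    pc <- coords[ctx$prot, , drop = FALSE]
    com <- colMeans(pc)
    rel <- sweep(pc, 2, com)
    Ftot <- colSums(f[ctx$prot, , drop = FALSE])
    tau <- c(
      sum(rel[, 2] * f[ctx$prot, 3] - rel[, 3] * f[ctx$prot, 2]),
      sum(rel[, 3] * f[ctx$prot, 1] - rel[, 1] * f[ctx$prot, 3]),
      sum(rel[, 1] * f[ctx$prot, 2] - rel[, 2] * f[ctx$prot, 1])
    )
    zeta_r <- ctx$zeta_p * sum(rel * rel)           # free-draining rotational drag
    mu_r <- if (zeta_r > 0) 1 / zeta_r else 0
    drift <- ctx$mu_t * Ftot * dt
    nd <- sqrt(sum(drift^2))
    if (nd > params$max_drift) drift <- drift * params$max_drift / nd
    dX <- drift + sqrt(2 * kT * ctx$mu_t * dt) * stats::rnorm(3)
    w <- mu_r * tau * dt + sqrt(2 * kT * mu_r * dt) * stats::rnorm(3)
    R <- rotation_matrix(w)
    newpc <- sweep(rel %*% t(R), 2, com + dX, "+")
    # wrap the rigid body by its COM so it never fragments across the boundary
    com2 <- colMeans(newpc)
    shift <- -box * floor(com2 / box)
    coords[ctx$prot, ] <- sweep(newpc, 2, shift, "+")
  }

  # --- lipids: free x-y diffusion, restrained z ---
  if (length(ctx$lip)) {
    n <- length(ctx$lip)
    drift <- cap_drift(ctx$mu_lip * f[ctx$lip, , drop = FALSE] * dt)
    disp <- drift + sqrt(2 * kT * ctx$mu_lip * dt) *
      matrix(stats::rnorm(3 * n), n, 3)
    coords[ctx$lip, ] <- wrap_coords(coords[ctx$lip, , drop = FALSE] + disp, box)
  }

  # --- ions: free 3-D diffusion ---
  if (length(ctx$ion)) {
    n <- length(ctx$ion)
    drift <- cap_drift(ctx$mu_ion * f[ctx$ion, , drop = FALSE] * dt)
    disp <- drift + sqrt(2 * kT * ctx$mu_ion * dt) *
      matrix(stats::rnorm(3 * n), n, 3)
    coords[ctx$ion, ] <- wrap_coords(coords[ctx$ion, , drop = FALSE] + disp, box)
  }
  coords
}

#' One Brownian-dynamics step
#'
#' Advances the system by one overdamped step: the protein moves as a single
#' rigid body (centre-of-mass translation plus a small-angle rotation from
#' the summed torque, each with matching thermal noise), lipid head beads
#' diffuse laterally while harmonically restrained to their leaflet plane in
#' z, and ions diffuse freely. All coordinates are periodically wrapped; the
#' protein is wrapped by its centre of mass so the rigid body never
#' fragments. The elastic network, if given, contributes no forces (the body
#' is exactly rigid) and is accepted for interface compatibility and
#' rigidity auditing.
#'
#' At `temperature = 0` the thermal noise vanishes and the step is the pure
#' drift map, so a force-free system is left unchanged.
#'
#' @param topology a [bead_topology()].
#' @param fr current [frame()].
#' @param elastic optional [build_elastic_network()] output (unused forces-wise).
#' @param params a [sim_params()].
#' @return the next [frame()], with `time` advanced by one timestep.
#' @export
bd_step <- function(topology, fr, elastic = NULL, params = sim_params()) {
  ctx <- make_dyn_context(topology, fr, params)
  coords <- dyn_step_core(ctx, fr$coords, fr$box, params)
  frame(coords, fr$box, fr$time + params$timestep)
}

#' Run a Brownian-dynamics trajectory
#'
#' Integrates `params$n_steps` steps from `frame0`, saving every
#' `params$save_interval` steps (the initial frame included). Fully
#' reproducible: all randomness flows from `params$seed` through a private
#' RNG stream, leaving the caller's RNG state untouched.
#'
#' @param topology a [bead_topology()].
#' @param frame0 initial [frame()].
#' @param params a [sim_params()].
#' @param elastic optional elastic network (see [bd_step()]).
#' @return a [trajectory()].
#' @export
bd_run <- function(topology, frame0, params = sim_params(), elastic = NULL) {
  ctx <- make_dyn_context(topology, frame0, params)
  with_seed(params$seed, {
    coords <- frame0$coords
    box <- frame0$box
    frames <- vector("list", params$n_steps %/% max(params$save_interval, 1L) + 1L)
    frames[[1]] <- frame(coords, box, frame0$time)
    nsave <- 1L
    if (params$n_steps > 0) {
      for (s in seq_len(params$n_steps)) {
        coords <- dyn_step_core(ctx, coords, box, params)
        if (s %% params$save_interval == 0L) {
          nsave <- nsave + 1L
          frames[[nsave]] <- frame(coords, box,
                                   frame0$time + s * params$timestep)
        }
      }
    }
    trajectory(topology, frames[seq_len(nsave)])
  })
}

#' Interaction-energy time series between two bead groups
#'
#' Evaluates [total_interaction_energy()] on every frame; the standard way to
#' monitor association/dissociation events from the energetic side.
#'
#' @param traj a [trajectory()].
#' @param group_a,group_b disjoint bead-id sets.
#' @param params a [sim_params()].
#' @return data frame with columns `time`, `electrostatic`, `van_der_waals`.
#' @export
interaction_energy_series <- function(traj, group_a, group_b,
                                      params = sim_params()) {
  rows <- lapply(traj$frames, function(fr) {
    e <- total_interaction_energy(traj$topology, fr, group_a, group_b, params)
    data.frame(time = e$time, electrostatic = e$electrostatic,
               van_der_waals = e$van_der_waals)
  })
  do.call(rbind, rows)
}
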