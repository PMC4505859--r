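# Builders for synthetic coarse-grained systems: a planar two-leaflet bilayer
# with an asymmetrically PIP2-enriched upper leaflet, a rigid quasi-spherical
# toy protein with surface basic residues, and their combination at a
# controlled protein-membrane gap. Every builder is deterministic under an
# integer seed.

# Evaluate `code` under a private RNG stream; the caller's RNG state is
# untouched.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# round-to-nearest with halves up (33.1 -> 33; 2.5 -> 3), independent of the
# IEC 60559 banker's rounding of base round().
round_half_up <- function(x) floor(x + 0.5)

#' Build a planar two-leaflet DOPC bilayer
#'
#' Places `n_per_leaflet` single-head-bead lipids per leaflet on square
#' lattices at `z_center +/- z_separation / 2`. The box x-y cross-section is a
#' square of area `n_per_leaflet * area_per_lipid`.
#'
#' @param n_per_leaflet lipids per leaflet (>= 1).
#' @param area_per_lipid area per lipid in nm^2 (default 0.698, giving the
#'   15.2 nm edge of a 331-lipid leaflet).
#' @param z_separation head-plane separation in nm (default 4.0, a typical
#'   phosphate-to-phosphate distance for a fluid PC bilayer).
#' @param box_z box height in nm.
#' @param z_center bilayer mid-plane height in nm; default `box_z / 3`, which
#'   leaves head room above the upper leaflet for a protein.
#' @return list with elements `topology` ([bead_topology()]) and `frame`
#'   ([frame()]).
#' @export
build_bilayer <- function(n_per_leaflet, area_per_lipid = 0.698,
                          z_separation = 4.0, box_z = 12,
                          z_center = box_z / 3) {
  if (n_per_leaflet < 1) stop("n_per_leaflet must be >= 1", call. = FALSE)
  if (area_per_lipid <= 0) stop("area_per_lipid must be > 0", call. = FALSE)
  if (z_separation <= 0 || box_z <= z_separation) {
    stop("need 0 < z_separation < box_z", call. = FALSE)
  }
  n <- as.integer(n_per_leaflet)
  edge <- sqrt(n * area_per_lipid)
  m <- ceiling(sqrt(n))
  a <- edge / m
  idx <- 0:(n - 1L)
  gx <- (idx %% m + 0.5) * a
  gy <- (idx %/% m + 0.5) * a
  z_lower <- z_center - z_separation / 2
  z_upper <- z_center + z_separation / 2
  coords <- rbind(cbind(gx, gy, z_lower), cbind(gx, gy, z_upper))
  nb <- 2L * n
  top <- bead_topology(data.frame(
    bead_id = 0:(nb - 1L),
    bead_name = "NC3",
    residue_id = 1:nb,
    residue_name = "DOPC",
    molecule_id = 1:nb,
    molecule_class = "DOPC",
    charge = 0,
    is_phosphate = FALSE,
    leaflet = rep(c("lower", "upper"), each = n),
    stringsAsFactors = FALSE
  ))
  list(topology = top, frame = frame(coords, c(edge, edge, box_z), time = 0))
}

#' Randomly replace a fraction of one leaflet's lipids with PIP2
#'
#' Relabels `round(fraction * n_leaflet)` uniformly chosen lipids (without
#' replacement, halves rounded up) of the given leaflet as PIP2: the head bead
#' becomes the 1'-phosphate reference bead and carries the PIP2 head-group
#' charge. Coordinates are untouched.
#'
#' @param system list with `topology` and `frame` (from [build_bilayer()]).
#' @param fraction fraction of the leaflet's lipids to replace, in [0, 1].
#' @param leaflet `"upper"` (default) or `"lower"`.
#' @param seed integer seed for the selection.
#' @param head_charge PIP2 head-bead charge in e (default -5, a common
#'   coarse-grained choice for the doubly phosphorylated inositol head group).
#' @return system list with updated topology.
#' @export
assign_pip2 <- function(system, fraction, leaflet = "upper", seed = 1,
                        head_charge = -5) {
  if (!is.numeric(fraction) || fraction < 0 || fraction > 1) {
    stop("fraction must lie in [0, 1]", call. = FALSE)
  }
  if (!leaflet %in% c("upper", "lower")) {
    stop("leaflet must be 'upper' or 'lower'", call. = FALSE)
  }
  top <- system$topology
  cand_mols <- unique(top$molecule_id[
    top$molecule_class == "DOPC" & !is.na(top$leaflet) & top$leaflet == leaflet])
  n_rep <- round_half_up(fraction * length(cand_mols))
  if (n_rep > 0) {
    chosen <- with_seed(seed, sample(cand_mols, n_rep, replace = FALSE))
    sel <- top$molecule_id %in% chosen
    top$molecule_class[sel] <- "PIP2"
    top$residue_name[sel] <- "PIP2"
    # single-bead lipids: the head bead is the phosphate bead
    head <- sel & top$bead_name %in% c("NC3", "PO4", "P1")
    top$bead_name[head] <- "P1"
    top$is_phosphate[head] <- TRUE
    top$charge[head] <- head_charge
  }
  system$topology <- bead_topology(top)
  system
}

#' Build a rigid quasi-spherical toy protein
#'
#' One backbone bead per residue, laid out on a Fibonacci spherical lattice of
#' the given radius with a small seeded radial jitter and a random global
#' rotation, centred at the origin. Residues in `basic_residue_ids` model
#' surface lysines/arginines and carry `basic_charge`; all others are neutral.
#'
#' @param n_residues number of residues (beads).
#' @param radius shell radius in nm.
#' @param basic_residue_ids integer residue ids (subset of `1:n_residues`)
#'   to make basic.
#' @param basic_charge charge per basic bead in e (default +1).
#' @param seed integer seed for jitter and orientation.
#' @param jitter relative radial jitter amplitude (default 0.02).
#' @return list with `topology` and `frame`.
#' @export
build_toy_protein <- function(n_residues, radius, basic_residue_ids = integer(),
                              basic_charge = 1, seed = 1, jitter = 0.02) {
  if (n_residues < 1) stop("n_residues must be >= 1", call. = FALSE)
  if (radius <= 0) stop("radius must be > 0", call. = FALSE)
  basic_residue_ids <- as.integer(basic_residue_ids)
  unknown <- setdiff(basic_residue_ids, seq_len(n_residues))
  if (length(unknown) > 0) {
    stop("unknown residue id(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  n <- as.integer(n_residues)
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)                  # polar angle
  theta <- pi * (1 + sqrt(5)) * i             # golden-angle azimuth
  coords <- with_seed(seed, {
    r <- radius * (1 + runif(n, -jitter, jitter))
    xyz <- cbind(r * sin(phi) * cos(theta),
                 r * sin(phi) * sin(theta),
                 r * cos(phi))
    xyz %*% t(random_rotation())
  })
  coords <- sweep(coords, 2, colMeans(coords))  # centre of geometry at origin
  is_basic <- seq_len(n) %in% basic_residue_ids
  top <- bead_topology(data.frame(
    bead_id = 0:(n - 1L),
    bead_name = "BB",
    residue_id = seq_len(n),
    residue_name = ifelse(is_basic, "LYS", "GLY"),
    molecule_id = 1L,
    molecule_class = "protein",
    charge = ifelse(is_basic, basic_charge, 0),
    is_phosphate = FALSE,
    leaflet = NA_character_,
    stringsAsFactors = FALSE
  ))
  side <- 4 * radius + 2
  list(topology = top, frame = frame(coords, c(side, side, side), time = 0))
}

# Uniform random rotation matrix (quaternion method); uses the current RNG.
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Build an elastic network over protein beads
#'
#' Harmonic bonds between every unordered bead pair closer than `cutoff` in
#' the build-time frame, each at its build-time distance as rest length. With
#' the protein integrated as a rigid body the network contributes no forces;
#' it documents the structure and serves as a rigidity check (rest lengths
#' must match pair distances in every later frame).
#'
#' @param fr a [frame()].
#' @param protein_beads bead ids (0-based) to connect.
#' @param cutoff distance cutoff in nm (default 0.9).
#' @param k force constant in kJ mol^-1 nm^-2 (default 500).
#' @return data frame of class `elastic_network` with columns `i`, `j`
#'   (bead ids, `i < j`), `rest_length`, `force_constant`.
#' @export
build_elastic_network <- function(fr, protein_beads, cutoff = 0.9, k = 500) {
  if (cutoff <= 0) stop("cutoff must be > 0", call. = FALSE)
  ids <- sort(as.integer(protein_beads))
  xyz <- fr$coords[bead_rows(ids), , drop = FALSE]
  d <- pair_distances(xyz, xyz, fr$box)
  sel <- which(upper.tri(d) & d < cutoff, arr.ind = TRUE)
  net <- data.frame(
    i = ids[sel[, 1]],
    j = ids[sel[, 2]],
    rest_length = d[sel],
    force_constant = rep(k, nrow(sel))
  )
  net <- net[order(net$i, net$j), , drop = FALSE]
  rownames(net) <- NULL
  class(net) <- c("elastic_network", "data.frame")
  net
}

#' Place a protein above a bilayer at a given gap
#'
#' Merges the two systems, translating the protein so its x-y centroid sits at
#' the box centre and the z-distance between its lowest bead and the
#' upper-leaflet head-bead plane (mean z of upper-leaflet beads) equals `gap`.
#' Protein beads come first in the merged numbering.
#'
#' @param bilayer_system list with `topology`/`frame` (bilayer).
#' @param protein_system list with `topology`/`frame` (protein).
#' @param gap requested gap in nm (>= 0).
#' @return merged list with `topology` and `frame` (bilayer box).
#' @export
place_protein <- function(bilayer_system, protein_system, gap) {
  if (gap < 0) stop("gap must be >= 0", call. = FALSE)
  btop <- bilayer_system$topology
  bfr <- bilayer_system$frame
  ptop <- protein_system$topology
  pco <- protein_system$frame$coords
  up <- leaflet_beads(btop, "upper")
  plane <- mean(bfr$coords[bead_rows(up), 3])
  box <- bfr$box
  shift_xy <- c(box[1] / 2, box[2] / 2) - colMeans(pco)[1:2]
  shift_z <- (plane + gap) - min(pco[, 3])
  pco <- sweep(pco, 2, -c(shift_xy, shift_z))
  if (max(pco[, 3]) > box[3] || min(pco[, 3]) < 0) {
    stop("gap of ", gap, " nm pushes the protein outside the box z-extent",
         call. = FALSE)
  }
  np <- nrow(ptop)
  btop2 <- btop
  btop2$bead_id <- btop2$bead_id + np
  btop2$molecule_id <- btop2$molecule_id + max(ptop$molecule_id)
  merged <- rbind(as.data.frame(ptop), as.data.frame(btop2))
  list(topology = bead_topology(merged),
       frame = frame(rbind(pco, bfr$coords), box, time = 0))
}

#' Add freely diffusing monovalent ions
#'
#' Scatters `n_ions` point charges uniformly in the box (kept off the bilayer
#' slab so they start in the solvent region).
#'
#' @param system list with `topology` and `frame`.
#' @param n_ions number of ions.
#' @param charge ion charge in e (default +1, sodium-like).
#' @param seed integer seed.
#' @return system with ions appended.
#' @export
add_ions <- function(system, n_ions, charge = 1, seed = 1) {
  if (n_ions < 1) return(system)
  top <- system$topology
  fr <- system$frame
  box <- fr$box
  lip <- bead_rows(c(class_beads(top, "DOPC"), class_beads(top, "PIP2")))
  zlo <- if (length(lip)) min(fr$coords[lip, 3]) - 0.5 else Inf
  zhi <- if (length(lip)) max(fr$coords[lip, 3]) + 0.5 else -Inf
  xyz <- with_seed(seed, {
    out <- matrix(NA_real_, n_ions, 3)
    got <- 0
    while (got < n_ions) {
      p <- c(stats::runif(1, 0, box[1]), stats::runif(1, 0, box[2]),
             stats::runif(1, 0, box[3]))
      if (p[3] < zlo || p[3] > zhi) {
        got <- got + 1
        out[got, ] <- p
      }
    }
    out
  })
  n0 <- nrow(top)
  m0 <- max(top$molecule_id)
  r0 <- max(top$residue_id)
  itop <- data.frame(
    bead_id = n0:(n0 + n_ions - 1L),
    bead_name = "NA+",
    residue_id = r0 + seq_len(n_ions),
    residue_name = "ION",
    molecule_id = m0 + seq_len(n_ions),
    molecule_class = "ion",
    charge = charge,
    is_phosphate = FALSE,
    leaflet = NA_character_,
    stringsAsFactors = FALSE
  )
  list(topology = bead_topology(rbind(as.data.frame(top), itop)),
       frame = frame(rbind(fr$coords, xyz), box, fr$time))
}
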