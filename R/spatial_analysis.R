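# Spatial analyses: radial distribution functions, protein principal-axis
# orientation against the bilayer normal, centre-of-mass axes between residue
# sets, and binding-pose classification against named site groups.

#' Named residue set used for pose classification
#'
#' @param name site name (e.g. `"Group I"`).
#' @param residue_ids nonempty integer residue ids.
#' @param labels optional residue labels (e.g. `"K621"`), kept for reporting.
#' @return list of class `site_definition`.
#' @export
site_definition <- function(name, residue_ids, labels = NULL) {
  residue_ids <- as.integer(residue_ids)
  if (length(residue_ids) == 0) stop("site needs residues", call. = FALSE)
  if (anyDuplicated(residue_ids)) stop("duplicate residue ids", call. = FALSE)
  structure(list(name = name, residue_ids = residue_ids, labels = labels),
            class = "site_definition")
}

check_sites_disjoint <- function(sites) {
  ids <- lapply(sites, function(s) s$residue_ids)
  if (length(Reduce(intersect, ids)) > 0 ||
      anyDuplicated(unlist(ids)) > 0) {
    stop("sites in one classification scheme must not overlap", call. = FALSE)
  }
  invisible(sites)
}

#' Radial distribution function
#'
#' Pair-correlation g(r) between a reference and a target bead set,
#' accumulated over frames with minimum-image distances and normalised by
#' shell volume (`mode = "3d"`) or shell area (`mode = "lateral"`, using x-y
#' distances) and the mean target density. Self-pairs are excluded, so for a
#' uniform ideal-gas target g(r) -> 1.
#'
#' @param traj a [trajectory()].
#' @param reference,target nonempty bead-id sets (0-based).
#' @param r_max histogram range in nm; must not exceed half the smallest
#'   relevant box edge (minimum-image validity).
#' @param n_bins number of uniform bins.
#' @param mode `"3d"` or `"lateral"`.
#' @param frame_range optional `c(t_min, t_max)` in ns restricting the
#'   analysed frames (e.g. to drop an equilibration period).
#' @return list of class `rdf_profile` with `r` (bin centres), `g`, `counts`,
#'   `mode`, `n_frames`.
#' @export
rdf <- function(traj, reference, target, r_max, n_bins = 60,
                mode = c("3d", "lateral"), frame_range = NULL) {
  mode <- match.arg(mode)
  if (length(reference) == 0 || length(target) == 0) {
    stop("selectors must be nonempty", call. = FALSE)
  }
  frames <- traj$frames
  if (!is.null(frame_range)) {
    times <- vapply(frames, function(f) f$time, numeric(1))
    frames <- frames[times >= frame_range[1] & times <= frame_range[2]]
    if (length(frames) == 0) stop("frame_range selects no frames", call. = FALSE)
  }
  box <- frames[[1]]$box
  half <- if (mode == "3d") min(box) / 2 else min(box[1:2]) / 2
  if (r_max > half + 1e-9) {
    stop("r_max (", r_max, " nm) exceeds half the smallest box edge (",
         signif(half, 4), " nm): minimum image invalid", call. = FALSE)
  }
  rr <- bead_rows(reference); rt <- bead_rows(target)
  self_mask <- outer(reference, target, "==")
  breaks <- seq(0, r_max, length.out = n_bins + 1)
  counts <- numeric(n_bins)
  for (fr in frames) {
    d <- if (mode == "3d") {
      pair_distances(fr$coords[rr, , drop = FALSE],
                     fr$coords[rt, , drop = FALSE], fr$box)
    } else {
      pair_distances_xy(fr$coords[rr, , drop = FALSE],
                        fr$coords[rt, , drop = FALSE], fr$box)
    }
    d <- d[!self_mask]
    d <- d[d < r_max]
    counts <- counts + tabulate(findInterval(d, breaks, left.open = TRUE,
                                             rightmost.closed = TRUE),
                                nbins = n_bins)
  }
  # expected pair count per shell for a uniform target
  n_pairs <- length(reference) * length(target) - sum(self_mask)
  if (mode == "3d") {
    vol <- prod(box)
    shell <- 4 / 3 * pi * diff(breaks^3)
  } else {
    vol <- box[1] * box[2]
    shell <- pi * diff(breaks^2)
  }
  expected <- length(frames) * n_pairs * shell / vol
  g <- ifelse(expected > 0, counts / expected, 0)
  structure(list(r = (breaks[-1] + breaks[-length(breaks)]) / 2, g = g,
                 counts = counts, mode = mode, n_frames = length(frames)),
            class = "rdf_profile")
}

#' First principal axis of a bead cloud
#'
#' Eigenvector of the bead-coordinate covariance matrix with the largest
#' eigenvalue, sign-fixed to a non-negative z-component (ties broken toward
#' non-negative x, then y). The attribute `degenerate` flags clouds whose
#' leading axis is ill-defined (coincident beads, or leading eigenvalues
#' equal within tolerance).
#'
#' @param fr a [frame()].
#' @param beads nonempty bead-id set (0-based).
#' @param tol relative degeneracy tolerance (default 1e-8).
#' @return unit 3-vector with attribute `degenerate` (logical).
#' @export
principal_axis <- function(fr, beads, tol = 1e-8) {
  if (length(beads) < 2) stop("need at least 2 beads", call. = FALSE)
  xyz <- fr$coords[bead_rows(beads), , drop = FALSE]
  e <- eigen(stats::cov(xyz), symmetric = TRUE)
  v <- e$vectors[, 1]
  lam <- e$values
  degen <- lam[1] < tol || (lam[1] - lam[2]) < tol * max(lam[1], 1)
  s <- sign(v[3])
  if (s == 0) s <- sign(v[1])
  if (s == 0) s <- sign(v[2])
  if (s == 0) s <- 1
  v <- v * s
  attr(v, "degenerate") <- degen
  v
}

#' Distribution of the principal-axis z-component over a trajectory
#'
#' Histograms the bilayer-normal component V_z of the protein's first
#' principal axis across frames. Because +/-v are the same axis, the signed
#' variant resolves each frame's sign by temporal continuity (maximal dot
#' product with the previous frame's axis; first frame non-negative z),
#' which makes isotropically tumbling bodies uniform over [-1, 1]. The
#' `"folded"` variant histograms |V_z| instead, sidestepping the sign
#' convention entirely.
#'
#' @param traj a [trajectory()].
#' @param beads protein bead ids.
#' @param n_bins number of bins over [-1, 1].
#' @param variant `"signed"` (default) or `"folded"`.
#' @return list of class `orientation_histogram` with `breaks`, `mids`, `p`
#'   (probabilities summing to 1), `v_z` (per-frame values) and `variant`.
#' @export
orientation_distribution <- function(traj, beads, n_bins = 20,
                                     variant = c("signed", "folded")) {
  variant <- match.arg(variant)
  vz <- numeric(length(traj$frames))
  prev <- NULL
  for (k in seq_along(traj$frames)) {
    v <- principal_axis(traj$frames[[k]], beads)
    if (!is.null(prev) && sum(v * prev) < 0) v <- -v
    prev <- v
    vz[k] <- v[3]
  }
  if (variant == "folded") vz <- abs(vz)
  breaks <- seq(-1, 1, length.out = n_bins + 1)
  h <- tabulate(findInterval(vz, breaks, rightmost.closed = TRUE,
                             all.inside = TRUE), nbins = n_bins)
  structure(list(breaks = breaks,
                 mids = (breaks[-1] + breaks[-length(breaks)]) / 2,
                 p = h / sum(h), v_z = vz, variant = variant),
            class = "orientation_histogram")
}

#' Unit vector between centres of mass of two residue-set unions
#'
#' Direction from the centre of mass of the beads in `set_a` to that of
#' `set_b`. Beads carry equal masses unless the topology has a `mass`
#' column.
#'
#' @param fr a [frame()].
#' @param topology a [bead_topology()].
#' @param set_a,set_b residue-id vectors (unions are taken as given).
#' @return unit 3-vector.
#' @export
com_axis <- function(fr, topology, set_a, set_b) {
  com_of <- function(res_ids) {
    rows <- which(topology$molecule_class == "protein" &
                    topology$residue_id %in% res_ids)
    if (length(rows) == 0) stop("residue set selects no beads", call. = FALSE)
    w <- if ("mass" %in% names(topology)) topology$mass[rows]
    else rep(1, length(rows))
    colSums(fr$coords[rows, , drop = FALSE] * w) / sum(w)
  }
  v <- com_of(set_b) - com_of(set_a)
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("coincident centres of mass", call. = FALSE)
  v / n
}

#' Classify the binding pose of one bound frame
#'
#' Labels a bound frame by which site groups have at least one residue in
#' PIP2 contact: `"I_only"`, `"II_only"`, `"both"`, or `"neither"` (bound
#' through a residue outside both sites). Calling it on an unbound frame is
#' an error: pose is conditional on binding.
#'
#' @param fr a [frame()].
#' @param topology a [bead_topology()].
#' @param site_I,site_II disjoint [site_definition()]s.
#' @param params an [analysis_params()].
#' @return character label.
#' @export
classify_pose <- function(fr, topology, site_I, site_II,
                          params = analysis_params()) {
  check_sites_disjoint(list(site_I, site_II))
  prot <- protein_beads(topology)
  phos <- phosphate_beads(topology)
  if (length(phos) == 0) stop("topology has no PIP2 phosphate beads", call. = FALSE)
  d <- pair_distances(fr$coords[bead_rows(prot), , drop = FALSE],
                      fr$coords[bead_rows(phos), , drop = FALSE], fr$box)
  if (min(d) >= params$contact_cutoff) {
    stop("classify_pose called on an unbound frame", call. = FALSE)
  }
  bead_res <- topology$residue_id[bead_rows(prot)]
  in_contact <- unique(bead_res[apply(d < params$contact_cutoff, 1, any)])
  hitI <- any(in_contact %in% site_I$residue_ids)
  hitII <- any(in_contact %in% site_II$residue_ids)
  if (hitI && hitII) "both" else if (hitI) "I_only"
  else if (hitII) "II_only" else "neither"
}

#' Aggregate pose labels over bound frames
#'
#' Percentages of bound frames per pose class; the four classes partition
#' the bound frames and sum to 100.
#'
#' @param timeline a [binding_timeline()] built with site definitions.
#' @return data frame with columns `pose` and `pct`; attribute `n_bound`.
#'   With no bound frames, a zero-row frame with attribute `empty = TRUE`.
#' @export
aggregate_poses <- function(timeline) {
  lab <- timeline$pose[timeline$bound]
  labels <- c("I_only", "II_only", "both", "neither")
  if (length(lab) == 0) {
    out <- data.frame(pose = character(0), pct = numeric(0))
    attr(out, "empty") <- TRUE
    attr(out, "n_bound") <- 0L
    return(out)
  }
  if (any(is.na(lab))) {
    stop("timeline has bound frames without pose labels; ",
         "build it with site definitions", call. = FALSE)
  }
  pct <- 100 * vapply(labels, function(l) mean(lab == l), numeric(1))
  out <- data.frame(pose = labels, pct = unname(pct), stringsAsFactors = FALSE)
  attr(out, "empty") <- FALSE
  attr(out, "n_bound") <- length(lab)
  out
}
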