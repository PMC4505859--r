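# Contact statistics for protein-PIP2 association: the distance-based
# binding criterion, per-frame stoichiometry, residue-level contact
# occupancies x_i = n_i / N, lipid contact censuses, the residue selection
# rule, and the cutoff sensitivity sweep.

#' Analysis parameters
#'
#' @param contact_cutoff binding criterion in nm: the protein is bound in a
#'   frame when the minimal distance between any protein bead and any PIP2
#'   phosphate bead is strictly below this (default 0.52).
#' @param residue_thresh_major fraction: a residue is selected if its x_i
#'   strictly exceeds this in any single simulation (default 0.10).
#' @param residue_thresh_minor fraction: ... or strictly exceeds this in at
#'   least `min_sims_minor` simulations (default 0.05).
#' @param min_sims_minor count for the minor-threshold rule (default 2).
#' @param lipid_census_thresholds fractions at which the lipid census N_L is
#'   reported (default 0.05 and 0.10).
#' @param equilibration_skip ns of trajectory to drop before analysis
#'   (default 0: the full trajectory is analysed).
#' @param residue_contact_beads `"phosphate"` (default) to measure residue
#'   contacts to PIP2 phosphate beads only, matching the molecule-level
#'   criterion; `"all"` to use every PIP2 bead.
#' @param count_mode `"frames"` (default): n_i and N count frames;
#'   `"events"`: they count residue-lipid / protein-lipid contact events, so
#'   simultaneous multi-lipid contacts weigh more.
#' @return list of class `analysis_params`.
#' @export
analysis_params <- function(contact_cutoff = 0.52,
                            residue_thresh_major = 0.10,
                            residue_thresh_minor = 0.05,
                            min_sims_minor = 2,
                            lipid_census_thresholds = c(0.05, 0.10),
                            equilibration_skip = 0,
                            residue_contact_beads = c("phosphate", "all"),
                            count_mode = c("frames", "events")) {
  stopifnot(contact_cutoff >= 0,
            residue_thresh_major > 0, residue_thresh_major < 1,
            residue_thresh_minor > 0, residue_thresh_minor < 1,
            all(lipid_census_thresholds > 0 & lipid_census_thresholds < 1),
            equilibration_skip >= 0)
  p <- list(contact_cutoff = contact_cutoff,
            residue_thresh_major = residue_thresh_major,
            residue_thresh_minor = residue_thresh_minor,
            min_sims_minor = as.integer(min_sims_minor),
            lipid_census_thresholds = sort(lipid_census_thresholds),
            equilibration_skip = equilibration_skip,
            residue_contact_beads = match.arg(residue_contact_beads),
            count_mode = match.arg(count_mode))
  class(p) <- "analysis_params"
  p
}

# one-letter code for the residue labels used in result tables
one_letter <- function(resname) {
  map <- c(LYS = "K", ARG = "R", GLY = "G", ALA = "A", HIS = "H")
  out <- unname(map[resname])
  out[is.na(out)] <- "X"
  out
}

#' Minimal cross-group bead distance
#'
#' Minimum over all cross pairs of minimum-image Euclidean distance.
#'
#' @param fr a [frame()].
#' @param topology a [bead_topology()].
#' @param group_a,group_b nonempty bead-id sets (0-based).
#' @return distance in nm.
#' @export
min_distance <- function(fr, topology, group_a, group_b) {
  if (length(group_a) == 0 || length(group_b) == 0) {
    stop("bead groups must be nonempty", call. = FALSE)
  }
  min(pair_distances(fr$coords[bead_rows(group_a), , drop = FALSE],
                     fr$coords[bead_rows(group_b), , drop = FALSE],
                     fr$box))
}

# One pass over the trajectory computing everything the contact statistics
# need. Returns per-frame vectors and residue/lipid contact incidence.
scan_contacts <- function(traj, params = analysis_params(), with_pc = TRUE) {
  top <- traj$topology
  prot <- protein_beads(top)
  phos <- phosphate_beads(top)
  if (length(prot) == 0) stop("topology has no protein beads", call. = FALSE)
  if (length(phos) == 0) {
    stop("topology has no PIP2 phosphate beads", call. = FALSE)
  }
  res_target <- if (params$residue_contact_beads == "all") {
    class_beads(top, "PIP2")
  } else phos
  pc <- if (with_pc) class_beads(top, "DOPC") else integer(0)
  prot_rows <- bead_rows(prot)
  phos_rows <- bead_rows(phos)
  rt_rows <- bead_rows(res_target)
  pc_rows <- bead_rows(pc)
  res_ids <- top$residue_id[prot_rows]
  residues <- sort(unique(res_ids))
  phos_mol <- top$molecule_id[phos_rows]
  rt_mol <- top$molecule_id[rt_rows]
  pip_mols <- sort(unique(phos_mol))
  pc_mol <- top$molecule_id[pc_rows]
  pc_mols <- sort(unique(pc_mol))

  times <- vapply(traj$frames, function(f) f$time, numeric(1))
  keep <- times >= times[1] + params$equilibration_skip
  frames <- traj$frames[keep]
  nf <- length(frames)
  cut <- params$contact_cutoff

  min_dist <- numeric(nf)
  n_P <- integer(nf)
  res_contact <- matrix(FALSE, nf, length(residues))
  res_events <- matrix(0L, nf, length(residues))
  pip_contact <- matrix(FALSE, nf, length(pip_mols))
  pc_contact <- matrix(FALSE, nf, length(pc_mols))
  pc_bound <- logical(nf)

  for (k in seq_len(nf)) {
    fr <- frames[[k]]
    pxyz <- fr$coords[prot_rows, , drop = FALSE]
    d <- pair_distances(pxyz, fr$coords[phos_rows, , drop = FALSE], fr$box)
    min_dist[k] <- min(d)
    # molecule-level contact: any phosphate bead of the molecule within cutoff
    mol_hit <- tapply(apply(d, 2, min), phos_mol, min) < cut
    pip_contact[k, ] <- mol_hit[as.character(pip_mols)]
    n_P[k] <- sum(pip_contact[k, ])
    # residue-level contact to the configured PIP2 bead set
    dr <- if (identical(rt_rows, phos_rows)) d else
      pair_distances(pxyz, fr$coords[rt_rows, , drop = FALSE], fr$box)
    hit <- dr < cut
    # residue x molecule incidence
    rm_hit <- rowsum((hit %*% outer(rt_mol, pip_mols, "==")) * 1, res_ids) > 0
    res_events[k, ] <- as.integer(rowSums(rm_hit))
    res_contact[k, ] <- res_events[k, ] > 0
    if (length(pc_rows)) {
      dpc <- pair_distances(pxyz, fr$coords[pc_rows, , drop = FALSE], fr$box)
      pc_hit <- tapply(apply(dpc, 2, min), pc_mol, min) < cut
      pc_contact[k, ] <- pc_hit[as.character(pc_mols)]
      pc_bound[k] <- any(pc_contact[k, ])
    }
  }
  res_names <- top$residue_name[prot_rows][match(residues, res_ids)]
  list(time = times[keep], min_dist = min_dist, bound = min_dist < cut,
       n_P = n_P, residues = residues,
       residue_labels = paste0(one_letter(res_names), residues),
       res_contact = res_contact, res_events = res_events,
       pip_mols = pip_mols, pip_contact = pip_contact,
       pc_mols = pc_mols, pc_contact = pc_contact, pc_bound = pc_bound)
}

#' Per-frame binding timeline
#'
#' Applies the binding criterion frame by frame: the protein is bound when
#' the minimal distance between any of its beads and any PIP2 phosphate bead
#' is strictly less than the contact cutoff (a frame sitting exactly at the
#' cutoff is unbound). `n_P` counts the distinct PIP2 molecules with a
#' phosphate bead within the cutoff of any protein bead; it is >= 1 exactly
#' on bound frames. If site definitions are supplied, bound frames also get
#' a pose label (see [classify_pose()]).
#'
#' @param traj a [trajectory()].
#' @param params an [analysis_params()].
#' @param sites optional named list of [site_definition()]s (exactly two:
#'   site I and site II) for pose labelling.
#' @return data frame of class `binding_timeline` with columns `time`,
#'   `bound`, `n_P`, `min_dist`, `pose` (NA on unbound frames or when no
#'   sites are given).
#' @export
binding_timeline <- function(traj, params = analysis_params(), sites = NULL) {
  sc <- scan_contacts(traj, params, with_pc = FALSE)
  pose <- rep(NA_character_, length(sc$time))
  if (!is.null(sites)) {
    stopifnot(length(sites) == 2)
    check_sites_disjoint(sites)
    in_I <- sc$residues %in% sites[[1]]$residue_ids
    in_II <- sc$residues %in% sites[[2]]$residue_ids
    for (k in which(sc$bound)) {
      hitI <- any(sc$res_contact[k, in_I])
      hitII <- any(sc$res_contact[k, in_II])
      pose[k] <- if (hitI && hitII) "both" else if (hitI) "I_only"
      else if (hitII) "II_only" else "neither"
    }
  }
  tl <- data.frame(time = sc$time, bound = sc$bound, n_P = sc$n_P,
                   min_dist = sc$min_dist, pose = pose,
                   stringsAsFactors = FALSE)
  class(tl) <- c("binding_timeline", "data.frame")
  tl
}

#' Percentage of analysed time the protein is bound
#' @param timeline a [binding_timeline()].
#' @return percentage in [0, 100].
#' @export
binding_fraction <- function(timeline) 100 * mean(timeline$bound)

#' Distribution of binding stoichiometry
#'
#' Percentage of *bound* frames in which the protein simultaneously contacts
#' n_P = 1, 2, 3, or 4..`max_n` PIP2 molecules. The classes partition the
#' bound frames, so the percentages sum to 100 (the same normalisation that
#' makes each row of a per-simulation stoichiometry table sum to ~100
#' alongside a total binding percentage below 100).
#'
#' @param timeline a [binding_timeline()].
#' @param max_n largest stoichiometry in the pooled top class (default 6).
#' @return data frame with columns `n_P` (labels `"1"`, `"2"`, `"3"`,
#'   `"4-6"`) and `pct`; attribute `n_bound` carries the bound-frame count.
#'   With no bound frames, a zero-row frame with attribute `empty = TRUE`.
#' @export
stoichiometry_distribution <- function(timeline, max_n = 6) {
  if (nrow(timeline) == 0) stop("timeline is empty", call. = FALSE)
  np <- timeline$n_P[timeline$bound]
  labels <- c("1", "2", "3", paste0("4-", max_n))
  if (length(np) == 0) {
    out <- data.frame(n_P = character(0), pct = numeric(0))
    attr(out, "empty") <- TRUE
    attr(out, "n_bound") <- 0L
    return(out)
  }
  cls <- ifelse(np >= 4, labels[4], as.character(pmin(np, 3)))
  pct <- 100 * vapply(labels, function(l) mean(cls == l), numeric(1))
  out <- data.frame(n_P = labels, pct = unname(pct), stringsAsFactors = FALSE)
  attr(out, "empty") <- FALSE
  attr(out, "n_bound") <- length(np)
  out
}

#' Residue-level contact occupancy x_i = n_i / N
#'
#' For each protein residue, n_i counts the frames in which at least one of
#' its beads lies within the contact cutoff of a PIP2 phosphate bead, and N
#' counts the frames in which the protein as a whole is bound; x_i = n_i / N.
#' With `count_mode = "events"` both counts are over residue-lipid /
#' protein-lipid contact events instead of frames.
#'
#' @param traj a [trajectory()].
#' @param params an [analysis_params()].
#' @return data frame of class `contact_table` with columns `residue_id`,
#'   `label`, `n_i`, `x_i`; attributes `N` and `undefined` (TRUE when N = 0,
#'   in which case all x_i are NA).
#' @export
residue_contact_fraction <- function(traj, params = analysis_params()) {
  sc <- scan_contacts(traj, params, with_pc = FALSE)
  if (params$count_mode == "events") {
    n_i <- colSums(sc$res_events)
    N <- sum(sc$n_P)
  } else {
    n_i <- colSums(sc$res_contact)
    N <- sum(sc$bound)
  }
  x_i <- if (N > 0) n_i / N else rep(NA_real_, length(n_i))
  out <- data.frame(residue_id = sc$residues, label = sc$residue_labels,
                    n_i = as.integer(n_i), x_i = x_i,
                    stringsAsFactors = FALSE)
  attr(out, "N") <- N
  attr(out, "undefined") <- N == 0
  class(out) <- c("contact_table", "data.frame")
  out
}

#' Per-lipid contact fractions and the lipid census N_L
#'
#' For each lipid class (PIP2 and DOPC) separately: each lipid's contact
#' count n_L (frames in which it touches the protein under the class's
#' contact criterion) is normalised by the total number of frames in which
#' the protein touches *any* lipid of that class, giving per-lipid fractions
#' x_L. N_L at a threshold is the number of lipids with x_L strictly above
#' it; nested thresholds give nested censuses.
#'
#' @param traj a [trajectory()].
#' @param params an [analysis_params()].
#' @return list of class `lipid_census` with `per_lipid` (molecule_id,
#'   class, n_L, x_L), `census` (class, threshold, N_L),
#'   `pct_time_binding` (named, percentage of frames bound to each class)
#'   and `N_class` (the per-class normalising counts).
#' @export
lipid_contact_census <- function(traj, params = analysis_params()) {
  sc <- scan_contacts(traj, params)
  per <- list(); cen <- list()
  N_class <- c(PIP2 = sum(sc$bound), DOPC = sum(sc$pc_bound))
  pct <- c(PIP2 = 100 * mean(sc$bound), DOPC = 100 * mean(sc$pc_bound))
  for (cls in c("PIP2", "DOPC")) {
    mols <- if (cls == "PIP2") sc$pip_mols else sc$pc_mols
    mat <- if (cls == "PIP2") sc$pip_contact else sc$pc_contact
    if (length(mols) == 0) next
    n_L <- colSums(mat)
    x_L <- if (N_class[[cls]] > 0) n_L / N_class[[cls]] else rep(0, length(n_L))
    per[[cls]] <- data.frame(molecule_id = mols, class = cls,
                             n_L = as.integer(n_L), x_L = x_L,
                             stringsAsFactors = FALSE)
    cen[[cls]] <- data.frame(class = cls,
                             threshold = params$lipid_census_thresholds,
                             N_L = vapply(params$lipid_census_thresholds,
                                          function(th) sum(x_L > th),
                                          numeric(1)),
                             stringsAsFactors = FALSE)
  }
  structure(list(per_lipid = do.call(rbind, unname(per)),
                 census = do.call(rbind, unname(cen)),
                 pct_time_binding = pct, N_class = N_class),
            class = "lipid_census")
}

#' Select binding residues across simulations
#'
#' A residue is selected when its contact occupancy x_i strictly exceeds the
#' minor threshold (default 5%) in at least `min_sims_minor` simulations, or
#' strictly exceeds the major threshold (default 10%) in any single
#' simulation.
#'
#' @param x a simulations-by-residues matrix of x_i *fractions* with residue
#'   column names, or a `contact_matrix_fixture` (whose percentages are
#'   converted to fractions).
#' @param params an [analysis_params()].
#' @return character vector of selected residue labels, in column order.
#' @export
select_binding_residues <- function(x, params = analysis_params()) {
  if (inherits(x, "contact_matrix_fixture")) x <- x$values / 100
  x <- as.matrix(x)
  minor_n <- colSums(x > params$residue_thresh_minor)
  major <- apply(x > params$residue_thresh_major, 2, any)
  colnames(x)[minor_n >= params$min_sims_minor | major]
}

#' Mean and sd of the bound-frame minimal distance
#' @param timeline a [binding_timeline()].
#' @return list with `mean` and `sd` in nm (NA with attribute
#'   `no_bound_frames = TRUE` when never bound).
#' @export
mean_bound_distance <- function(timeline) {
  d <- timeline$min_dist[timeline$bound]
  if (length(d) == 0) {
    return(structure(list(mean = NA_real_, sd = NA_real_),
                     no_bound_frames = TRUE))
  }
  list(mean = mean(d), sd = if (length(d) > 1) stats::sd(d) else 0)
}

#' Time of the first bound frame
#' @param timeline a [binding_timeline()].
#' @return time in ns, or NA if the protein never binds.
#' @export
first_binding_time <- function(timeline) {
  if (!any(timeline$bound)) return(NA_real_)
  min(timeline$time[timeline$bound])
}

#' Residue contact occupancies across a ladder of contact cutoffs
#'
#' Recomputes each residue's contact occupancy at every cutoff, reported as
#' the fraction of analysed frames in which the residue touches a PIP2
#' phosphate bead. The denominator is fixed across the ladder (unlike the
#' per-run table convention x_i = n_i / N, whose denominator N itself grows
#' with the cutoff), so enlarging the cutoff can only add contact frames and
#' every residue's value is exactly non-decreasing; the identity of the
#' top-ranked residues is the cutoff-robustness diagnostic.
#'
#' @param traj a [trajectory()].
#' @param cutoffs numeric vector of cutoffs in nm.
#' @param params an [analysis_params()] (its `contact_cutoff` is ignored).
#' @return residues-by-cutoffs matrix of occupancies with residue labels as
#'   row names; attribute `N` holds the bound-frame count per cutoff and
#'   `n_frames` the (fixed) analysed-frame count.
#' @export
cutoff_sweep <- function(traj, cutoffs, params = analysis_params()) {
  cutoffs <- sort(cutoffs)
  cols <- lapply(cutoffs, function(cc) {
    p <- params; p$contact_cutoff <- cc
    residue_contact_fraction(traj, p)
  })
  times <- vapply(traj$frames, function(f) f$time, numeric(1))
  nf <- sum(times >= times[1] + params$equilibration_skip)
  m <- do.call(cbind, lapply(cols, function(tb) tb$n_i / nf))
  rownames(m) <- cols[[1]]$label
  colnames(m) <- format(cutoffs)
  attr(m, "N") <- vapply(cols, function(tb) attr(tb, "N"), numeric(1))
  attr(m, "n_frames") <- nf
  m
}

#' Per-frame minimal distance to each leaflet
#'
#' Distance from any protein bead to the nearest lipid bead of the
#' PIP2-containing leaflet and of the PIP2-free leaflet, per frame: the
#' leaflet-preference diagnostic for an asymmetric bilayer reachable from
#' both sides through the periodic boundary.
#'
#' @param traj a [trajectory()].
#' @return data frame with columns `time`, `dist_pip2_leaflet`,
#'   `dist_bare_leaflet`.
#' @export
leaflet_min_distance_series <- function(traj) {
  top <- traj$topology
  prot <- protein_beads(top)
  if (length(prot) == 0) stop("topology has no protein beads", call. = FALSE)
  pip_leaflets <- unique(top$leaflet[top$molecule_class == "PIP2"])
  if (length(pip_leaflets) != 1) {
    stop("need PIP2 confined to exactly one leaflet", call. = FALSE)
  }
  bare <- setdiff(c("upper", "lower"), pip_leaflets)
  g_pip <- leaflet_beads(top, pip_leaflets)
  g_bare <- leaflet_beads(top, bare)
  rows <- lapply(traj$frames, function(fr) {
    data.frame(time = fr$time,
               dist_pip2_leaflet = min_distance(fr, top, prot, g_pip),
               dist_bare_leaflet = min_distance(fr, top, prot, g_bare))
  })
  do.call(rbind, rows)
}
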