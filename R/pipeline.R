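# End-to-end orchestration from a YAML configuration: build the synthetic
# system, run the Brownian simulator, analyse the trajectory into the
# standard table set, and render a human-readable summary. Every stage is
# deterministic under the configuration seed and can write its artifacts to
# an output directory.

#' Load and validate a run configuration
#'
#' Reads a YAML configuration, fills unset fields from the packaged toy
#' defaults, and validates the result. Schema violations are reported with
#' dotted field paths (e.g. `system.pip2_fraction`).
#'
#' @param path YAML file; `NULL` loads the packaged toy configuration.
#' @param seed optional integer overriding the configuration seed.
#' @param overrides optional named list of overrides, with dotted paths as
#'   names (e.g. `list("simulation.n_steps" = 100)`).
#' @return validated configuration list of class `run_config`.
#' @export
load_run_config <- function(path = NULL, seed = NULL, overrides = NULL) {
  default_path <- system.file("extdata", "toy_config.yaml",
                              package = "pipbind", mustWork = TRUE)
  config <- yaml::read_yaml(default_path)
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    config <- modify_list_deep(config, user)
  }
  if (!is.null(overrides)) {
    for (i in seq_along(overrides)) {   # by index: duplicated names apply in order
      config <- set_path(config,
                         strsplit(names(overrides)[i], ".", fixed = TRUE)[[1]],
                         overrides[[i]])
    }
  }
  if (!is.null(seed)) config$seed <- as.integer(seed)
  validate_config(config)
}

modify_list_deep <- function(base, new) {
  for (nm in names(new)) {
    if (is.list(new[[nm]]) && is.list(base[[nm]]) &&
        !is.null(names(new[[nm]]))) {
      base[[nm]] <- modify_list_deep(base[[nm]], new[[nm]])
    } else {
      base[[nm]] <- new[[nm]]
    }
  }
  base
}

set_path <- function(x, path, value) {
  if (length(path) == 1) {
    x[[path]] <- value
  } else {
    x[[path[1]]] <- set_path(x[[path[1]]], path[-1], value)
  }
  x
}

#' Validate a run configuration
#'
#' @param config configuration list.
#' @return the configuration, classed `run_config`; stops with the offending
#'   field path on violation.
#' @export
validate_config <- function(config) {
  fail <- function(path, why) {
    stop("config schema error at '", path, "': ", why, call. = FALSE)
  }
  need_num <- function(path, lo = -Inf, hi = Inf) {
    v <- get_path(config, path)
    if (is.null(v) || !is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      fail(path, "must be a single finite number")
    }
    if (v < lo || v > hi) fail(path, paste0("must be in [", lo, ", ", hi, "]"))
    v
  }
  need_num("system.n_per_leaflet", 1)
  need_num("system.area_per_lipid", 1e-6)
  need_num("system.z_separation", 1e-6)
  need_num("system.box_z", 1e-6)
  need_num("system.pip2_fraction", 0, 1)
  need_num("system.gap", 0)
  need_num("system.n_ions", 0)
  need_num("system.protein.n_residues", 1)
  need_num("system.protein.radius", 1e-6)
  need_num("simulation.timestep", 1e-9)
  need_num("simulation.n_steps", 0)
  need_num("simulation.save_interval", 1)
  need_num("simulation.temperature", 0)
  need_num("simulation.debye_length", 1e-9)
  need_num("simulation.dielectric", 1e-9)
  need_num("analysis.contact_cutoff", 1e-9)
  lf <- get_path(config, "system.pip2_leaflet")
  if (is.null(lf) || !lf %in% c("upper", "lower")) {
    fail("system.pip2_leaflet", "must be 'upper' or 'lower'")
  }
  ids <- get_path(config, "system.protein.basic_residue_ids")
  nres <- get_path(config, "system.protein.n_residues")
  if (length(ids) > 0 && (any(ids < 1) || any(ids > nres))) {
    fail("system.protein.basic_residue_ids",
         paste0("ids must lie in 1..", nres))
  }
  if (is.null(config$seed) || !is.numeric(config$seed)) {
    fail("seed", "must be an integer")
  }
  if (!is.null(config$sites)) {
    if (!is.list(config$sites) || length(config$sites) != 2) {
      fail("sites", "must name exactly two residue groups")
    }
  }
  class(config) <- c("run_config", "list")
  config
}

get_path <- function(x, path) {
  for (p in strsplit(path, ".", fixed = TRUE)[[1]]) {
    x <- x[[p]]
    if (is.null(x)) return(NULL)
  }
  x
}

#' Hash of a resolved configuration
#' @param config configuration list.
#' @return md5 hex string of the canonical YAML serialisation.
#' @export
config_hash <- function(config) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  writeLines(yaml::as.yaml(unclass(config)), f)
  unname(tools::md5sum(f))
}

sub_seed <- function(seed, k) (as.integer(seed) %% 100000L) * 13L + k

config_sim_params <- function(config) {
  s <- config$simulation
  sim_params(timestep = s$timestep, n_steps = s$n_steps,
             save_interval = s$save_interval, temperature = s$temperature,
             friction = c(protein = s$friction_protein,
                          lipid = s$friction_lipid, ion = s$friction_ion),
             debye_length = s$debye_length, dielectric = s$dielectric,
             lj_sigma = s$lj_sigma, lj_epsilon = s$lj_epsilon,
             nonbond_cutoff = s$nonbond_cutoff,
             leaflet_restraint_k = s$leaflet_restraint_k,
             seed = sub_seed(config$seed, 2L))
}

config_analysis_params <- function(config) {
  a <- config$analysis
  analysis_params(contact_cutoff = a$contact_cutoff,
                  residue_thresh_major = a$residue_thresh_major,
                  residue_thresh_minor = a$residue_thresh_minor,
                  min_sims_minor = a$min_sims_minor,
                  lipid_census_thresholds = unlist(a$lipid_census_thresholds),
                  equilibration_skip = a$equilibration_skip)
}

config_sites <- function(config) {
  if (is.null(config$sites)) return(NULL)
  nms <- names(config$sites)
  out <- lapply(seq_along(nms), function(i) {
    site_definition(nms[i], unlist(config$sites[[i]]))
  })
  names(out) <- nms
  out
}

#' Build the configured system
#'
#' Bilayer + PIP2 replacement + toy protein + placement (+ ions), with the
#' elastic network over the protein beads. With `out_dir` set, writes
#' `system.gro`, `topology.tsv`, `elastic.tsv` and a composition log.
#'
#' @param config a [load_run_config()] result.
#' @param out_dir optional output directory (created if missing).
#' @return list with `system` (`topology` + `frame`), `elastic`, and
#'   `composition` (named counts).
#' @export
run_build <- function(config, out_dir = NULL) {
  config <- validate_config(config)
  sy <- config$system
  zc <- if (is.null(sy$z_center)) sy$box_z / 3 else sy$z_center
  bil <- build_bilayer(sy$n_per_leaflet, sy$area_per_lipid, sy$z_separation,
                       sy$box_z, z_center = zc)
  bil <- assign_pip2(bil, sy$pip2_fraction, sy$pip2_leaflet,
                     seed = sub_seed(config$seed, 1L),
                     head_charge = sy$pip2_charge)
  prot <- build_toy_protein(sy$protein$n_residues, sy$protein$radius,
                            unlist(sy$protein$basic_residue_ids),
                            basic_charge = sy$protein$basic_charge,
                            seed = sub_seed(config$seed, 3L))
  system <- place_protein(bil, prot, sy$gap)
  if (sy$n_ions > 0) {
    system <- add_ions(system, sy$n_ions, charge = sy$ion_charge,
                       seed = sub_seed(config$seed, 4L))
  }
  elastic <- build_elastic_network(system$frame,
                                   protein_beads(system$topology),
                                   cutoff = sy$protein$elastic_cutoff,
                                   k = sy$protein$elastic_k)
  composition <- c(
    DOPC = n_molecules(system$topology, "DOPC"),
    PIP2 = n_molecules(system$topology, "PIP2"),
    protein_beads = length(protein_beads(system$topology)),
    ions = n_molecules(system$topology, "ion"),
    elastic_bonds = nrow(elastic)
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_gro(file.path(out_dir, "system.gro"), system$topology, system$frame)
    write_topology_tsv(system$topology, file.path(out_dir, "topology.tsv"))
    write_elastic_tsv(elastic, file.path(out_dir, "elastic.tsv"))
    write_result_tsv(data.frame(quantity = names(composition),
                                count = as.integer(composition)),
                     file.path(out_dir, "composition.tsv"),
                     meta = run_meta(config))
  }
  list(system = system, elastic = elastic, composition = composition)
}

run_meta <- function(config, extra = list()) {
  c(list(seed = config$seed, config_hash = config_hash(config),
         label = if (is.null(config$label)) "run" else config$label), extra)
}

#' Simulate the configured system
#'
#' @param config a [load_run_config()] result.
#' @param built optional [run_build()] result (rebuilt if omitted).
#' @param out_dir optional output directory; writes `trajectory.gro` and
#'   `energies.tsv` (protein-PIP2 interaction energies per saved frame).
#' @return list with `trajectory`, `energies`, `params`, `built`.
#' @export
run_simulate <- function(config, built = NULL, out_dir = NULL) {
  config <- validate_config(config)
  if (is.null(built)) built <- run_build(config)
  params <- config_sim_params(config)
  traj <- bd_run(built$system$topology, built$system$frame, params,
                 elastic = built$elastic)
  pip <- class_beads(traj$topology, "PIP2")
  energies <- if (length(pip) > 0) {
    interaction_energy_series(traj, protein_beads(traj$topology), pip, params)
  } else {
    data.frame(time = numeric(0), electrostatic = numeric(0),
               van_der_waals = numeric(0))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_gro(file.path(out_dir, "trajectory.gro"), traj$topology,
              traj$frames)
    # the trajectory is only interpretable with its own topology (PIP2
    # placement depends on the run seed), so always write the sidecar
    write_topology_tsv(traj$topology, file.path(out_dir, "topology.tsv"))
    write_result_tsv(energies, file.path(out_dir, "energies.tsv"),
                     meta = run_meta(config))
  }
  list(trajectory = traj, energies = energies, params = params, built = built)
}

#' Analyse a trajectory into the standard table set
#'
#' Produces the binding timeline, the lipid-class comparison (binding
#' percentages and censuses), the stoichiometry distribution, the residue
#' contact-occupancy table, the pose-class percentages, the leaflet
#' minimal-distance series, and (when the system permits) RDF and
#' orientation profiles. With `out_dir` set, each table is written as TSV
#' with a reproducibility header.
#'
#' @param config a [load_run_config()] result.
#' @param traj a [trajectory()] (or a [run_simulate()] result).
#' @param out_dir optional output directory.
#' @return list of class `report_bundle`.
#' @export
run_analyze <- function(config, traj, out_dir = NULL) {
  config <- validate_config(config)
  if (!inherits(traj, "cg_trajectory") && !is.null(traj$trajectory)) {
    traj <- traj$trajectory
  }
  params <- config_analysis_params(config)
  sites <- config_sites(config)
  top <- traj$topology
  label <- if (is.null(config$label)) "run" else config$label
  has_pip <- length(phosphate_beads(top)) > 0

  if (!has_pip) {
    bundle <- list(label = label,
                   timeline = NULL,
                   lipid_comparison = NULL, stoichiometry = NULL,
                   residue_table = NULL, poses = NULL,
                   note = "no PIP2 in topology; binding analyses skipped")
    class(bundle) <- "report_bundle"
    return(bundle)
  }

  tl <- binding_timeline(traj, params, sites = sites)
  census <- lipid_contact_census(traj, params)
  stoich <- stoichiometry_distribution(tl)
  restab <- residue_contact_fraction(traj, params)
  poses <- if (!is.null(sites)) aggregate_poses(tl) else NULL
  leaflets <- leaflet_min_distance_series(traj)
  mbd <- mean_bound_distance(tl)

  lipid_comparison <- data.frame(
    simulation = label,
    class = names(census$pct_time_binding),
    pct_time_binding = unname(census$pct_time_binding),
    stringsAsFactors = FALSE
  )
  lipid_comparison <- merge(
    lipid_comparison,
    stats::reshape(census$census, idvar = "class", timevar = "threshold",
                   direction = "wide"),
    by = "class", all.x = TRUE)

  # RDF of PIP2 phosphates around PIP2 phosphates (needs >= 2 molecules)
  phos <- phosphate_beads(top)
  r_max <- min(traj$frames[[1]]$box[1:2]) / 2 * 0.99
  rdf_pip <- if (length(phos) >= 2) {
    rdf(traj, phos, phos, r_max = r_max, n_bins = 40, mode = "lateral")
  } else NULL
  ions <- class_beads(top, "ion")
  rdf_ion <- if (length(ions) > 0) {
    rdf(traj, phos, ions, r_max = min(traj$frames[[1]]$box) / 2 * 0.99,
        n_bins = 40, mode = "3d")
  } else NULL
  orient <- orientation_distribution(traj, protein_beads(top), n_bins = 20)

  bundle <- list(
    label = label, timeline = tl,
    binding_pct = binding_fraction(tl),
    first_binding = first_binding_time(tl),
    mean_bound_distance = mbd,
    lipid_comparison = lipid_comparison,
    stoichiometry = stoich,
    residue_table = restab,
    poses = poses,
    leaflet_series = leaflets,
    rdf_pip2 = rdf_pip, rdf_ion = rdf_ion,
    orientation = orient
  )
  class(bundle) <- "report_bundle"

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    meta <- run_meta(config, list(contact_cutoff = params$contact_cutoff,
                                  n_frames = length(traj$frames),
                                  n_beads = nrow(top)))
    write_result_tsv(tl, file.path(out_dir, "timeline.tsv"), meta)
    write_result_tsv(lipid_comparison,
                     file.path(out_dir, "lipid_comparison.tsv"), meta)
    write_result_tsv(stoich, file.path(out_dir, "stoichiometry.tsv"), meta)
    write_result_tsv(restab, file.path(out_dir, "residue_contacts.tsv"), meta)
    if (!is.null(poses)) {
      write_result_tsv(poses, file.path(out_dir, "poses.tsv"), meta)
    }
    write_result_tsv(leaflets, file.path(out_dir, "leaflet_distances.tsv"),
                     meta)
    if (!is.null(rdf_pip)) {
      write_result_tsv(data.frame(r = rdf_pip$r, g = rdf_pip$g),
                       file.path(out_dir, "rdf_pip2_pip2.tsv"), meta)
    }
    if (!is.null(rdf_ion)) {
      write_result_tsv(data.frame(r = rdf_ion$r, g = rdf_ion$g),
                       file.path(out_dir, "rdf_ion_pip2.tsv"), meta)
    }
    write_result_tsv(data.frame(v_z = orient$mids, p = orient$p),
                     file.path(out_dir, "orientation.tsv"), meta)
  }
  bundle
}

#' Render a report bundle as human-readable text
#'
#' One markdown summary per run; reports only numbers present in the bundle.
#'
#' @param bundle a [run_analyze()] result.
#' @return character vector of markdown lines.
#' @export
run_report <- function(bundle) {
  out <- c(sprintf("# Membrane-association run %s", bundle$label), "")
  if (!is.null(bundle$note)) {
    return(c(out, bundle$note))
  }
  if (is.null(bundle$timeline)) return(c(out, "(empty bundle)"))
  out <- c(out, sprintf("- frames analysed: %d", nrow(bundle$timeline)),
           sprintf("- %% time bound to PIP2: %.1f", bundle$binding_pct))
  if (is.finite(bundle$first_binding)) {
    out <- c(out, sprintf("- first binding at %.2f ns", bundle$first_binding))
  } else {
    out <- c(out, "- never bound")
  }
  if (!is.na(bundle$mean_bound_distance$mean)) {
    out <- c(out, sprintf("- mean bound distance: %.3f +/- %.3f nm",
                          bundle$mean_bound_distance$mean,
                          bundle$mean_bound_distance$sd))
  }
  if (!is.null(bundle$stoichiometry) && nrow(bundle$stoichiometry) > 0) {
    out <- c(out, "", "## Stoichiometry (% of bound frames)",
             sprintf("- n_P = %s: %.1f", bundle$stoichiometry$n_P,
                     bundle$stoichiometry$pct))
  }
  if (!is.null(bundle$residue_table)) {
    tb <- bundle$residue_table
    tb <- tb[order(-tb$x_i), ]
    top5 <- utils::head(tb[tb$n_i > 0, ], 5)
    if (nrow(top5) > 0) {
      out <- c(out, "", "## Top contact residues (x_i)",
               sprintf("- %s: %.3f", top5$label, top5$x_i))
    }
  }
  if (!is.null(bundle$poses) && nrow(bundle$poses) > 0) {
    out <- c(out, "", "## Pose classes (% of bound frames)",
             sprintf("- %s: %.1f", bundle$poses$pose, bundle$poses$pct))
  }
  out
}

#' Run the full pipeline (build, simulate, analyze, report)
#'
#' @param config a [load_run_config()] result.
#' @param out_dir optional output directory for all artifacts.
#' @return list with `built`, `sim`, `bundle`, `report`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  built <- run_build(config, out_dir)
  sim <- run_simulate(config, built, out_dir)
  bundle <- run_analyze(config, sim$trajectory, out_dir)
  report <- run_report(bundle)
  if (!is.null(out_dir)) {
    writeLines(report, file.path(out_dir, "report.md"))
  }
  list(built = built, sim = sim, bundle = bundle, report = report)
}

#' Residue ids forming a surface cluster on the toy protein lattice
#'
#' Picks the `k` residues whose lattice positions are nearest to a chosen
#' centre residue on the Fibonacci shell (jitter-free positions), giving a
#' contiguous surface patch - the standard way to plant a basic binding site
#' on the toy protein.
#'
#' @param n_residues shell size.
#' @param k patch size.
#' @param center centre residue id (default 1).
#' @return integer vector of `k` residue ids (including `center`).
#' @export
clustered_residue_ids <- function(n_residues, k, center = 1) {
  stopifnot(k >= 1, k <= n_residues, center >= 1, center <= n_residues)
  i <- seq_len(n_residues) - 0.5
  phi <- acos(1 - 2 * i / n_residues)
  theta <- pi * (1 + sqrt(5)) * i
  xyz <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  d <- sqrt(colSums((t(xyz) - xyz[center, ])^2))
  sort(order(d)[seq_len(k)])
}
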