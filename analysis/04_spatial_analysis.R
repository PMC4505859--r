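#!/usr/bin/env Rscript
# Spatial statistics for the three standard runs.
#
# Writes, under results/spatial/:
#   * lateral PIP2-PIP2 RDFs for run I with the protein present, and for a
#     protein-free control simulated at the same conditions (the
#     no-recruitment comparison),
#   * signed and folded orientation histograms of the protein principal
#     axis V_z for each run,
#   * the pose-class table (only site I / only site II / both / neither, %
#     of bound frames) across runs,
#   * per-run leaflet minimal-distance series (PIP2-containing vs bare).

suppressMessages(library(pipbind))
dir.create("results/spatial", recursive = TRUE, showWarnings = FALSE)

labels <- c("I", "II", "III")
pose_rows <- NULL
for (label in labels) {
  run_dir <- file.path("results/runs", label)
  cfg <- validate_config(yaml::read_yaml(file.path(run_dir, "config.yaml")))
  top <- read_topology_tsv(file.path(run_dir, "topology.tsv"))
  traj <- trajectory(top, read_gro(file.path(run_dir, "trajectory.gro"))$frames)

  for (variant in c("signed", "folded")) {
    h <- orientation_distribution(traj, protein_beads(top), n_bins = 20,
                                  variant = variant)
    write_result_tsv(data.frame(v_z = h$mids, p = h$p),
                     sprintf("results/spatial/orientation_%s_%s.tsv",
                             label, variant), meta = list(seed = cfg$seed))
  }
  sites <- list(site_definition("Site I", unlist(cfg$sites[[1]])),
                site_definition("Site II", unlist(cfg$sites[[2]])))
  tl <- binding_timeline(traj, sites = sites)
  po <- aggregate_poses(tl)
  if (!attr(po, "empty")) pose_rows <- rbind(pose_rows,
                                             cbind(run = label, po))
  ls <- leaflet_min_distance_series(traj)
  write_result_tsv(ls, sprintf("results/spatial/leaflets_%s.tsv", label),
                   meta = list(seed = cfg$seed))
  pref <- c(pip2 = mean(ls$dist_pip2_leaflet < 0.52),
            bare = mean(ls$dist_bare_leaflet < 0.52))
  cat(sprintf("run %-3s: %% frames within cutoff of PIP2 leaflet %5.1f, bare %5.1f\n",
              label, 100 * pref[["pip2"]], 100 * pref[["bare"]]))
}
write_result_tsv(pose_rows, "results/spatial/pose_classes.tsv",
                 meta = list(runs = paste(labels, collapse = ",")))
cat("\npose classes (% of bound frames):\n")
print(pose_rows, row.names = FALSE)

# PIP2-PIP2 RDF with and without the protein
cfgI <- validate_config(yaml::read_yaml("results/runs/I/config.yaml"))
top <- read_topology_tsv("results/runs/I/topology.tsv")
trajI <- trajectory(top, read_gro("results/runs/I/trajectory.gro")$frames)
phos <- phosphate_beads(top)
r_max <- min(trajI$frames[[1]]$box[1:2]) / 2 * 0.99
g_with <- rdf(trajI, phos, phos, r_max = r_max, n_bins = 24, mode = "lateral")

cfg0 <- load_run_config(seed = cfgI$seed,
                        overrides = list("system.protein.n_residues" = 1,
                                         "system.protein.basic_residue_ids" = list(),
                                         "system.protein.basic_charge" = 0,
                                         "system.gap" = 4.0,
                                         "label" = "no-protein-control"))
sim0 <- run_simulate(cfg0)
top0 <- sim0$trajectory$topology
g_without <- rdf(sim0$trajectory, phosphate_beads(top0),
                 phosphate_beads(top0), r_max = r_max, n_bins = 24,
                 mode = "lateral")
write_result_tsv(data.frame(r = g_with$r, g_with_protein = g_with$g,
                            g_without_protein = g_without$g),
                 "results/spatial/rdf_pip2_pip2.tsv",
                 meta = list(seed = cfgI$seed))
ks <- suppressWarnings(stats::ks.test(g_with$g, g_without$g))
cat(sprintf("\nPIP2-PIP2 RDF with vs without protein: KS p = %.3f\n",
            ks$p.value))
cat(if (ks$p.value > 0.05) {
  "the protein leaves the global PIP2 distribution unperturbed here\n"
} else {
  paste("local PIP2 enrichment under the protein is detectable at this",
        "patch size:\nwith only 5 PIP2 in a 5.6 nm patch, gathering 2-3",
        "under the protein shifts\nthe global g(r) - a scale effect the",
        "full-size bilayer (33 PIP2, 15.2 nm)\nwould dilute\n")
})
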