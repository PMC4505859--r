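# Full-scale synthetic geometry: a 331-lipid-per-leaflet bilayer (15.2 nm
# edge at 0.698 nm^2 per lipid) with 10% of the upper leaflet replaced by
# PIP2 (33 PIP2 / 629 DOPC) in a 19.1 nm-tall box, and the protein placed
# 4.5 nm above the upper head-group plane (the most distant of the standard
# 4.5 / 2.5 / 1.5 nm starting gaps). Simulation settings inherit from the
# toy configuration; trajectories at this size are for demonstration runs,
# not for the test suite.
system:
  n_per_leaflet: 331
  area_per_lipid: 0.698
  z_separation: 4.0
  box_z: 19.1
  pip2_fraction: 0.10
  pip2_leaflet: upper
  pip2_charge: -5
  gap: 4.5
  n_ions: 0
  ion_charge: 1
  protein:
    n_residues: 50
    radius: 1.6
    basic_residue_ids: [1, 2, 3, 5, 6, 7]
    basic_charge: 1
    elastic_cutoff: 0.9
    elastic_k: 500
label: I
seed: 1
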