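# Packaged toy conditions: a small PIP2-enriched bilayer patch and a rigid
# 30-residue protein carrying two basic surface patches (~90 degrees apart,
# mirroring a two-site binding surface), simulated with Brownian dynamics for
# 80 ns - long enough for diffusive approach and multiple transient,
# electrostatically driven binding and unbinding events. All lengths nm,
# times ns, energies kJ/mol, charges e.
system:
  n_per_leaflet: 49
  area_per_lipid: 0.64
  z_separation: 4.0
  box_z: 11.0
  z_center: 2.5
  pip2_fraction: 0.10
  pip2_leaflet: upper
  pip2_charge: -5
  gap: 1.5
  n_ions: 0
  ion_charge: 1
  protein:
    n_residues: 30
    radius: 1.2
    basic_residue_ids: [1, 3, 4, 10, 15, 23]
    basic_charge: 3
    elastic_cutoff: 0.9
    elastic_k: 500
simulation:
  timestep: 0.005
  n_steps: 16000
  save_interval: 40
  temperature: 320
  friction_protein: 1.5
  friction_lipid: 30
  friction_ion: 5
  debye_length: 0.78
  dielectric: 78
  lj_sigma: 0.47
  lj_epsilon: 2.0
  nonbond_cutoff: 1.2
  leaflet_restraint_k: 100
analysis:
  contact_cutoff: 0.52
  residue_thresh_major: 0.10
  residue_thresh_minor: 0.05
  min_sims_minor: 2
  lipid_census_thresholds: [0.05, 0.10]
  equilibration_skip: 0
sites:
  "Site I": [1, 3, 4]
  "Site II": [10, 15, 23]
label: toy
seed: 1
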