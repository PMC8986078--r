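name: control
notes: >
  Control-like islet sorting condition: beta-beta contacts strongly
  adhesive, beta to alpha/delta weakly adhesive, non-beta pairs weaker
  still, no perturbation. 15000 Metropolis sweeps at temperature 0.8
  anneal the pattern into a beta core with an alpha/delta mantle.
  Calibrated jointly with nicd.yaml so that the perturbed-to-control
  ratio of the core alpha-cell percentage (mantle depth 1.5 median cell
  diameters, boundary reconstructed from the cell disks) is 2.5.
n_alpha: 20
n_beta: 70
n_delta: 10
domain_radius: 57
cell_radius: 3.5
adhesion:
  alpha: {alpha: -0.3, beta: -0.4, delta: -0.3}
  beta: {alpha: -0.4, beta: -2.0, delta: -0.4}
  delta: {alpha: -0.3, beta: -0.4, delta: -0.3}
repulsion_beta: 0.0
frac_perturbed_beta: 0.0
temperature: 0.8
n_steps: 15000
pixel_size: 1
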