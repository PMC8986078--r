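name: nicd
notes: >
  Notch-active (NICD-like) condition: identical to control.yaml except
  that every beta cell is flagged perturbed and all its contacts pay an
  extra repulsion energy of 2.0, modelling cell-autonomous ephrin-driven
  contact repulsion. The repulsion strength is a modelling choice, not a
  measured constant: it was calibrated so the ground-truth core
  alpha-cell percentage is 2.5 times the control value under the same
  measurement settings.
n_alpha: 20
n_beta: 70
n_delta: 10
domain_radius: 57
cell_radius: 3.5
adhesion:
  alpha: {alpha: -0.3, beta: -0.4, delta: -0.3}
  beta: {alpha: -0.4, beta: -2.0, delta: -0.4}
  delta: {alpha: -0.3, beta: -0.4, delta: -0.3}
repulsion_beta: 2.4
frac_perturbed_beta: 1.0
temperature: 0.8
n_steps: 15000
pixel_size: 1
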