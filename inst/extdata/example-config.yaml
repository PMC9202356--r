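# Example run configuration for run_pipeline() / read_run_config().
#
# Global settings (all optional; defaults shown):
#   n_states:   13        alchemical windows, uniform global lambda on [0, 1]
#   scheme:     one_step  lambda schedule convention (one_step | two_step)
#   n_samples:  1000      samples per window per replica
#   n_replicas: 5         ensemble size per window
#   autocorr_rho: 0       lag-1 autocorrelation of the generated series
#   estimators: [TI, MBAR]
#   n_boot:     5000      bootstrap resamples
#   overlap_threshold: 0.03
#   significance_z: 1
#   distribution_min_replicas: 48
#   master_seed: 1
#
# Each transformation defines its solvent and complex legs as Gaussian-chain
# endpoint parameters: kf (force constants, reduced energy/length^2), mu
# (centers), offset (reduced-energy offsets). The closed-form chain ddG is
# used as the reference unless reference_ddg is given (kcal/mol).
n_states: 13
n_samples: 1000
n_replicas: 5
n_boot: 5000
master_seed: 1
transformations:
  - name: t1
    solvent:
      kf: [1.0, 2.0]
      mu: [0.0, 0.5]
    complex:
      kf: [1.0, 4.0]
      mu: [0.0, 1.0]
  - name: t2
    solvent:
      kf: [1.0, 1.5]
    complex:
      kf: [1.5, 3.0]
      offset: [0.0, 0.4]
  - name: t3
    solvent:
      kf: [2.0, 1.0]
    complex:
      kf: [2.0, 2.5]
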