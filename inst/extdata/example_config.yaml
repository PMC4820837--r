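# Reduced example configuration: 4 simulated subjects, 2 runs,
# hippocampus-like ROI plus one flat control ROI of 48 voxels each.
seed: 7
n_subjects: 4
design:
  n_runs: 2
rois:
  HIPP:
    n_voxels: 48
    n_units: 120
    c_global: {NoFace: 0.10, DifferentFace: 0.18, SameFace: 0.18}
    c_pair: {NoFace: 0.15, DifferentFace: -0.03, SameFace: -0.15}
  EVC:
    n_voxels: 48
    n_units: 120
    c_global: {NoFace: 0.20, DifferentFace: 0.20, SameFace: 0.20}
    c_pair: {NoFace: 0.20, DifferentFace: 0.20, SameFace: 0.20}
noise:
  sigma: 1.0
  ar1_phi: 0.3
glm:
  prewhiten: ar1
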