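# Demo configuration for runPipeline(): a 8 x 8 mm synthetic landscape
# section carried through imaging, profiling, flow/transport, a short
# rate/diffusivity fit, and landscape upscaling.
seed: 4
stages:
  - synth
  - imaging
  - profiles
  - hydro
  - fit
  - upscale
synth:
  domain_size_mm: [8.0, 8.0]
  pixel_mm: 0.1
  axial_mm: 0.02
hydro:
  nx: 48
  nz: 48
  u_bulk: 0.1
  rate: -0.001
fit:
  free: [R, C]
  maxit: 60
  restarts: 1
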