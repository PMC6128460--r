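# Example configuration for: paretoprior.R rank --config example-rank-config.yaml
# Layer paths are relative to the working directory. `criteria` may be one of
# the named presets (FS, HS, FG, HG, FSG, HSG) instead of an explicit list.
layers:
  nfires: attrs/nfires.asc
  pr_ign: attrs/pr_ign.asc
  frid: attrs/frid.asc
  plant: attrs/plant.asc
  herp: attrs/herp.asc
  bird: attrs/bird.asc
  mamm: attrs/mamm.asc
mask: inputs/mask.asc
criteria:
  attribute: [nfires, pr_ign, frid, plant, herp, bird, mamm]
  direction:
    - higher_is_priority
    - higher_is_priority
    - lower_is_priority
    - higher_is_priority
    - higher_is_priority
    - higher_is_priority
    - higher_is_priority
prefix: FS
out_dir: ranks
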