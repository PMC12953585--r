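# Demo pipeline configuration: simulate a three-lineage wolf cohort and run
# every analysis stage at desk scale. Run with
#   lupus-popgen run --config demo_config.yaml
out_dir: lupuspg_demo
seed: 7
simulation:
  model: default_wolf
  samples_per_pop: {Indian: 4, Tibetan: 2, Holarctic: 4, SWAsia: 6,
                    Outgroup1: 2, Outgroup2: 2}
stages: {dstat: true, topoweights: true, roh: true, diversity: true,
         load: true, sfsfit: true}
options:
  dstat:
    quartet: [Holarctic, SWAsia, Indian, Outgroup1]
  topoweights:
    groups: [Indian, SWAsia, Holarctic, Outgroup1]
    max_per_group: 2
    max_windows: 400
  load:
    outgroups: [Outgroup1, Outgroup2]
  sfsfit:
    pops: [Indian, SWAsia, Holarctic]
    subsample: [2, 3, 3]
    models: [A, B]
    n_loci: 2000
    grid_points: 3
    refine_iter: 0
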