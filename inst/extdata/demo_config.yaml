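# Demo pipeline configuration: small cohort so the end-to-end run stays fast.
n: 250
seed: 3
out_dir: pipeline_demo
profile: atlantis_experimental
regimen:
  lrb_dose: 2.0
  dox_dose: 40
counterfactual_lrb_dose: 3.2
n_boot: 30
n_replicates: 20
test_fraction: 0.3
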