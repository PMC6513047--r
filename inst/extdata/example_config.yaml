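# Example octsum run configuration (see ?runConfig for all keys).
# Any omitted key keeps its package default.
cohort:
  nVolumes: 8
  fracNormal: 0.3
  pArtifact: 0.5
phantom:
  nSlices: 24
  speckle: 0.2
preprocess:
  sigma: 6.0
train:
  learningRate: 1.0e-4
  maxEpochs: 5
  batchSize: 16
  stopRule: val_auc_plateau
  patience: 3
summary:
  gapT: 3
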