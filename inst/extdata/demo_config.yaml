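# Demonstration pipeline configuration: a small noiseless laminar slab.
phantom:
  shape: [32, 32, 32]
  spacing: 50          # micrometres
  laminaPeriod: 150
  intersticeFraction: 0.4
st:
  dtw: 3
  stw: 3
  nLevels: 2           # 50 -> 100 -> 200 micrometres
dti:
  nDir: 6
  bValue: 1000         # s/mm^2
  S0: 100
  noiseSigma: 0
fi:
  factor: 4            # 50 -> 12.5 micrometres
  kThreshold: 7.0
  minFaces: 10
normal: [0.333333333333, 0.666666666667, 0.666666666667]
seed: 1
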