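# Demonstration pipeline configuration. Every physical constant of the
# modelled recordings appears here as a named default so deviations are
# visible diffs.
seed: 1
outDir: hergfit-demo
nTrain: 500          # synthetic training examples
valFraction: 0.2
nCells: 10           # benchmark cells
sigma: 10.84         # recording-noise SD, pA
factor: 50           # decimation: 5 kHz -> 100 Hz
sampleRate: 5000.0   # simulation rate, Hz
maxIter: 300         # CMA-ES iteration cap for the benchmark
regressor:
  channels: [12, 24, 48]
  hidden: 96
  batchSize: 32
  learningRate: 1.0e-3
  schedule:
    - resolution: 33
      fraction: 0.6
      epochs: 16
    - resolution: 49
      fraction: 1.0
      epochs: 10
      lr: 5.0e-4
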