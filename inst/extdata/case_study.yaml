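# Case-study run configuration: endogenous normalization, NA threshold 10%,
# RT-efficiency threshold 5 cycles. Input paths are relative; override them
# with readRunConfig(path, counts = ..., annotation = ..., metadata = ...,
# outputDir = ...) or the corresponding mirct CLI flags.
counts: counts.csv
annotation: annotation.csv
metadata: metadata.csv
outputDir: results
maxNaFraction: 0.10
rtThreshold: 5
rtForm: difference
normalization: endogenous
alpha: 0.05
adjust: BH
evidence: both
minSources: 1
seed: 42
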