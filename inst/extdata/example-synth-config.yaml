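# Example generator configuration (desk scale).
# Use with the CLI:  Rscript inst/cli/mtcsn.R generate --config <this> --out DIR
imageHeight: 96
imageWidth: 96
nSamples: 100
blurKernelLength: 9
blurProb: 0.24
bubbleCountRange: [0, 5]
excretaCoverageRange: [0.0, 0.7]
reflectionProb: 0.5
tauInvisible: 0.4
tauBlur: 0.25
seed: 7
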