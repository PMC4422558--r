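substrate,rate_per_h
succinate,0.46
pyruvate,0.61
oxaloacetate,0.79
glycerol,0.63
glucose,0.85
mannose,0.42
xylose,0.61
maltose,0.67
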