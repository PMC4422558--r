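substrate_1,substrate_2,rate_per_h,group
mannose,succinate,0.64,A
mannose,pyruvate,0.70,A
mannose,oxaloacetate,0.87,A
xylose,succinate,0.71,A
xylose,pyruvate,0.80,A
xylose,oxaloacetate,0.88,A
glycerol,succinate,0.73,A
glycerol,pyruvate,0.85,A
glycerol,oxaloacetate,0.93,A
maltose,succinate,0.77,A
maltose,pyruvate,0.85,A
maltose,oxaloacetate,0.90,A
glucose,succinate,0.86,A
glucose,pyruvate,0.88,A
glucose,oxaloacetate,0.94,A
mannose,glycerol,0.65,B
xylose,glycerol,0.64,B
maltose,glycerol,0.70,B
mannose,glucose,0.84,B
xylose,glucose,0.84,B
maltose,glucose,0.84,B
glycerol,glucose,0.84,B
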