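model,peak,shift_ppm,rel_amp
phantom,P1,-3.93,0.082
phantom,P2,-3.51,0.623
phantom,P3,-3.22,0.015
phantom,P4,-2.79,0.096
phantom,P5,-2.57,0.048
phantom,P6,-2.05,0.009
phantom,P7,-0.73,0.026
phantom,P8,-0.51,0.018
phantom,P9,0.52,0.083
invivo,P1,-3.66,0.083
invivo,P2,-3.24,0.688
invivo,P3,-2.91,0.010
invivo,P4,-2.49,0.098
invivo,P5,-2.27,0.042
invivo,P6,-1.71,0.006
invivo,P7,-0.39,0.013
invivo,P8,0.78,0.060
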