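# AMP singly deuterated at ring position 5 (FTMW only; distortion
# constants held at parent values).
species: AMP-d5
states:
  ground:
    A: 5778.43386
    B: 2613.82591
    C: 1801.46262
    DJ: 0.137393
    DJK: 0.202569
    DK: 0.93701
    dJ: 0.0458083
    dK: 0.365563
    HK: 0.000605
hyperfine:
  Na: {chi32aa: 3.6005, bbcc4: 1.5056}
  Nr: {chi32aa: -0.048, bbcc4: -1.1695}
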