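# AMP singly deuterated at ring position 6 (FTMW only; distortion
# constants held at parent values).
species: AMP-d6
states:
  ground:
    A: 5485.85599
    B: 2700.45410
    C: 1811.36749
    DJ: 0.137393
    DJK: 0.202569
    DK: 0.93701
    dJ: 0.0458083
    dK: 0.365563
    HK: 0.000605
hyperfine:
  Na: {chi32aa: 3.5732, bbcc4: 1.5021}
  Nr: {chi32aa: 0.226, bbcc4: -1.2171}
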