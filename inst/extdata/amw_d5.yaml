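species: AMW-d5
states:
  ground:
    A: 3640.3373
    B: 1354.60499
    C: 989.28824
    DJ: 0.2533
    DJK: 0.419
    DK: 2.21
    dJ: 0.0588
    dK: 0.612
hyperfine:
  Na: {chi32aa: 3.113, bbcc4: 1.542}
  Nr: {chi32aa: -4.821, bbcc4: -0.1455}
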