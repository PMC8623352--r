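species: AMW-d6
states:
  ground:
    A: 3558.6210
    B: 1383.47362
    C: 998.26318
    DJ: 0.2279
    DJK: 0.419
    DK: 2.21
    dJ: 0.0588
    dK: 0.612
hyperfine:
  Na: {chi32aa: 2.975, bbcc4: 1.5513}
  Nr: {chi32aa: -4.816, bbcc4: -0.1256}
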