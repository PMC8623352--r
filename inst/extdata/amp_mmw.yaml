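# Reference constants for the two amine-inversion sublevels of AMP from
# room-temperature millimetre-wave spectroscopy.
species: AMP
states:
  "0+":
    A: 5780.37487
    B: 2733.50446
    C: 1857.675172
    DJ: 0.137392
    DJK: 0.202586
    DK: 0.93717
    dJ: 0.0458083
    dK: 0.365545
    HK: 0.000643
  "0-":
    A: 5778.56502
    B: 2730.18938
    C: 1857.14913
    DJ: 0.137264
    DJK: 0.203231
    DK: 0.93003
    dJ: 0.0456266
    dK: 0.364984
    HK: 0.000571
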