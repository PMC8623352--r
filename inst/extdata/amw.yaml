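# Reference experimental constants: the 1:1 2-aminopyridine-water cluster
# (AMW), parent species, FTMW measurements.
species: AMW
states:
  ground:
    A: 3722.8201
    B: 1384.23544
    C: 1011.15836
    DJ: 0.2058
    DJK: 0.419
    DK: 2.21
    dJ: 0.0588
    dK: 0.612
hyperfine:
  Na: {chi32aa: 3.0091, bbcc4: 1.55556}
  Nr: {chi32aa: -4.8756, bbcc4: -0.1284, chi_ab: 1.43}
extra:
  mu: [0.86, 0.17, 0.0]         # a-type dominant in the cluster
  theta_za_calc: 18.3           # deg, computed diagonalization angle
  theta_str_calc: 19.9          # deg, computed structural angle
  efg_scale_factor: 0.941       # computed-to-experimental EFG scaling
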