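# Reference experimental spectroscopic constants: 2-aminopyridine (AMP),
# parent species, global fit to combined FTMW + MMW + CMW measurements.
# Units: A,B,C MHz; DJ..dK kHz; HK Hz; hyperfine parameters MHz.
species: AMP
states:
  ground:
    A: 5780.374597
    B: 2733.504446
    C: 1857.675169
    DJ: 0.137393
    DJK: 0.202569
    DK: 0.93701
    dJ: 0.0458083
    dK: 0.365563
    HK: 0.000605
hyperfine:
  Na: {chi32aa: 3.5854, bbcc4: 1.50413}
  Nr: {chi32aa: -0.0789, bbcc4: -1.15823, chi_ab: 2.92}
extra:
  mu: [0.166, 0.86, 0.0]        # Debye, ground-state dipole components
  theta_za_exp_Nr: 55.5         # deg, from tensor diagonalization
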