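# Experimental ground-state principal moments of inertia (u A^2) of the
# AMW cluster and its two ring-deuterated isotopologues (rows: parent,
# d-5, d-6), the nine observables of the three-parameter r0 structure fit.
Ia Ib Ic
135.7523 365.0978 499.8001
138.8246 373.0822 510.8523
142.0154 365.2971 506.2585
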