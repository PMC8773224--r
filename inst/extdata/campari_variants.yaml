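# CaMPARI2 variant table: Ca2+ affinity (kd_nM) and, where calibrated,
# conversion hazards of the Ca2+-free and Ca2+-bound states (per s).
# K_D is published for CaMPARI2 and CaMPARI2-F391W only. Hazards are
# left null: the two-point mechanistic calibration at the published
# K_D values and basal Ca2+ is infeasible (see the methods vignette);
# per-condition hazards are set empirically with calibrateEmpirical().
variants:
  - name: CaMPARI2
    kd_nM: 199.2
    hill_n: 1
    k_free: null
    k_bound: null
  - name: CaMPARI2-F391W
    kd_nM: 109.7
    hill_n: 1
    k_free: null
    k_bound: null
  - name: CaMPARI2-H396K
    kd_nM: null
    hill_n: 1
    k_free: null
    k_bound: null
  - name: CaMPARI2-F391W-G395D
    kd_nM: null
    hill_n: 1
    k_free: null
    k_bound: null
  - name: CaMPARI2-L398T
    kd_nM: null
    hill_n: 1
    k_free: null
    k_bound: null
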