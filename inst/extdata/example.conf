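# zobmol configuration: key: value pairs
# metals considered for organometallic classification (comma-separated)
metals: Hf, Co, Zr, W, Ni, Pt, Os, Ti, Rh, Fe
# standard valence table used by the hydrogen rules
valences: C=4, N=3, P=3, O=2, S=2
# molfile property tag carrying explicit hydrogen counts
hcount_tag: ZHC
# expand HOSE spheres through metal atoms
hose_through_metals: yes
# prediction reliability thresholds
warn_spheres: 3
min_examples: 2
# aggregation of matched reference shifts
aggregate: mean
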