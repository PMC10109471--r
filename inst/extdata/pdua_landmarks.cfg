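# Landmark maps: role = residue number(s), PduA-style numbering per protein.
# Two-residue roles are comma-separated; unstated roles fall back to the
# PduA defaults.

[PduA]
lys_edge = 26
bend_pair = 27, 38
tilt_pair = 24, 18
plane_probe = 54
arg_insert = 79
pocket_acid = 83
saltbridge_pair = 28, 49
core_range = 1, 90
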