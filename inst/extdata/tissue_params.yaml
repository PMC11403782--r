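# 3 T literature relaxation times (ms) and gadolinium relaxivities
# (L/mmol/s). Relaxivities are medium-dependent, not field-dependent.
# Blood values are for fully oxygenated blood (longest T2), matching the
# long-TE blood-suppression rationale; hct is informational only.
#
# printed_with_gd records published post-contrast values for reference.
# Note they are mutually inconsistent under 1/T_Gd = 1/T_0 + r*[Gd]
# for blood (T1 implies ~1.02 mmol/L, T2 implies ~1.37 mmol/L); the
# package always computes post-contrast relaxation from the equations
# and never uses these printed numbers.
csf:
  T1_0: 4310
  T2_0: 1400
  r1: 2.8
  r2: 3.4
  printed_with_gd: {c: 0.2, T1: 1262, T2: 717}
blood:
  T1_0: 1878
  T2_0: 157
  r1: 4.4
  r2: 5.5
  hct: 0.43
  printed_with_gd: {T1: 199, T2: 72}
gm:
  T1_0: 1607
  T2_0: 63
  r1: 0
  r2: 0
wm:
  T1_0: 838
  T2_0: 77
  r1: 0
  r2: 0
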