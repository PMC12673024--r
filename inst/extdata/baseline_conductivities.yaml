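# Baseline tissue conductivities and reference tissue state.
#
# Per-axis conductivities in S/m (fiber, transverse, sheet-normal). Values
# sit in the upper part of the experimentally reported range so that the
# reference tissue conducts at ~75 cm/s along the fiber: with physiological
# activation mimicked by pacing a handful of endocardial surface sites
# (no explicit His-Purkinje system), tissue-level velocities this fast are
# the standard way to reproduce realistic total activation times. The
# monodomain (harmonic) combination keeps a ~8x fiber/cross-fiber
# anisotropy.
sigma_i:          # intracellular
  fiber: 0.28
  transverse: 0.030
  normal: 0.030
sigma_e:          # extracellular (at the reference ECV, no fibrosis)
  fiber: 1.00
  transverse: 0.38
  normal: 0.38
cm_uF_cm2: 1.0    # tissue membrane capacitance per unit area
ecv_ref: 0.258    # reference extracellular volume fraction
r_ref_um: 15.45   # reference cell radius (um)
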