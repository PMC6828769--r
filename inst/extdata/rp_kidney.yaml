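# Operating data for the RP disposable flat-plate artificial kidney.
# Flows are device totals over the eight blood compartments; the entrance
# pressure is the trans-membrane pressure difference (back pressure p_m = 0).
L.cm: 42.0
t.cm: 2.59e-3
w.cm: 11.6
n_compartments: 8
a.cm: 9.0e-3
p_i_tilde.mmHg: 150.0
mu.dyn_s_cm2: 6.9e-3
Q_total.ml_min: 160.0
Q_w_total.ml_hr: 200.0
# Jeffrey fluid parameters for blood (dimensionless).
lambda1: 0.1
lambda2: 0.03
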