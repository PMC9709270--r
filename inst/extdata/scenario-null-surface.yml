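# Example scenario override: two synthetic years with the default
# environment but no planted covariate effects (pair with a null
# true_surface() to simulate under the global null).
n_days: 730
gamma_tv: 0
rh_quad: 0
delta_pm25: 0
zeta_so2: 0
trend: 0
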