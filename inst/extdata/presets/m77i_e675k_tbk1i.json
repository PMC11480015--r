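{
  "name": "m77i_e675k_tbk1i",
  "g0": 0.014,
  "act_v_half": 10, "act_k": 8,
  "tau_act": 0.6, "tau_deact": 20,
  "inact_v_half_ref": -25, "inact_k": 5, "inact_floor": 0.02,
  "tau_inact_1": 136, "tau_inact_2": 43, "a1_frac": 0.3,
  "persistent_frac": 0.05,
  "tau_rec_ref": 1200,
  "k_shift_delta": 6, "k_rec_gamma": 0.5, "k_gain_alpha": 0.3,
  "poisonous": false,
  "source": {
    "tau_inact_1": "reported: forced-long E675K channel after TBK1-inhibitor treatment, tau1 = 136 ms",
    "tau_inact_2": "reported: tau2 = 43 ms",
    "a1_frac": "reported: A1/(A1+A2) = 0.3",
    "g0": "reported: ~30% reduction carried over from e675k",
    "other": "e675k in the m77i background"
  }
}
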