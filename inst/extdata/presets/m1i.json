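{
  "name": "m1i",
  "g0": 0.02,
  "act_v_half": 10, "act_k": 8,
  "tau_act": 0.6, "tau_deact": 20,
  "inact_v_half_ref": -25, "inact_k": 5, "inact_floor": 0.01,
  "tau_inact_1": 400, "tau_inact_2": 150, "a1_frac": 0.4,
  "persistent_frac": 0.98,
  "tau_rec_ref": 800,
  "k_shift_delta": 6, "k_rec_gamma": 0.5, "k_gain_alpha": 0.3,
  "poisonous": false,
  "source": {
    "act_v_half": "reported: GV shifted about +5 mV vs wild-type",
    "persistent_frac": "reported qualitatively: forced-short channel lacks the inactivation ball (no fast inactivation)",
    "other": "identical to wt"
  }
}
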