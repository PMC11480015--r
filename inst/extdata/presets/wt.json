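{
  "name": "wt",
  "g0": 0.02,
  "act_v_half": 5, "act_k": 8,
  "tau_act": 0.6, "tau_deact": 20,
  "inact_v_half_ref": -25, "inact_k": 5, "inact_floor": 0.05,
  "tau_inact_1": 400, "tau_inact_2": 150, "a1_frac": 0.4,
  "persistent_frac": 0.05,
  "tau_rec_ref": 800,
  "k_shift_delta": 6, "k_rec_gamma": 0.5, "k_gain_alpha": 0.3,
  "poisonous": false,
  "source": {
    "g0": "synthetic (absolute current scale is arbitrary)",
    "act_v_half": "synthetic, typical Kv3.3 wild-type value",
    "act_k": "synthetic, typical Kv3.3 wild-type value",
    "tau_act": "synthetic, ultrafast Kv3-family activation",
    "tau_deact": "synthetic",
    "inact_v_half_ref": "synthetic, typical Kv3.3 N-type inactivation midpoint",
    "inact_k": "synthetic",
    "inact_floor": "synthetic",
    "tau_inact_1": "synthetic, order of reported Kv3.3 decay",
    "tau_inact_2": "synthetic, order of reported Kv3.3 decay",
    "a1_frac": "synthetic",
    "persistent_frac": "synthetic",
    "tau_rec_ref": "synthetic, seconds-scale recovery",
    "k_shift_delta": "synthetic calibration reproducing the reported rightward inactivation shift with [K+]ex",
    "k_rec_gamma": "synthetic calibration reproducing the reported recovery speed-up with [K+]ex",
    "k_gain_alpha": "synthetic calibration reproducing the reported paradoxical K+ activation"
  }
}
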