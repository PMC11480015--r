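{
  "name": "e675k",
  "g0": 0.014,
  "act_v_half": 5, "act_k": 8,
  "tau_act": 0.6, "tau_deact": 20,
  "inact_v_half_ref": -25, "inact_k": 5, "inact_floor": 0.02,
  "tau_inact_1": 400, "tau_inact_2": 150, "a1_frac": 0.4,
  "persistent_frac": 0.05,
  "tau_rec_ref": 1200,
  "k_shift_delta": 6, "k_rec_gamma": 0.5, "k_gain_alpha": 0.3,
  "poisonous": false,
  "source": {
    "g0": "reported: ~30% peak-current reduction vs wild-type (0.7 x wt g0)",
    "tau_rec_ref": "synthetic calibration: slowed recovery driving the reported deeper cumulative inactivation",
    "inact_floor": "synthetic calibration: destabilized inactivation floor",
    "other": "identical to wt: the variant leaves voltage dependence and activation kinetics unchanged"
  }
}
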