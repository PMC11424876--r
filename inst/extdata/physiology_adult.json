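{
  "description": "Reference adult human physiology for the whole-body perfusion-limited model: tissue volumes (L) and blood flows (L/h), arterial/venous blood volumes (L), cardiac output (L/h), body weight (kg). Values are standard ~70 kg adult reference figures; liver flow is total (hepatic artery + portal inflow from gut and spleen); rest-of-body closes the flow and volume balance.",
  "body_weight_kg": 70,
  "cardiac_output_L_h": 336,
  "v_arterial_L": 1.5,
  "v_venous_L": 3.9,
  "tissues": {
    "lung":          {"volume_L": 0.50,  "flow_L_h": 336.0},
    "adipose":       {"volume_L": 18.20, "flow_L_h": 16.8},
    "muscle":        {"volume_L": 29.00, "flow_L_h": 57.1},
    "liver":         {"volume_L": 1.80,  "flow_L_h": 79.0},
    "gut":           {"volume_L": 1.20,  "flow_L_h": 50.4},
    "spleen":        {"volume_L": 0.18,  "flow_L_h": 6.7},
    "heart":         {"volume_L": 0.33,  "flow_L_h": 13.4},
    "brain":         {"volume_L": 1.45,  "flow_L_h": 40.3},
    "kidney":        {"volume_L": 0.31,  "flow_L_h": 63.8},
    "skin":          {"volume_L": 3.30,  "flow_L_h": 16.8},
    "reproductive":  {"volume_L": 0.05,  "flow_L_h": 1.7},
    "red_marrow":    {"volume_L": 1.10,  "flow_L_h": 10.1},
    "yellow_marrow": {"volume_L": 2.20,  "flow_L_h": 3.4},
    "rest":          {"volume_L": 4.90,  "flow_L_h": 33.6}
  }
}
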