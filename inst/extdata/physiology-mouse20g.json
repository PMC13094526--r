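{
  "name": "Reference physiology for a 20 g tumor-bearing mouse",
  "data_version": "1.0",
  "source": "Organ weights, regional blood flows and vascular volume fractions assembled from standard rodent physiology compendia (Brown et al.-style reference tables), with a 0.3 g subcutaneous tumor added. Organ density taken as 1 g/mL. Volumes and flows scale linearly with body weight.",
  "body_weight_g": 20,
  "cardiac_output_mL_min": 13.0,
  "blood_volume_mL": 1.7,
  "organs": {
    "heart":  {"volume_mL": 0.095, "flow_mL_min": 0.9,  "vascular_fraction": 0.26},
    "liver":  {"volume_mL": 1.10,  "flow_mL_min": 2.25, "vascular_fraction": 0.31},
    "spleen": {"volume_mL": 0.10,  "flow_mL_min": 0.13, "vascular_fraction": 0.22},
    "lung":   {"volume_mL": 0.15,  "flow_mL_min": 0.40, "vascular_fraction": 0.50},
    "kidney": {"volume_mL": 0.34,  "flow_mL_min": 2.60, "vascular_fraction": 0.24},
    "tumor":  {"volume_mL": 0.30,  "flow_mL_min": 0.20, "vascular_fraction": 0.07},
    "rest":   {"volume_mL": 16.2,  "flow_mL_min": 6.40, "vascular_fraction": 0.04}
  }
}
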