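{
  "name": "Default nanocluster transport parameters (non-targeted ultrasmall AuNC)",
  "data_version": "1.0",
  "source": "Order-of-magnitude defaults for an ultrasmall (~2 nm) renally cleared gold nanocluster: slow membrane-limited extravasation (PA well below organ plasma flows), moderate tissue partitioning, small irreversible sequestration in liver/spleen (reticuloendothelial) and tumor (receptor-mediated), and renal clearance dominating elimination. Chosen so the forward simulation is renal-dominant with sustained tumor retention; generator defaults for synthetic studies, not fitted claims about any measured probe.",
  "permeability_PA_mL_min": {
    "heart": 0.005, "liver": 0.03, "spleen": 0.005, "lung": 0.01,
    "kidney": 0.05, "tumor": 0.002, "rest": 0.05
  },
  "partition_K": {
    "heart": 1.0, "liver": 3.0, "spleen": 3.0, "lung": 1.0,
    "kidney": 5.0, "tumor": 5.0, "rest": 0.5
  },
  "sequestration_k_min": {
    "heart": 0.0, "liver": 0.001, "spleen": 0.001, "lung": 0.0,
    "kidney": 0.0, "tumor": 0.002, "rest": 0.0
  },
  "renal_clearance_CL_mL_min": 0.25,
  "tumor_uptake_enhancement": 3.0
}
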