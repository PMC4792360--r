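{
  "demographics": {
    "age_group": [1, 2, 3, 4, 5, 1, 2, 3, 4, 5, 1, 2, 3, 4, 5, 1, 2, 3, 4, 5, 1, 2, 3, 4, 5, 1, 2, 3, 4, 5, 1, 2, 3, 4, 5, 1, 2, 3, 4, 5, 1, 2, 3, 4, 5, 1, 2, 3, 4, 5, 1, 2, 3, 4, 5, 1, 2, 3, 4, 5, 1, 2, 3, 4, 5, 1, 2, 3, 4, 5, 1, 2, 3, 4, 5, 1, 2, 3, 4, 5, 1, 2, 3, 4, 5, 1, 2, 3, 4, 5, 1, 2, 3, 4, 5, 1, 2, 3, 4, 5, 1, 2, 3, 4, 5, 1, 2, 3, 4, 5, 1, 2, 3, 4, 5, 1, 2, 3, 4, 5],
    "race": ["white", "white", "white", "white", "white", "black", "black", "black", "black", "black", "hispanic", "hispanic", "hispanic", "hispanic", "hispanic", "other", "other", "other", "other", "other", "white", "white", "white", "white", "white", "black", "black", "black", "black", "black", "hispanic", "hispanic", "hispanic", "hispanic", "hispanic", "other", "other", "other", "other", "other", "white", "white", "white", "white", "white", "black", "black", "black", "black", "black", "hispanic", "hispanic", "hispanic", "hispanic", "hispanic", "other", "other", "other", "other", "other", "white", "white", "white", "white", "white", "black", "black", "black", "black", "black", "hispanic", "hispanic", "hispanic", "hispanic", "hispanic", "other", "other", "other", "other", "other", "white", "white", "white", "white", "white", "black", "black", "black", "black", "black", "hispanic", "hispanic", "hispanic", "hispanic", "hispanic", "other", "other", "other", "other", "other", "white", "white", "white", "white", "white", "black", "black", "black", "black", "black", "hispanic", "hispanic", "hispanic", "hispanic", "hispanic", "other", "other", "other", "other", "other"],
    "gender": ["female", "female", "female", "female", "female", "female", "female", "female", "female", "female", "female", "female", "female", "female", "female", "female", "female", "female", "female", "female", "male", "male", "male", "male", "male", "male", "male", "male", "male", "male", "male", "male", "male", "male", "male", "male", "male", "male", "male", "male", "female", "female", "female", "female", "female", "female", "female", "female", "female", "female", "female", "female", "female", "female", "female", "female", "female", "female", "female", "female", "male", "male", "male", "male", "male", "male", "male", "male", "male", "male", "male", "male", "male", "male", "male", "male", "male", "male", "male", "male", "female", "female", "female", "female", "female", "female", "female", "female", "female", "female", "female", "female", "female", "female", "female", "female", "female", "female", "female", "female", "male", "male", "male", "male", "male", "male", "male", "male", "male", "male", "male", "male", "male", "male", "male", "male", "male", "male", "male", "male"],
    "income": ["low", "low", "low", "low", "low", "low", "low", "low", "low", "low", "low", "low", "low", "low", "low", "low", "low", "low", "low", "low", "low", "low", "low", "low", "low", "low", "low", "low", "low", "low", "low", "low", "low", "low", "low", "low", "low", "low", "low", "low", "middle", "middle", "middle", "middle", "middle", "middle", "middle", "middle", "middle", "middle", "middle", "middle", "middle", "middle", "middle", "middle", "middle", "middle", "middle", "middle", "middle", "middle", "middle", "middle", "middle", "middle", "middle", "middle", "middle", "middle", "middle", "middle", "middle", "middle", "middle", "middle", "middle", "middle", "middle", "middle", "high", "high", "high", "high", "high", "high", "high", "high", "high", "high", "high", "high", "high", "high", "high", "high", "high", "high", "high", "high", "high", "high", "high", "high", "high", "high", "high", "high", "high", "high", "high", "high", "high", "high", "high", "high", "high", "high", "high", "high"],
    "prob": [0.04032, 0.0336, 0.025536, 0.018816, 0.016128, 0.004536, 0.00378, 0.0028728, 0.0021168, 0.0018144, 0.003528, 0.00294, 0.0022344, 0.0016464, 0.0014112, 0.002016, 0.00168, 0.0012768, 0.0009408, 0.0008064, 0.03168, 0.0264, 0.020064, 0.014784, 0.012672, 0.003564, 0.00297, 0.0022572, 0.0016632, 0.0014256, 0.002772, 0.00231, 0.0017556, 0.0012936, 0.0011088, 0.001584, 0.00132, 0.0010032, 0.0007392, 0.0006336, 0.0672, 0.056, 0.04256, 0.03136, 0.02688, 0.00756, 0.0063, 0.004788, 0.003528, 0.003024, 0.00588, 0.0049, 0.003724, 0.002744, 0.002352, 0.00336, 0.0028, 0.002128, 0.001568, 0.001344, 0.0528, 0.044, 0.03344, 0.02464, 0.02112, 0.00594, 0.00495, 0.003762, 0.002772, 0.002376, 0.00462, 0.00385, 0.002926, 0.002156, 0.001848, 0.00264, 0.0022, 0.001672, 0.001232, 0.001056, 0.02688, 0.0224, 0.017024, 0.012544, 0.010752, 0.003024, 0.00252, 0.0019152, 0.0014112, 0.0012096, 0.002352, 0.00196, 0.0014896, 0.0010976, 0.0009408, 0.001344, 0.00112, 0.0008512, 0.0006272, 0.0005376, 0.02112, 0.0176, 0.013376, 0.009856, 0.008448, 0.002376, 0.00198, 0.0015048, 0.0011088, 0.0009504, 0.001848, 0.00154, 0.0011704, 0.0008624, 0.0007392, 0.001056, 0.00088, 0.0006688, 0.0004928, 0.0004224]
  },
  "p_diabetes": {
    "age_group": [1, 2, 3, 4, 5],
    "p": [0.2, 0.22, 0.23, 0.22, 0.18]
  },
  "p_hypertension": {
    "race": ["white", "black", "hispanic", "other", "white", "black", "hispanic", "other"],
    "diabetes": [false, false, false, false, true, true, true, true],
    "p": [0.55, 0.7, 0.58, 0.55, 0.7, 0.85, 0.73, 0.7]
  },
  "p_chf": {
    "age_group": [1, 2, 3, 4, 5, 1, 2, 3, 4, 5, 1, 2, 3, 4, 5, 1, 2, 3, 4, 5],
    "diabetes": [false, false, false, false, false, true, true, true, true, true, false, false, false, false, false, true, true, true, true, true],
    "hypertension": [false, false, false, false, false, false, false, false, false, false, true, true, true, true, true, true, true, true, true, true],
    "p": [0.04, 0.06, 0.08, 0.1, 0.13, 0.072, 0.108, 0.144, 0.18, 0.234, 0.06, 0.09, 0.12, 0.15, 0.195, 0.108, 0.162, 0.216, 0.27, 0.351]
  },
  "p_initial_inpatient_dx": 0.5
}
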