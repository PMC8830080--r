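{
  "family": "gamma log-link",
  "n": 388,
  "description": "Multivariable gamma log-link cost equations from the reference retrospective VATS lobectomy cost analysis (n=388). p-values printed as '<0.001' are stored as 0.001. The drugs-equation BMI term is stored as the 28<=BMI<30 band exactly as tabulated.",
  "categories": {
    "disposables": {
      "terms": [
        { "term": "(Intercept)", "estimate": 9.279, "ci_low": 9.203, "ci_high": 9.357, "p_value": 0.001 },
        { "term": "powered", "estimate": -0.007, "ci_low": -0.084, "ci_high": 0.069, "p_value": 0.854 },
        { "term": "male", "estimate": 0.041, "ci_low": -0.048, "ci_high": 0.129, "p_value": 0.361 },
        { "term": "bmi_18_5_24", "estimate": -0.099, "ci_low": -0.171, "ci_high": -0.028, "p_value": 0.007 },
        { "term": "bmi_24_28", "estimate": -0.133, "ci_low": -0.214, "ci_high": -0.052, "p_value": 0.001 },
        { "term": "bmi_30_40", "estimate": -0.388, "ci_low": -0.624, "ci_high": -0.134, "p_value": 0.002 },
        { "term": "adenocarcinoma", "estimate": -0.041, "ci_low": -0.108, "ci_high": 0.025, "p_value": 0.225 },
        { "term": "stage_i", "estimate": 0.058, "ci_low": -0.005, "ci_high": 0.120, "p_value": 0.072 },
        { "term": "abn_inr", "estimate": 0.141, "ci_low": -0.022, "ci_high": 0.311, "p_value": 0.099 },
        { "term": "abn_hemoglobin", "estimate": 0.076, "ci_low": -0.004, "ci_high": 0.157, "p_value": 0.066 },
        { "term": "site_upper_left", "estimate": -0.026, "ci_low": -0.100, "ci_high": 0.050, "p_value": 0.500 },
        { "term": "cm_hypertension", "estimate": -0.051, "ci_low": -0.128, "ci_high": 0.026, "p_value": 0.193 },
        { "term": "cm_immune", "estimate": 0.177, "ci_low": -0.193, "ci_high": 0.583, "p_value": 0.355 },
        { "term": "cm_breast", "estimate": -0.524, "ci_low": -0.917, "ci_high": -0.075, "p_value": 0.015 }
      ]
    },
    "drugs": {
      "terms": [
        { "term": "(Intercept)", "estimate": 9.492, "ci_low": 9.337, "ci_high": 9.649, "p_value": 0.001 },
        { "term": "powered", "estimate": -0.256, "ci_low": -0.375, "ci_high": -0.139, "p_value": 0.001 },
        { "term": "male", "estimate": 0.041, "ci_low": -0.048, "ci_high": 0.129, "p_value": 0.361 },
        { "term": "bmi_24_28", "estimate": -0.148, "ci_low": -0.250, "ci_high": -0.044, "p_value": 0.005 },
        { "term": "bmi_28_30", "estimate": -0.330, "ci_low": -0.535, "ci_high": -0.112, "p_value": 0.002 },
        { "term": "residence_county", "estimate": 0.134, "ci_low": -0.002, "ci_high": 0.273, "p_value": 0.058 },
        { "term": "married", "estimate": -0.010, "ci_low": -0.129, "ci_high": 0.106, "p_value": 0.864 },
        { "term": "ins_urban_employee", "estimate": -0.049, "ci_low": -0.155, "ci_high": 0.058, "p_value": 0.367 },
        { "term": "adenocarcinoma", "estimate": 0.018, "ci_low": -0.074, "ci_high": 0.109, "p_value": 0.702 },
        { "term": "stage_i", "estimate": -0.153, "ci_low": -0.240, "ci_high": -0.067, "p_value": 0.001 },
        { "term": "abn_platelet", "estimate": 0.233, "ci_low": 0.085, "ci_high": 0.386, "p_value": 0.002 },
        { "term": "site_upper_left", "estimate": 0.029, "ci_low": -0.071, "ci_high": 0.131, "p_value": 0.576 },
        { "term": "cm_diabetes", "estimate": 0.124, "ci_low": -0.017, "ci_high": 0.270, "p_value": 0.091 },
        { "term": "cm_cerebrovascular", "estimate": 0.095, "ci_low": -0.018, "ci_high": 0.210, "p_value": 0.103 },
        { "term": "cm_urological", "estimate": 0.144, "ci_low": 0.045, "ci_high": 0.246, "p_value": 0.005 },
        { "term": "cm_cardiovascular", "estimate": 0.073, "ci_low": -0.066, "ci_high": 0.217, "p_value": 0.310 },
        { "term": "cm_endocrine", "estimate": -0.164, "ci_low": -0.297, "ci_high": -0.026, "p_value": 0.019 }
      ]
    },
    "operation": {
      "terms": [
        { "term": "(Intercept)", "estimate": 8.925, "ci_low": 8.856, "ci_high": 8.994, "p_value": 0.001 },
        { "term": "powered", "estimate": 0.004, "ci_low": -0.065, "ci_high": 0.072, "p_value": 0.909 },
        { "term": "stage_i", "estimate": -0.052, "ci_low": -0.110, "ci_high": 0.006, "p_value": 0.079 },
        { "term": "site_upper_left", "estimate": 0.002, "ci_low": -0.070, "ci_high": 0.075, "p_value": 0.954 },
        { "term": "cm_bronchial", "estimate": 0.108, "ci_low": 0.015, "ci_high": 0.203, "p_value": 0.025 },
        { "term": "cm_immune", "estimate": -0.393, "ci_low": -0.707, "ci_high": -0.047, "p_value": 0.019 },
        { "term": "cm_cerebrovascular", "estimate": 0.040, "ci_low": -0.038, "ci_high": 0.120, "p_value": 0.316 },
        { "term": "cm_urological", "estimate": 0.074, "ci_low": 0.002, "ci_high": 0.146, "p_value": 0.045 },
        { "term": "cm_cardiovascular", "estimate": 0.066, "ci_low": -0.032, "ci_high": 0.167, "p_value": 0.196 },
        { "term": "cm_sport", "estimate": 0.071, "ci_low": -0.033, "ci_high": 0.178, "p_value": 0.186 },
        { "term": "cm_vascular", "estimate": 0.088, "ci_low": -0.142, "ci_high": 0.334, "p_value": 0.472 }
      ]
    },
    "laboratory": {
      "terms": [
        { "term": "(Intercept)", "estimate": 9.133, "ci_low": 8.851, "ci_high": 9.417, "p_value": 0.001 },
        { "term": "powered", "estimate": -0.094, "ci_low": -0.203, "ci_high": 0.014, "p_value": 0.082 },
        { "term": "age", "estimate": 0.002, "ci_low": -0.003, "ci_high": 0.007, "p_value": 0.367 },
        { "term": "bmi_18_5_24", "estimate": 0.100, "ci_low": 0.013, "ci_high": 0.188, "p_value": 0.024 },
        { "term": "ins_new_rural", "estimate": -0.029, "ci_low": -0.128, "ci_high": 0.071, "p_value": 0.562 },
        { "term": "adenocarcinoma", "estimate": -0.031, "ci_low": -0.117, "ci_high": 0.055, "p_value": 0.480 },
        { "term": "stage_i", "estimate": -0.033, "ci_low": -0.113, "ci_high": 0.048, "p_value": 0.427 },
        { "term": "abn_leukocyte", "estimate": -0.117, "ci_low": -0.256, "ci_high": 0.026, "p_value": 0.101 },
        { "term": "site_upper_left", "estimate": 0.014, "ci_low": -0.082, "ci_high": 0.111, "p_value": 0.781 },
        { "term": "cm_immune", "estimate": -0.521, "ci_low": -0.944, "ci_high": -0.039, "p_value": 0.023 },
        { "term": "cm_diabetes", "estimate": 0.165, "ci_low": 0.030, "ci_high": 0.305, "p_value": 0.019 },
        { "term": "cm_cerebrovascular", "estimate": 0.046, "ci_low": -0.063, "ci_high": 0.157, "p_value": 0.415 },
        { "term": "cm_urological", "estimate": 0.133, "ci_low": 0.038, "ci_high": 0.230, "p_value": 0.007 },
        { "term": "cm_cardiovascular", "estimate": 0.088, "ci_low": -0.046, "ci_high": 0.225, "p_value": 0.206 }
      ]
    },
    "other": {
      "terms": [
        { "term": "(Intercept)", "estimate": 7.707, "ci_low": 7.618, "ci_high": 7.798, "p_value": 0.001 },
        { "term": "powered", "estimate": -0.008, "ci_low": -0.099, "ci_high": 0.080, "p_value": 0.854 },
        { "term": "stage_i", "estimate": -0.083, "ci_low": -0.159, "ci_high": -0.007, "p_value": 0.033 },
        { "term": "site_upper_left", "estimate": -0.019, "ci_low": -0.111, "ci_high": 0.075, "p_value": 0.684 },
        { "term": "cm_immune", "estimate": -0.410, "ci_low": -0.817, "ci_high": 0.054, "p_value": 0.064 },
        { "term": "cm_diabetes", "estimate": 0.158, "ci_low": 0.028, "ci_high": 0.292, "p_value": 0.020 },
        { "term": "cm_cerebrovascular", "estimate": 0.068, "ci_low": -0.033, "ci_high": 0.172, "p_value": 0.195 },
        { "term": "cm_urological", "estimate": 0.176, "ci_low": 0.084, "ci_high": 0.269, "p_value": 0.001 }
      ]
    }
  }
}
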