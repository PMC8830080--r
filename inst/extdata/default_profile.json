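{
  "description": "Default cohort profile: covariate marginals, device utilization and episode characteristics of a retrospective VATS lobectomy cost cohort (296 powered-stapler and 92 manual-stapler episodes) in a Chinese tertiary hospital. Comorbidities without a published marginal (immune, breast, cardiovascular, vascular, lung_infection, tuberculosis) carry assumed low prevalences; episode-course fields (operation time, stay, bleeding, drainage) are assumed realistic values, not published ones.",
  "dispersion": 4.9,
  "groups": {
    "powered": {
      "n": 296,
      "age": { "mean": 57.9, "sd": 8.9 },
      "bmi": { "mean": 23.8, "sd": 3.1 },
      "male": 0.53,
      "staplers": { "mean": 1.2, "sd": 0.6 },
      "cartridges": { "mean": 7.0, "sd": 3.9 },
      "residence": { "provincial_capital": 0.254, "prefecture": 0.593, "county": 0.075, "other": 0.078 },
      "insurance": { "urban_employee": 0.271, "urban_resident": 0.220, "new_rural": 0.271, "other": 0.237 },
      "marital": { "married": 0.993, "single": 0.007 },
      "histology": { "squamous": 0.146, "adenocarcinoma": 0.782, "other": 0.071 },
      "stage": { "in_situ": 0.010, "I": 0.565, "II": 0.118, "III": 0.297, "IV": 0.010 },
      "lobectomy_site": { "upper_right": 0.381, "right_middle": 0.075, "lower_right": 0.143, "upper_middle_right": 0.008, "lower_middle_right": 0.016, "left_lung": 0.004, "upper_left": 0.258, "bottom_left": 0.115 },
      "comorbidity": { "digestive": 0.439, "urological": 0.230, "hypertension": 0.203, "reproductive": 0.172, "cerebrovascular": 0.159, "bronchial": 0.135, "endocrine": 0.111, "sport": 0.098, "diabetes": 0.091, "heart": 0.088, "emphysema": 0.074, "bullae": 0.051, "coronary": 0.027, "immune": 0.010, "breast": 0.010, "cardiovascular": 0.030, "vascular": 0.010, "lung_infection": 0.050, "tuberculosis": 0.030 },
      "marrow": { "inr": 0.039, "hemoglobin": 0.159, "erythrocyte": 0.244, "leukocyte": 0.085, "platelet": 0.075 }
    },
    "manual": {
      "n": 92,
      "age": { "mean": 58.5, "sd": 9.0 },
      "bmi": { "mean": 23.5, "sd": 2.8 },
      "male": 0.63,
      "staplers": { "mean": 1.2, "sd": 0.5 },
      "cartridges": { "mean": 7.5, "sd": 4.0 },
      "residence": { "provincial_capital": 0.143, "prefecture": 0.604, "county": 0.198, "other": 0.055 },
      "insurance": { "urban_employee": 0.192, "urban_resident": 0.077, "new_rural": 0.365, "other": 0.365 },
      "marital": { "married": 1.0, "single": 0.0 },
      "histology": { "squamous": 0.148, "adenocarcinoma": 0.815, "other": 0.037 },
      "stage": { "in_situ": 0.0, "I": 0.478, "II": 0.174, "III": 0.337, "IV": 0.011 },
      "lobectomy_site": { "upper_right": 0.258, "right_middle": 0.030, "lower_right": 0.242, "upper_middle_right": 0.0, "lower_middle_right": 0.015, "left_lung": 0.0, "upper_left": 0.212, "bottom_left": 0.242 },
      "comorbidity": { "digestive": 0.380, "urological": 0.163, "hypertension": 0.174, "reproductive": 0.130, "cerebrovascular": 0.174, "bronchial": 0.033, "endocrine": 0.076, "sport": 0.033, "diabetes": 0.087, "heart": 0.120, "emphysema": 0.076, "bullae": 0.054, "coronary": 0.098, "immune": 0.010, "breast": 0.010, "cardiovascular": 0.030, "vascular": 0.010, "lung_infection": 0.050, "tuberculosis": 0.030 },
      "marrow": { "inr": 0.035, "hemoglobin": 0.242, "erythrocyte": 0.143, "leukocyte": 0.099, "platelet": 0.121 }
    }
  },
  "episode": {
    "operation_minutes": { "mean": 180, "sd": 60, "min": 30, "max": 700 },
    "length_of_stay": { "mean": 9, "sd": 4, "min": 2, "max": 40 },
    "bleeding_ml": { "mean": 100, "sd": 80, "min": 5, "max": 2000 },
    "drainage_ml": { "mean": 900, "sd": 450, "min": 50, "max": 5000 },
    "p_death_in_surgery": 0.002,
    "p_routine_discharge": 0.98
  }
}
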