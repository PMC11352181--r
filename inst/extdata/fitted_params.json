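{
  "comment": "Published estimates of the three absorption parameters per drug. lambda values on the 1e-3 m^2/s scale, kd on the 1e-5 1/s scale.",
  "drugs": {
    "Aprepitant":   {"lambda_j": 5.157,   "lambda_ic": 5.100,    "kd": 2.012},
    "Ketoconazole": {"lambda_j": 3.506,   "lambda_ic": 1.311,    "kd": 8.095},
    "Griseofulvin": {"lambda_j": 5.858,   "lambda_ic": 4.949,    "kd": 4.695},
    "Linezolid":    {"lambda_j": 1.184,   "lambda_ic": 1.195,    "kd": 5.352},
    "Irbesartan":   {"lambda_j": 6.860,   "lambda_ic": 5.994e-3, "kd": 5.036},
    "Danazol":      {"lambda_j": 7.325,   "lambda_ic": 4.029,    "kd": 10.287},
    "Fenofibrate":  {"lambda_j": 104.031, "lambda_ic": 73.810,   "kd": 0.836},
    "Ibuprofen":    {"lambda_j": 286.936, "lambda_ic": 18.827,   "kd": 3.074},
    "Ketoprofen":   {"lambda_j": 7.000,   "lambda_ic": 6.000,    "kd": 25.343},
    "Etoricoxib":   {"lambda_j": 6.993,   "lambda_ic": 6.988,    "kd": 2.011}
  }
}
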