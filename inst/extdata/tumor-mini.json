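{
  "domain": {
    "size": [32, 32, 32],
    "blocks": [2, 2, 2],
    "colors": 8,
    "stencil": 27,
    "metric": "marching",
    "mean_step": 5,
    "temperature": 6,
    "seed": 1
  },
  "signals": ["nutrient"],
  "celltypes": {
    "liquid": {"liquid": true},
    "vessel": {
      "solid": true,
      "constant_signal": true,
      "start_signal": {"nutrient": 1},
      "adhesion": {"liquid": 0, "vessel": 0, "tumor": 0, "aggressive": 0, "apoptotic": 0},
      "diffusion": {"vessel": 0, "tumor": 0.1, "aggressive": 0.1, "apoptotic": 0, "liquid": 0}
    },
    "tumor": {
      "V0": 100, "S0": 160, "lambda_V": 1, "lambda_S": 0.1,
      "adhesion": {"liquid": 4, "tumor": 2, "aggressive": 2, "apoptotic": 2},
      "start_signal": {"nutrient": 0.5},
      "decay": {"nutrient": {"relative": 0.95}},
      "diffusion": {"tumor": 0.05, "aggressive": 0.05, "apoptotic": 0.02, "liquid": 0},
      "division": {
        "rate": 0.3, "min_age": 2, "mutation_rate": 0.05,
        "signal_min": {"nutrient": 0.2},
        "mutation": {"tumor": 0, "aggressive": 1}
      },
      "death": {
        "rate": 0.2, "min_age": 3, "apoptotic_type": "apoptotic", "chi": 20,
        "signal_max": {"nutrient": 0.05}
      }
    },
    "aggressive": {
      "V0": 100, "S0": 160, "lambda_V": 1, "lambda_S": 0.1,
      "size_change": {"V0": 1, "S0": 1},
      "adhesion": {"liquid": 3, "aggressive": 1, "apoptotic": 2},
      "start_signal": {"nutrient": 0.5},
      "decay": {"nutrient": {"relative": 0.93}},
      "diffusion": {"aggressive": 0.05, "apoptotic": 0.02, "liquid": 0},
      "division": {
        "rate": 0.5, "min_age": 1,
        "signal_min": {"nutrient": 0.15}
      },
      "death": {
        "rate": 0.2, "min_age": 3, "apoptotic_type": "apoptotic", "chi": 20,
        "signal_max": {"nutrient": 0.05}
      }
    },
    "apoptotic": {
      "V0": 100, "S0": 160, "lambda_V": 1, "lambda_S": 0.1,
      "adhesion": {"liquid": 2, "apoptotic": 2},
      "diffusion": {"apoptotic": 0.02, "liquid": 0},
      "death": {"chi": 20}
    }
  },
  "init": [
    {"shape": "cube", "corner": [2, 12, 12], "size": 4, "type": "vessel"},
    {"shape": "cube", "corner": [14, 14, 14], "size": 5, "type": "tumor"}
  ],
  "output": {"every": 0},
  "sanity": {"single_voxel": true, "every": 1}
}
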