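{
  "domain": {
    "size": [64, 64, 64],
    "blocks": [2, 2, 2],
    "colors": 8,
    "stencil": 27,
    "metric": "marching",
    "volume_method": "count",
    "mean_step": 100,
    "temperature": 14,
    "seed": 1
  },
  "signals": [],
  "celltypes": {
    "liquid": {"liquid": true},
    "cell": {
      "V0": 1000,
      "S0": 1400,
      "lambda_V": 0.02,
      "lambda_S": 0.01,
      "adhesion": {"liquid": 0, "cell": 0}
    }
  },
  "init": [
    {"shape": "sphere", "center": [16, 16, 16], "radius": 6.2, "type": "cell"},
    {"shape": "sphere", "center": [32, 32, 32], "radius": 6.2, "type": "cell"}
  ],
  "output": {"every": 0},
  "sanity": {"single_voxel": true, "every": 1}
}
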