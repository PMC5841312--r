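{
  "version": 1,
  "loop": "open",
  "blood": { "viscosity": 0.004, "density": 1040 },
  "thickness_fit": { "a": 0.09, "b": -2000, "c": 0.11, "d": -5 },
  "inflow": { "kind": "csv", "path": "example-inflow.csv" },
  "segments": [
    {
      "id": "aorta",
      "type": "VV",
      "parent": null,
      "geometry": { "length": 0.04, "radius": 0.005,
                    "thickness": 0.00075, "youngs_modulus": 8e5 }
    },
    {
      "id": "left",
      "type": "PP_BC_TERMINAL",
      "parent": "aorta",
      "geometry": { "length": 0.025, "radius": 0.0037,
                    "thickness": 0.0006, "youngs_modulus": 8e5 },
      "terminal": { "RTP": 1e8, "RTD": 1.16e9, "CT": 1.5e-9, "mu_out": 0 }
    },
    {
      "id": "right",
      "type": "PP_BC_TERMINAL",
      "parent": "aorta",
      "viscoelastic": true,
      "geometry": { "length": 0.025, "radius": 0.0037,
                    "thickness": 0.0006, "youngs_modulus": 8e5,
                    "stress_relax": 0.005 },
      "terminal": { "RTP": 1e8, "RTD": 1.16e9, "CT": 1.5e-9, "mu_out": 0 }
    }
  ]
}
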