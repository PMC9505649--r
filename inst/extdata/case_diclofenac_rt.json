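{
  "case_id": "diclofenac_RT",
  "end_time": 47,
  "geometry": {
    "exposure_area": 0.636,
    "donor_volume": 1,
    "receptor_volume": 12
  },
  "layers": [
    {
      "name": "donor",
      "diffusivity": 1000,
      "thickness": null,
      "volume": 1,
      "initial_concentration": 5
    },
    {
      "name": "skin",
      "diffusivity": 0.0012,
      "thickness": 0.07,
      "volume": null,
      "initial_concentration": 0
    },
    {
      "name": "receptor",
      "diffusivity": 1000,
      "thickness": null,
      "volume": 12,
      "initial_concentration": 0
    }
  ],
  "interfaces": [
    {
      "partition": 8,
      "mass_transfer": 0.08,
      "orientation": "skin_downstream"
    },
    {
      "partition": 25,
      "mass_transfer": 0.04,
      "orientation": "skin_upstream"
    }
  ]
}
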