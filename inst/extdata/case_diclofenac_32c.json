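{
  "case_id": "diclofenac_32C",
  "end_time": 51.5,
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
      "diffusivity": 0.0018,
      "thickness": 0.1,
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
      "partition": 5,
      "mass_transfer": 0.12,
      "orientation": "skin_downstream"
    },
    {
      "partition": 10,
      "mass_transfer": 0.1,
      "orientation": "skin_upstream"
    }
  ]
}
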