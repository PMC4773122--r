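{
  "field_strength": "3T",
  "substrate": {
    "source": "recipe",
    "recipe": {
      "grid_shape": [48, 48, 48],
      "voxel_size_mm": 0.7,
      "rng_seed": 1
    }
  },
  "protocol": {
    "TE_ms": 57,
    "TR_ms": 8800,
    "delta_ms": 12.9,
    "Delta_ms": 21.8,
    "bvals": [1000],
    "n_dirs": 60,
    "n_b0": 6,
    "native_voxel_mm": 0.7,
    "resolution_factor": 3,
    "filter": "none",
    "snr": null,
    "seed": 1
  }
}
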