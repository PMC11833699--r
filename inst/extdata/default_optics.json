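{
  "gray_matter": {
    "670":  {"mua": 0.050, "mus": 9.0, "g": 0.89, "n": 1.37},
    "810":  {"mua": 0.028, "mus": 8.1, "g": 0.89, "n": 1.37},
    "850":  {"mua": 0.027, "mus": 7.8, "g": 0.89, "n": 1.37},
    "980":  {"mua": 0.055, "mus": 7.0, "g": 0.89, "n": 1.37},
    "1070": {"mua": 0.045, "mus": 6.5, "g": 0.89, "n": 1.37}
  },
  "white_matter": {
    "670":  {"mua": 0.090, "mus": 40.0, "g": 0.86, "n": 1.38},
    "810":  {"mua": 0.045, "mus": 36.0, "g": 0.86, "n": 1.38},
    "850":  {"mua": 0.040, "mus": 34.5, "g": 0.87, "n": 1.38},
    "980":  {"mua": 0.070, "mus": 31.0, "g": 0.87, "n": 1.38},
    "1070": {"mua": 0.060, "mus": 29.0, "g": 0.87, "n": 1.38}
  },
  "csf": {
    "670":  {"mua": 0.0004, "mus": 0.30, "g": 0.90, "n": 1.33},
    "810":  {"mua": 0.0022, "mus": 0.30, "g": 0.90, "n": 1.33},
    "850":  {"mua": 0.0043, "mus": 0.30, "g": 0.90, "n": 1.33},
    "980":  {"mua": 0.0450, "mus": 0.30, "g": 0.90, "n": 1.33},
    "1070": {"mua": 0.0160, "mus": 0.30, "g": 0.90, "n": 1.33}
  },
  "skull": {
    "670":  {"mua": 0.025, "mus": 20.0, "g": 0.92, "n": 1.55},
    "810":  {"mua": 0.020, "mus": 18.0, "g": 0.92, "n": 1.55},
    "850":  {"mua": 0.019, "mus": 17.5, "g": 0.92, "n": 1.55},
    "980":  {"mua": 0.040, "mus": 16.0, "g": 0.92, "n": 1.55},
    "1070": {"mua": 0.035, "mus": 15.5, "g": 0.92, "n": 1.55}
  },
  "soft_tissue": {
    "670":  {"mua": 0.030, "mus": 20.0, "g": 0.90, "n": 1.40},
    "810":  {"mua": 0.022, "mus": 17.5, "g": 0.90, "n": 1.40},
    "850":  {"mua": 0.021, "mus": 17.0, "g": 0.90, "n": 1.40},
    "980":  {"mua": 0.050, "mus": 15.0, "g": 0.90, "n": 1.40},
    "1070": {"mua": 0.040, "mus": 14.0, "g": 0.90, "n": 1.40}
  },
  "air": {
    "670":  {"mua": 0, "mus": 0, "g": 0, "n": 1},
    "810":  {"mua": 0, "mus": 0, "g": 0, "n": 1},
    "850":  {"mua": 0, "mus": 0, "g": 0, "n": 1},
    "980":  {"mua": 0, "mus": 0, "g": 0, "n": 1},
    "1070": {"mua": 0, "mus": 0, "g": 0, "n": 1}
  },
  "cornea": {
    "670":  {"mua": 0.0030, "mus": 1.2, "g": 0.90, "n": 1.376},
    "810":  {"mua": 0.0030, "mus": 1.0, "g": 0.90, "n": 1.376},
    "850":  {"mua": 0.0035, "mus": 1.0, "g": 0.90, "n": 1.376},
    "980":  {"mua": 0.0450, "mus": 0.9, "g": 0.90, "n": 1.376},
    "1070": {"mua": 0.0170, "mus": 0.9, "g": 0.90, "n": 1.376}
  },
  "aqueous": {
    "670":  {"mua": 0.0005, "mus": 0.10, "g": 0.90, "n": 1.336},
    "810":  {"mua": 0.0022, "mus": 0.10, "g": 0.90, "n": 1.336},
    "850":  {"mua": 0.0043, "mus": 0.10, "g": 0.90, "n": 1.336},
    "980":  {"mua": 0.0450, "mus": 0.10, "g": 0.90, "n": 1.336},
    "1070": {"mua": 0.0160, "mus": 0.10, "g": 0.90, "n": 1.336}
  },
  "lens": {
    "670":  {"mua": 0.0040, "mus": 2.8, "g": 0.92, "n": 1.41},
    "810":  {"mua": 0.0040, "mus": 2.5, "g": 0.92, "n": 1.41},
    "850":  {"mua": 0.0050, "mus": 2.4, "g": 0.92, "n": 1.41},
    "980":  {"mua": 0.0400, "mus": 2.2, "g": 0.92, "n": 1.41},
    "1070": {"mua": 0.0160, "mus": 2.1, "g": 0.92, "n": 1.41}
  },
  "vitreous": {
    "670":  {"mua": 0.0005, "mus": 0.10, "g": 0.90, "n": 1.336},
    "810":  {"mua": 0.0022, "mus": 0.10, "g": 0.90, "n": 1.336},
    "850":  {"mua": 0.0043, "mus": 0.10, "g": 0.90, "n": 1.336},
    "980":  {"mua": 0.0450, "mus": 0.10, "g": 0.90, "n": 1.336},
    "1070": {"mua": 0.0160, "mus": 0.10, "g": 0.90, "n": 1.336}
  },
  "orbital_fat": {
    "670":  {"mua": 0.012, "mus": 13.0, "g": 0.92, "n": 1.44},
    "810":  {"mua": 0.010, "mus": 12.0, "g": 0.92, "n": 1.44},
    "850":  {"mua": 0.010, "mus": 11.7, "g": 0.92, "n": 1.44},
    "980":  {"mua": 0.030, "mus": 11.0, "g": 0.92, "n": 1.44},
    "1070": {"mua": 0.025, "mus": 10.5, "g": 0.92, "n": 1.44}
  },
  "muscle": {
    "670":  {"mua": 0.070, "mus": 9.5, "g": 0.93, "n": 1.40},
    "810":  {"mua": 0.055, "mus": 9.0, "g": 0.93, "n": 1.40},
    "850":  {"mua": 0.052, "mus": 8.8, "g": 0.93, "n": 1.40},
    "980":  {"mua": 0.075, "mus": 8.2, "g": 0.93, "n": 1.40},
    "1070": {"mua": 0.065, "mus": 8.0, "g": 0.93, "n": 1.40}
  },
  "sclera_retina": {
    "670":  {"mua": 0.090, "mus": 38.0, "g": 0.90, "n": 1.40},
    "810":  {"mua": 0.075, "mus": 35.0, "g": 0.90, "n": 1.40},
    "850":  {"mua": 0.072, "mus": 34.0, "g": 0.90, "n": 1.40},
    "980":  {"mua": 0.095, "mus": 31.0, "g": 0.90, "n": 1.40},
    "1070": {"mua": 0.085, "mus": 30.0, "g": 0.90, "n": 1.40}
  },
  "eyelid_skin": {
    "670":  {"mua": 0.030, "mus": 24.0, "g": 0.90, "n": 1.40},
    "810":  {"mua": 0.025, "mus": 22.0, "g": 0.90, "n": 1.40},
    "850":  {"mua": 0.024, "mus": 21.5, "g": 0.90, "n": 1.40},
    "980":  {"mua": 0.050, "mus": 19.5, "g": 0.90, "n": 1.40},
    "1070": {"mua": 0.040, "mus": 18.5, "g": 0.90, "n": 1.40}
  }
}
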