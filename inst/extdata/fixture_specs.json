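{
  "no_lateral_straight": {
    "image_size": [400, 300],
    "trunk": {
      "row": [20, 110, 200, 290, 380],
      "col": [150, 151, 149, 150, 150]
    },
    "width": [9, 5],
    "seed": 101,
    "bg_level": 30,
    "root_level": 200,
    "noise_sd": 0,
    "blur_sigma": 0,
    "mm_per_px": 0.0846666666666667
  },
  "no_lateral_curved": {
    "image_size": [400, 300],
    "trunk": {
      "row": [20, 110, 200, 290, 380],
      "col": [150, 135, 160, 145, 152]
    },
    "width": [9, 3],
    "seed": 102,
    "bg_level": 30,
    "root_level": 200,
    "noise_sd": 0,
    "blur_sigma": 0,
    "mm_per_px": 0.0846666666666667
  },
  "sparse_lateral": {
    "image_size": [400, 300],
    "trunk": {
      "row": [20, 110, 200, 290, 380],
      "col": [150, 148, 153, 150, 149]
    },
    "width": [9, 5],
    "laterals": {
      "s": [0.25, 0.45, 0.7],
      "side": [-1, 1, 1],
      "angle": [70, 100, 60],
      "length": [50, 40, 55],
      "width": [3, 3, 3]
    },
    "seed": 103,
    "bg_level": 30,
    "root_level": 200,
    "noise_sd": 0,
    "blur_sigma": 0,
    "mm_per_px": 0.0846666666666667
  },
  "dense_lateral": {
    "image_size": [400, 300],
    "trunk": {
      "row": [20, 110, 200, 290, 380],
      "col": [150, 152, 148, 151, 150]
    },
    "width": [9, 5],
    "laterals": {
      "s": [0.18, 0.3, 0.42, 0.54, 0.66, 0.78],
      "side": [-1, 1, -1, 1, -1, 1],
      "angle": [65, 80, 100, 70, 90, 60],
      "length": [35, 45, 30, 40, 35, 45],
      "width": [3, 3, 3, 3, 3, 3]
    },
    "seed": 104,
    "bg_level": 30,
    "root_level": 200,
    "noise_sd": 0,
    "blur_sigma": 0,
    "mm_per_px": 0.0846666666666667
  },
  "curved_trunk": {
    "image_size": [400, 300],
    "trunk": {
      "row": [20, 110, 200, 290, 380],
      "col": [160, 130, 165, 140, 155]
    },
    "width": [9, 5],
    "laterals": {
      "s": [0.35, 0.65],
      "side": [1, -1],
      "angle": [75, 105],
      "length": [50, 45],
      "width": [3, 3]
    },
    "seed": 105,
    "bg_level": 30,
    "root_level": 200,
    "noise_sd": 0,
    "blur_sigma": 0,
    "mm_per_px": 0.0846666666666667
  },
  "steep_lateral": {
    "image_size": [400, 300],
    "trunk": {
      "row": [20, 110, 200, 290, 380],
      "col": [150, 149, 151, 150, 150]
    },
    "width": [9, 5],
    "laterals": {
      "s": [0.3, 0.6],
      "side": [1, -1],
      "angle": [120, 130],
      "length": [45, 40],
      "width": [3, 3]
    },
    "seed": 106,
    "bg_level": 30,
    "root_level": 200,
    "noise_sd": 0,
    "blur_sigma": 0,
    "mm_per_px": 0.0846666666666667
  },
  "nodule_single": {
    "image_size": [400, 300],
    "trunk": {
      "row": [20, 110, 200, 290, 380],
      "col": [150, 151, 149, 150, 150]
    },
    "width": [9, 5],
    "nodules": {
      "s": 0.5,
      "a": 12,
      "b": 8
    },
    "seed": 107,
    "bg_level": 30,
    "root_level": 200,
    "noise_sd": 0,
    "blur_sigma": 0,
    "mm_per_px": 0.0846666666666667
  },
  "nodule_multi": {
    "image_size": [400, 300],
    "trunk": {
      "row": [20, 110, 200, 290, 380],
      "col": [150, 148, 152, 150, 149]
    },
    "width": [9, 5],
    "laterals": {
      "s": 0.3,
      "side": -1,
      "angle": 70,
      "length": 50,
      "width": 3
    },
    "nodules": {
      "s": [0.55, 0.8],
      "a": [11, 10],
      "b": [8, 7]
    },
    "seed": 108,
    "bg_level": 30,
    "root_level": 200,
    "noise_sd": 0,
    "blur_sigma": 0,
    "mm_per_px": 0.0846666666666667
  },
  "noisy_mild": {
    "image_size": [400, 300],
    "trunk": {
      "row": [20, 110, 200, 290, 380],
      "col": [150, 147, 152, 150, 150]
    },
    "width": [9, 5],
    "laterals": {
      "s": [0.3, 0.6],
      "side": [1, -1],
      "angle": [70, 95],
      "length": [50, 45],
      "width": [3, 3]
    },
    "noise_sd": 8,
    "blur_sigma": 0.8,
    "seed": 109,
    "bg_level": 30,
    "root_level": 200,
    "mm_per_px": 0.0846666666666667
  },
  "noisy_blur": {
    "image_size": [400, 300],
    "trunk": {
      "row": [20, 110, 200, 290, 380],
      "col": [150, 152, 148, 150, 151]
    },
    "width": [9, 5],
    "laterals": {
      "s": 0.5,
      "side": 1,
      "angle": 80,
      "length": 45,
      "width": 3
    },
    "noise_sd": 12,
    "blur_sigma": 1.2,
    "seed": 110,
    "bg_level": 30,
    "root_level": 200,
    "mm_per_px": 0.0846666666666667
  },
  "two_root": {
    "image_size": [400, 300],
    "trunk": {
      "row": [20, 110, 200, 290, 380],
      "col": [170, 168, 172, 170, 169]
    },
    "width": [9, 5],
    "second_trunk": {
      "trunk": {
        "row": [30, 120, 230, 340],
        "col": [80, 85, 75, 80]
      },
      "width": [7, 3]
    },
    "seed": 111,
    "bg_level": 30,
    "root_level": 200,
    "noise_sd": 0,
    "blur_sigma": 0,
    "mm_per_px": 0.0846666666666667
  },
  "wide_taper": {
    "image_size": [400, 300],
    "trunk": {
      "row": [20, 110, 200, 290, 380],
      "col": [150, 149, 151, 150, 150]
    },
    "width": [15, 3],
    "laterals": {
      "s": [0.35, 0.65],
      "side": [-1, 1],
      "angle": [75, 85],
      "length": [50, 45],
      "width": [3, 3]
    },
    "seed": 112,
    "bg_level": 30,
    "root_level": 200,
    "noise_sd": 0,
    "blur_sigma": 0,
    "mm_per_px": 0.0846666666666667
  }
}
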