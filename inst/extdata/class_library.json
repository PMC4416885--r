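{
  "Myocardium": {
    "class_code": 1,
    "class_name": "Myocardium",
    "peaks": [
      {
        "center": 1027,
        "height": 0.28,
        "fwhm": 25,
        "shape": "gaussian"
      },
      {
        "center": 1065,
        "height": 0.1,
        "fwhm": 25,
        "shape": "gaussian"
      },
      {
        "center": 1155,
        "height": 0.08,
        "fwhm": 25,
        "shape": "gaussian"
      },
      {
        "center": 1163,
        "height": 0.09,
        "fwhm": 25,
        "shape": "gaussian"
      },
      {
        "center": 1204,
        "height": 0.05,
        "fwhm": 25,
        "shape": "gaussian"
      },
      {
        "center": 1236,
        "height": 0.1,
        "fwhm": 25,
        "shape": "gaussian"
      },
      {
        "center": 1389,
        "height": 0.12,
        "fwhm": 25,
        "shape": "gaussian"
      },
      {
        "center": 1405,
        "height": 0.1,
        "fwhm": 25,
        "shape": "gaussian"
      },
      {
        "center": 1452,
        "height": 0.22,
        "fwhm": 25,
        "shape": "gaussian"
      },
      {
        "center": 1464,
        "height": 0,
        "fwhm": 25,
        "shape": "gaussian"
      },
      {
        "center": 1543,
        "height": 0.55,
        "fwhm": 25,
        "shape": "gaussian"
      },
      {
        "center": 1652,
        "height": 1,
        "fwhm": 25,
        "shape": "gaussian"
      },
      {
        "center": 3300,
        "height": 0.35,
        "fwhm": 120,
        "shape": "gaussian"
      }
    ]
  },
  "Endocardium": {
    "class_code": 2,
    "class_name": "Endocardium",
    "peaks": [
      {
        "center": 1027,
        "height": 0.14,
        "fwhm": 25,
        "shape": "gaussian"
      },
      {
        "center": 1065,
        "height": 0.12,
        "fwhm": 25,
        "shape": "gaussian"
      },
      {
        "center": 1155,
        "height": 0.1,
        "fwhm": 25,
        "shape": "gaussian"
      },
      {
        "center": 1163,
        "height": 0.12,
        "fwhm": 25,
        "shape": "gaussian"
      },
      {
        "center": 1204,
        "height": 0.16,
        "fwhm": 25,
        "shape": "gaussian"
      },
      {
        "center": 1236,
        "height": 0.26,
        "fwhm": 25,
        "shape": "gaussian"
      },
      {
        "center": 1389,
        "height": 0.14,
        "fwhm": 25,
        "shape": "gaussian"
      },
      {
        "center": 1405,
        "height": 0.11,
        "fwhm": 25,
        "shape": "gaussian"
      },
      {
        "center": 1452,
        "height": 0.26,
        "fwhm": 25,
        "shape": "gaussian"
      },
      {
        "center": 1464,
        "height": 0,
        "fwhm": 25,
        "shape": "gaussian"
      },
      {
        "center": 1543,
        "height": 0.52,
        "fwhm": 25,
        "shape": "gaussian"
      },
      {
        "center": 1652,
        "height": 1,
        "fwhm": 25,
        "shape": "gaussian"
      },
      {
        "center": 3300,
        "height": 0.33,
        "fwhm": 120,
        "shape": "gaussian"
      }
    ]
  },
  "Fibrosis-Endocardium": {
    "class_code": 3,
    "class_name": "Fibrosis-Endocardium",
    "peaks": [
      {
        "center": 1027,
        "height": 0.08,
        "fwhm": 25,
        "shape": "gaussian"
      },
      {
        "center": 1065,
        "height": 0.14,
        "fwhm": 25,
        "shape": "gaussian"
      },
      {
        "center": 1155,
        "height": 0.13,
        "fwhm": 25,
        "shape": "gaussian"
      },
      {
        "center": 1163,
        "height": 0.16,
        "fwhm": 25,
        "shape": "gaussian"
      },
      {
        "center": 1204,
        "height": 0.28,
        "fwhm": 25,
        "shape": "gaussian"
      },
      {
        "center": 1236,
        "height": 0.4,
        "fwhm": 25,
        "shape": "gaussian"
      },
      {
        "center": 1389,
        "height": 0.16,
        "fwhm": 25,
        "shape": "gaussian"
      },
      {
        "center": 1405,
        "height": 0.12,
        "fwhm": 25,
        "shape": "gaussian"
      },
      {
        "center": 1452,
        "height": 0.3,
        "fwhm": 25,
        "shape": "gaussian"
      },
      {
        "center": 1464,
        "height": 0,
        "fwhm": 25,
        "shape": "gaussian"
      },
      {
        "center": 1543,
        "height": 0.5,
        "fwhm": 25,
        "shape": "gaussian"
      },
      {
        "center": 1652,
        "height": 1,
        "fwhm": 25,
        "shape": "gaussian"
      },
      {
        "center": 3300,
        "height": 0.3,
        "fwhm": 120,
        "shape": "gaussian"
      }
    ]
  },
  "Fibrosis-Myocardium": {
    "class_code": 4,
    "class_name": "Fibrosis-Myocardium",
    "peaks": [
      {
        "center": 1027,
        "height": 0.1,
        "fwhm": 25,
        "shape": "gaussian"
      },
      {
        "center": 1065,
        "height": 0.13,
        "fwhm": 25,
        "shape": "gaussian"
      },
      {
        "center": 1155,
        "height": 0.12,
        "fwhm": 25,
        "shape": "gaussian"
      },
      {
        "center": 1163,
        "height": 0.14,
        "fwhm": 25,
        "shape": "gaussian"
      },
      {
        "center": 1204,
        "height": 0.22,
        "fwhm": 25,
        "shape": "gaussian"
      },
      {
        "center": 1236,
        "height": 0.34,
        "fwhm": 25,
        "shape": "gaussian"
      },
      {
        "center": 1389,
        "height": 0.15,
        "fwhm": 25,
        "shape": "gaussian"
      },
      {
        "center": 1405,
        "height": 0.12,
        "fwhm": 25,
        "shape": "gaussian"
      },
      {
        "center": 1452,
        "height": 0.28,
        "fwhm": 25,
        "shape": "gaussian"
      },
      {
        "center": 1464,
        "height": 0,
        "fwhm": 25,
        "shape": "gaussian"
      },
      {
        "center": 1543,
        "height": 0.51,
        "fwhm": 25,
        "shape": "gaussian"
      },
      {
        "center": 1652,
        "height": 1,
        "fwhm": 25,
        "shape": "gaussian"
      },
      {
        "center": 3300,
        "height": 0.31,
        "fwhm": 120,
        "shape": "gaussian"
      }
    ]
  },
  "Lymphocytes": {
    "class_code": 5,
    "class_name": "Lymphocytes",
    "peaks": [
      {
        "center": 1027,
        "height": 0.18,
        "fwhm": 25,
        "shape": "gaussian"
      },
      {
        "center": 1065,
        "height": 0.2,
        "fwhm": 25,
        "shape": "gaussian"
      },
      {
        "center": 1155,
        "height": 0.11,
        "fwhm": 25,
        "shape": "gaussian"
      },
      {
        "center": 1163,
        "height": 0.13,
        "fwhm": 25,
        "shape": "gaussian"
      },
      {
        "center": 1204,
        "height": 0.08,
        "fwhm": 25,
        "shape": "gaussian"
      },
      {
        "center": 1236,
        "height": 0.18,
        "fwhm": 25,
        "shape": "gaussian"
      },
      {
        "center": 1389,
        "height": 0.13,
        "fwhm": 25,
        "shape": "gaussian"
      },
      {
        "center": 1405,
        "height": 0.1,
        "fwhm": 25,
        "shape": "gaussian"
      },
      {
        "center": 1452,
        "height": 0.24,
        "fwhm": 25,
        "shape": "gaussian"
      },
      {
        "center": 1464,
        "height": 0,
        "fwhm": 25,
        "shape": "gaussian"
      },
      {
        "center": 1543,
        "height": 0.58,
        "fwhm": 25,
        "shape": "gaussian"
      },
      {
        "center": 1652,
        "height": 1,
        "fwhm": 25,
        "shape": "gaussian"
      },
      {
        "center": 3300,
        "height": 0.38,
        "fwhm": 120,
        "shape": "gaussian"
      }
    ]
  }
}
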