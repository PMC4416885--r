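[
  {
    "name": "phr_1389_1236",
    "kind": "peak_height_ratio",
    "params": [1389, 1236]
  },
  {
    "name": "phr_3315_1236",
    "kind": "peak_height_ratio",
    "params": [3315, 1236]
  },
  {
    "name": "phr_1204_1236",
    "kind": "peak_height_ratio",
    "params": [1204, 1236]
  },
  {
    "name": "phr_1027_1065",
    "kind": "peak_height_ratio",
    "params": [1027, 1065]
  },
  {
    "name": "phr_1163_1236",
    "kind": "peak_height_ratio",
    "params": [1163, 1236]
  },
  {
    "name": "phr_1239_1652",
    "kind": "peak_height_ratio",
    "params": [1239, 1652]
  },
  {
    "name": "phr_1239_1543",
    "kind": "peak_height_ratio",
    "params": [1239, 1543]
  },
  {
    "name": "phr_1163_1065",
    "kind": "peak_height_ratio",
    "params": [1163, 1065]
  },
  {
    "name": "phr_1236_1543",
    "kind": "peak_height_ratio",
    "params": [1236, 1543]
  },
  {
    "name": "phr_1389_1452",
    "kind": "peak_height_ratio",
    "params": [1389, 1452]
  },
  {
    "name": "phr_1452_1543",
    "kind": "peak_height_ratio",
    "params": [1452, 1543]
  },
  {
    "name": "phr_1236_3300",
    "kind": "peak_height_ratio",
    "params": [1236, 3300]
  },
  {
    "name": "phr_1239_3300",
    "kind": "peak_height_ratio",
    "params": [1239, 3300]
  },
  {
    "name": "phr_1389_1652",
    "kind": "peak_height_ratio",
    "params": [1389, 1652]
  },
  {
    "name": "phr_1389_3300",
    "kind": "peak_height_ratio",
    "params": [1389, 3300]
  },
  {
    "name": "phr_1389_1065",
    "kind": "peak_height_ratio",
    "params": [1389, 1065]
  },
  {
    "name": "phr_1452_1236",
    "kind": "peak_height_ratio",
    "params": [1452, 1236]
  },
  {
    "name": "phr_1027_1543",
    "kind": "peak_height_ratio",
    "params": [1027, 1543]
  },
  {
    "name": "phr_1405_1236",
    "kind": "peak_height_ratio",
    "params": [1405, 1236]
  },
  {
    "name": "phr_1155_1452",
    "kind": "peak_height_ratio",
    "params": [1155, 1452]
  },
  {
    "name": "phr_1032_1236",
    "kind": "peak_height_ratio",
    "params": [1032, 1236]
  },
  {
    "name": "ahr_1482_1594_1652",
    "kind": "area_to_height_ratio",
    "params": [1482, 1594, 1652]
  },
  {
    "name": "ahr_1424_1480_1546",
    "kind": "area_to_height_ratio",
    "params": [1424, 1480, 1546]
  },
  {
    "name": "ahr_1184_1300_1652",
    "kind": "area_to_height_ratio",
    "params": [1184, 1300, 1652]
  },
  {
    "name": "cog_1184_1302_1188_1216",
    "kind": "center_of_gravity",
    "params": [1184, 1302, 1188, 1216]
  },
  {
    "name": "cog_1482_1726_1482_1594",
    "kind": "center_of_gravity",
    "params": [1482, 1726, 1482, 1594]
  },
  {
    "name": "cog_984_1144_1016_1048",
    "kind": "center_of_gravity",
    "params": [984, 1144, 1016, 1048]
  }
]
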