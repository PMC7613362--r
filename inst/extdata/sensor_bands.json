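{
  "MSI": {
    "mission": "Sentinel-2A",
    "bands": [
      {"band": "B2",  "domain": "VIS",  "center": 490,  "width": 65},
      {"band": "B3",  "domain": "VIS",  "center": 560,  "width": 35},
      {"band": "B4",  "domain": "VIS",  "center": 665,  "width": 30},
      {"band": "B5",  "domain": "NIR",  "center": 705,  "width": 15},
      {"band": "B6",  "domain": "NIR",  "center": 740,  "width": 15},
      {"band": "B7",  "domain": "NIR",  "center": 783,  "width": 20},
      {"band": "B8",  "domain": "NIR",  "center": 842,  "width": 115},
      {"band": "B8A", "domain": "NIR",  "center": 865,  "width": 20},
      {"band": "B11", "domain": "SWIR", "center": 1610, "width": 90},
      {"band": "B12", "domain": "SWIR", "center": 2190, "width": 180}
    ]
  },
  "ETM+": {
    "mission": "Landsat 7",
    "bands": [
      {"band": "B1", "domain": "VIS",  "center": 485,  "width": 70},
      {"band": "B2", "domain": "VIS",  "center": 560,  "width": 80},
      {"band": "B3", "domain": "VIS",  "center": 660,  "width": 60},
      {"band": "B4", "domain": "NIR",  "center": 835,  "width": 130},
      {"band": "B5", "domain": "SWIR", "center": 1650, "width": 200},
      {"band": "B7", "domain": "SWIR", "center": 2220, "width": 260}
    ]
  },
  "OLI": {
    "mission": "Landsat 8",
    "bands": [
      {"band": "B2", "domain": "VIS",  "center": 482,  "width": 60},
      {"band": "B3", "domain": "VIS",  "center": 561,  "width": 57},
      {"band": "B4", "domain": "VIS",  "center": 654,  "width": 37},
      {"band": "B5", "domain": "NIR",  "center": 864,  "width": 30},
      {"band": "B6", "domain": "SWIR", "center": 1608, "width": 84},
      {"band": "B7", "domain": "SWIR", "center": 2200, "width": 187}
    ]
  }
}
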