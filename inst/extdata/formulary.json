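{
  "version": "cdc-2016-oral-mme/strengths-2026-01",
  "opioids": [
    {
      "name": "morphine",
      "ome_factor": 1,
      "formulations": [
        {"strength_mg": 10, "release": "immediate", "units_per_pack": 20},
        {"strength_mg": 20, "release": "immediate", "units_per_pack": 20},
        {"strength_mg": 10, "release": "extended", "units_per_pack": 30},
        {"strength_mg": 30, "release": "extended", "units_per_pack": 30},
        {"strength_mg": 60, "release": "extended", "units_per_pack": 30},
        {"strength_mg": 100, "release": "extended", "units_per_pack": 30}
      ],
      "is_backup_suitable": true
    },
    {
      "name": "oxycodone",
      "ome_factor": 1.5,
      "formulations": [
        {"strength_mg": 5, "release": "immediate", "units_per_pack": 20},
        {"strength_mg": 10, "release": "immediate", "units_per_pack": 20},
        {"strength_mg": 20, "release": "immediate", "units_per_pack": 20},
        {"strength_mg": 5, "release": "extended", "units_per_pack": 30},
        {"strength_mg": 10, "release": "extended", "units_per_pack": 30},
        {"strength_mg": 20, "release": "extended", "units_per_pack": 30},
        {"strength_mg": 40, "release": "extended", "units_per_pack": 30},
        {"strength_mg": 80, "release": "extended", "units_per_pack": 30}
      ],
      "is_backup_suitable": true
    },
    {
      "name": "hydromorphone",
      "ome_factor": 4,
      "formulations": [
        {"strength_mg": 1.3, "release": "immediate", "units_per_pack": 20},
        {"strength_mg": 2.6, "release": "immediate", "units_per_pack": 20},
        {"strength_mg": 4, "release": "extended", "units_per_pack": 30},
        {"strength_mg": 8, "release": "extended", "units_per_pack": 30},
        {"strength_mg": 16, "release": "extended", "units_per_pack": 30},
        {"strength_mg": 24, "release": "extended", "units_per_pack": 30}
      ],
      "is_backup_suitable": true
    },
    {
      "name": "tramadol",
      "ome_factor": 0.1,
      "formulations": [
        {"strength_mg": 50, "release": "immediate", "units_per_pack": 20},
        {"strength_mg": 100, "release": "extended", "units_per_pack": 30},
        {"strength_mg": 150, "release": "extended", "units_per_pack": 30},
        {"strength_mg": 200, "release": "extended", "units_per_pack": 30}
      ],
      "is_backup_suitable": true
    },
    {
      "name": "tapentadol",
      "ome_factor": 0.4,
      "formulations": [
        {"strength_mg": 50, "release": "immediate", "units_per_pack": 20},
        {"strength_mg": 75, "release": "immediate", "units_per_pack": 20},
        {"strength_mg": 50, "release": "extended", "units_per_pack": 30},
        {"strength_mg": 100, "release": "extended", "units_per_pack": 30},
        {"strength_mg": 150, "release": "extended", "units_per_pack": 30},
        {"strength_mg": 200, "release": "extended", "units_per_pack": 30},
        {"strength_mg": 250, "release": "extended", "units_per_pack": 30}
      ],
      "is_backup_suitable": true
    },
    {
      "name": "codeine",
      "ome_factor": 0.15,
      "formulations": [
        {"strength_mg": 30, "release": "immediate", "units_per_pack": 20},
        {"strength_mg": 60, "release": "immediate", "units_per_pack": 20}
      ],
      "is_backup_suitable": true
    }
  ]
}
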