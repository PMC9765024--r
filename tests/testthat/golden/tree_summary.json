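{
  "query": "SYN0001",
  "members": ["SYN0001", "FAM001", "FAM002", "FAM003", "FAM004", "FAM005"],
  "n_columns": 9,
  "columns": [6, 11, 35, 54, 63, 87, 92, 112, 114],
  "anchor_positions": {
    "col6": 6,
    "col11": 11,
    "col35": 35,
    "col54": 54,
    "col63": 63,
    "col87": 87,
    "col92": 92,
    "col112": 112,
    "col114": 114
  },
  "known_sites": {
    "SYN0001": [
      {
        "category": "active",
        "comment": "Nucleophile",
        "position": 54,
        "column": 54
      },
      {
        "category": "binding",
        "comment": "Zinc",
        "position": 92,
        "column": 92
      },
      {
        "category": "binding",
        "comment": "Zinc",
        "position": 112,
        "column": 112
      },
      {
        "category": "modified",
        "comment": "",
        "position": 6,
        "column": 6
      },
      {
        "category": "modified",
        "comment": "",
        "position": 114,
        "column": 114
      },
      {
        "category": "active",
        "comment": "Nucleophile",
        "position": 63,
        "column": 63
      },
      {
        "category": "binding",
        "comment": "Zinc",
        "position": 35,
        "column": 35
      },
      {
        "category": "binding",
        "comment": "Zinc",
        "position": 87,
        "column": 87
      },
      {
        "category": "mutagenesis",
        "comment": "Loss of activity",
        "position": 11,
        "column": 11
      }
    ]
  },
  "tree": "((((FAM001:0.03947444246,(FAM002:0.1355729502,FAM004:0.4283624989):0.02216757346):0.01387999284,SYN0001:0):0.02079648938,FAM003:0.2781650605):0.04919913895,FAM005:0.5344056935);"
}
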