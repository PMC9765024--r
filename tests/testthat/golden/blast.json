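{
  "query": {
    "id": "SYN0001",
    "description": "Synthetic fixture protein 1",
    "length": 116
  },
  "params": {
    "max_evalue": 0.001,
    "max_hits": 20,
    "db_len": 723
  },
  "hits": [
    {
      "subject_id": "SYN0001",
      "subject_description": "Synthetic fixture protein 1",
      "raw_score": 685,
      "bit_score": 268.4699,
      "evalue": 1.27671e-76,
      "percent_identity": 100,
      "q_start": 1,
      "q_end": 116,
      "s_start": 1,
      "s_end": 116,
      "q_aligned": "EHACMQVWALQLHKRFKQFFCLNRAYDGLLGRYYNGINGHWLGQCPVQGAWWIGNGIHMTEPISQYHPNSAPGTKHWVSMLHWCLAMRLSNHIAWDMAQGYKFQTDDHQDWNTKVT",
      "s_aligned": "EHACMQVWALQLHKRFKQFFCLNRAYDGLLGRYYNGINGHWLGQCPVQGAWWIGNGIHMTEPISQYHPNSAPGTKHWVSMLHWCLAMRLSNHIAWDMAQGYKFQTDDHQDWNTKVT",
      "sites": [
        {
          "category": "active",
          "comment": "Nucleophile",
          "ligand": "",
          "subject_pos": 54,
          "subject_res": "G",
          "query_pos": 54,
          "query_res": "G",
          "status": "match",
          "label": "G54 (= G54)"
        },
        {
          "category": "binding",
          "comment": "Zinc",
          "ligand": "",
          "subject_pos": 92,
          "subject_res": "H",
          "query_pos": 92,
          "query_res": "H",
          "status": "match",
          "label": "H92 (= H92)"
        },
        {
          "category": "binding",
          "comment": "Zinc",
          "ligand": "",
          "subject_pos": 112,
          "subject_res": "N",
          "query_pos": 112,
          "query_res": "N",
          "status": "match",
          "label": "N112 (= N112)"
        },
        {
          "category": "modified",
          "comment": "",
          "ligand": "",
          "subject_pos": 6,
          "subject_res": "Q",
          "query_pos": 6,
          "query_res": "Q",
          "status": "match",
          "label": "Q6 (= Q6)"
        },
        {
          "category": "modified",
          "comment": "",
          "ligand": "",
          "subject_pos": 114,
          "subject_res": "K",
          "query_pos": 114,
          "query_res": "K",
          "status": "match",
          "label": "K114 (= K114)"
        },
        {
          "category": "active",
          "comment": "Nucleophile",
          "ligand": "",
          "subject_pos": 63,
          "subject_res": "I",
          "query_pos": 63,
          "query_res": "I",
          "status": "match",
          "label": "I63 (= I63)"
        },
        {
          "category": "binding",
          "comment": "Zinc",
          "ligand": "",
          "subject_pos": 35,
          "subject_res": "N",
          "query_pos": 35,
          "query_res": "N",
          "status": "match",
          "label": "N35 (= N35)"
        },
        {
          "category": "binding",
          "comment": "Zinc",
          "ligand": "",
          "subject_pos": 87,
          "subject_res": "M",
          "query_pos": 87,
          "query_res": "M",
          "status": "match",
          "label": "M87 (= M87)"
        },
        {
          "category": "mutagenesis",
          "comment": "Loss of activity",
          "ligand": "",
          "subject_pos": 11,
          "subject_res": "Q",
          "query_pos": 11,
          "query_res": "Q",
          "status": "match",
          "label": "Q11 (= Q11)"
        }
      ]
    }
  ]
}
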