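{
  "store": {
    "synthetic": {
      "n_reports": 20000,
      "seed": 42,
      "signals": {
        "drug_code": "NILOTINIB",
        "pt_code": "PT_NEPHROTIC_SYNDROME",
        "lambda": 5
      }
    }
  },
  "dictionary": "demo",
  "selection": {},
  "screen": { "min_cases": 5, "z": 1.96 },
  "report": { "top_k": 5 },
  "out_dir": "rorscreen_demo_out"
}
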