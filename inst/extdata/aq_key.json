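{
  "n_items": 50,
  "agree_keyed_items": [2, 4, 5, 6, 7, 9, 12, 13, 16, 18, 19, 20, 21, 22, 23, 26, 33, 35, 39, 41, 42, 43, 45, 46],
  "note": "standard published AQ key: TRUE direction = agreement indicates autistic traits"
}
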