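{
  "id": [1, 2, 3, 4, 5, 6, 7, 8],
  "m1": [2, 1, 1, 2, 2, 1, 1, 2],
  "m2": [5, 3, 4, 6, 5, 3, 4, 6],
  "m3": [7, 8, 10, 9, 8, 7, 9, 10],
  "hemifield": ["upper", "upper", "lower", "lower", "upper", "upper", "lower", "lower"]
}
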