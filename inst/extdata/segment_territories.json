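{
  "_comment": "Approximate default mapping of the 16-segment canine short-axis model to coronary territories (anterior/anteroseptal -> LAD, lateral/inferolateral -> LCX, inferoseptal/apical overlap -> BOTH). The published layout is pictorial only; edit this file to match your contours.",
  "1": "LAD",
  "2": "LAD",
  "3": "BOTH",
  "4": "LCX",
  "5": "LCX",
  "6": "LAD",
  "7": "LAD",
  "8": "LAD",
  "9": "BOTH",
  "10": "LCX",
  "11": "LCX",
  "12": "LAD",
  "13": "LAD",
  "14": "BOTH",
  "15": "LCX",
  "16": "BOTH"
}
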