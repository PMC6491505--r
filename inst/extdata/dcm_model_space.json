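{
  "nodes": ["IPL", "rPFC", "DLPFC", "SFG"],
  "inputs": ["stim", "regular", "different"],
  "base": {
    "a": [["IPL", "rPFC"], ["IPL", "DLPFC"], ["DLPFC", "IPL"]],
    "b": {
      "regular": [["IPL", "rPFC"]],
      "different": [["IPL", "DLPFC"]]
    },
    "c": {"stim": ["IPL"]}
  },
  "models": [
    {
      "name": "Diamond",
      "class": "bilinear",
      "a": [["rPFC", "SFG"], ["DLPFC", "SFG"]]
    },
    {
      "name": "Fork",
      "class": "bilinear",
      "a": [["IPL", "SFG"]],
      "b": {
        "regular": [["IPL", "SFG"]],
        "different": [["IPL", "SFG"]]
      }
    },
    {
      "name": "Legs1",
      "class": "bilinear",
      "a": [["DLPFC", "SFG"]],
      "b": {"regular": [["DLPFC", "SFG"]]}
    },
    {
      "name": "Legs2",
      "class": "bilinear",
      "a": [["rPFC", "SFG"]],
      "b": {"different": [["rPFC", "SFG"]]}
    },
    {
      "name": "Stork1",
      "class": "nonlinear",
      "a": [["DLPFC", "SFG"]],
      "d": {"rPFC": [["DLPFC", "SFG"]]}
    },
    {
      "name": "Stork2",
      "class": "nonlinear",
      "a": [["rPFC", "SFG"]],
      "d": {"DLPFC": [["rPFC", "SFG"]]}
    },
    {
      "name": "Stork3",
      "class": "nonlinear",
      "a": [["DLPFC", "SFG"], ["rPFC", "SFG"]],
      "d": {
        "rPFC": [["DLPFC", "SFG"]],
        "DLPFC": [["rPFC", "SFG"]]
      }
    }
  ]
}
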