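[
  {
    "scenario": "A",
    "n": 1000,
    "censoring": "uniform",
    "a": 60,
    "y": 120,
    "tau": 3
  },
  {
    "scenario": "B",
    "n": 1000,
    "censoring": "uniform",
    "a": 60,
    "y": 120,
    "tau": 6
  },
  {
    "scenario": "C",
    "n": 1000,
    "censoring": "uniform",
    "a": 60,
    "y": 120,
    "tau": 12
  },
  {
    "scenario": "D",
    "n": 1000,
    "censoring": "admin",
    "a": null,
    "y": 120,
    "tau": 3
  },
  {
    "scenario": "E",
    "n": 1000,
    "censoring": "admin",
    "a": null,
    "y": 120,
    "tau": 6
  },
  {
    "scenario": "F",
    "n": 1000,
    "censoring": "admin",
    "a": null,
    "y": 120,
    "tau": 12
  },
  {
    "scenario": "G",
    "n": 2000,
    "censoring": "uniform",
    "a": 60,
    "y": 120,
    "tau": 3
  },
  {
    "scenario": "H",
    "n": 2000,
    "censoring": "uniform",
    "a": 60,
    "y": 120,
    "tau": 6
  },
  {
    "scenario": "I",
    "n": 2000,
    "censoring": "uniform",
    "a": 60,
    "y": 120,
    "tau": 12
  },
  {
    "scenario": "J",
    "n": 2000,
    "censoring": "admin",
    "a": null,
    "y": 120,
    "tau": 3
  },
  {
    "scenario": "K",
    "n": 2000,
    "censoring": "admin",
    "a": null,
    "y": 120,
    "tau": 6
  },
  {
    "scenario": "L",
    "n": 2000,
    "censoring": "admin",
    "a": null,
    "y": 120,
    "tau": 12
  },
  {
    "scenario": "M",
    "n": 400,
    "censoring": "uniform",
    "a": 60,
    "y": 120,
    "tau": 3
  },
  {
    "scenario": "N",
    "n": 400,
    "censoring": "uniform",
    "a": 60,
    "y": 120,
    "tau": 6
  },
  {
    "scenario": "O",
    "n": 400,
    "censoring": "uniform",
    "a": 60,
    "y": 120,
    "tau": 12
  },
  {
    "scenario": "P",
    "n": 400,
    "censoring": "admin",
    "a": null,
    "y": 120,
    "tau": 3
  },
  {
    "scenario": "Q",
    "n": 400,
    "censoring": "admin",
    "a": null,
    "y": 120,
    "tau": 6
  },
  {
    "scenario": "R",
    "n": 400,
    "censoring": "admin",
    "a": null,
    "y": 120,
    "tau": 12
  }
]
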