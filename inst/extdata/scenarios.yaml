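# Scenario grid mirroring the reported analyses.
scenarios:
  - {name: base, download_multiplier: 1.0, discount_rate: 0.03, decay: true, equity: false}
  - {name: download_x1_5, download_multiplier: 1.5, discount_rate: 0.03, decay: true, equity: false}
  - {name: download_x2, download_multiplier: 2.0, discount_rate: 0.03, decay: true, equity: false}
  - {name: discount_0, download_multiplier: 1.0, discount_rate: 0.00, decay: true, equity: false}
  - {name: discount_6, download_multiplier: 1.0, discount_rate: 0.06, decay: true, equity: false}
  - {name: no_decay, download_multiplier: 1.0, discount_rate: 0.03, decay: false, equity: false}
  - {name: equity, download_multiplier: 1.0, discount_rate: 0.03, decay: true, equity: true}
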