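{
  "description": "Per-category baseline hospital costs (CNY) of the manual-stapler reference scenario in the published base-case decision model. Used as the calibration of the aggregate-calibrated mode; acquisition (stapler/cartridge) costs are not part of the calibration because they follow from unit prices and utilization.",
  "disposables": 9989,
  "drugs": 13043,
  "operation": 7643,
  "laboratory": 11162,
  "other": 2248
}
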