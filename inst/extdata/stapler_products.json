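{
  "description": "Device price list and per-episode utilization means. Unit prices (CNY) are the published ones: ECHELON powered PSE45A stapler 6790 with ECR45B cartridge 2441; ECHELON manual EC45A stapler 3970 with ECR45B cartridge 2441; Victor Medical manual stapler 3800 with cartridge 2987. Utilization means are back-solved from the published base-case acquisition costs (8327/6790, 17129/2441, 4790/3970, 18308/2441), since only the rounded means 1.2 and 7.0/7.5 are printed. The Victor Medical product carries the published base-case acquisition cells (stapler 4882, cartridge 20974) as an acquisition_override because they are inconsistent with counts x unit prices (4585/22404); the price-only path is obtained by dropping the override.",
  "echelon_powered": {
    "name": "ECHELON powered (PSE45A / ECR45B)",
    "stapler_unit_price": 6790,
    "cartridge_unit_price": 2441,
    "mean_staplers": 1.22636229749632,
    "mean_cartridges": 7.0172060630889
  },
  "echelon_manual": {
    "name": "ECHELON manual (EC45A / ECR45B)",
    "stapler_unit_price": 3970,
    "cartridge_unit_price": 2441,
    "mean_staplers": 1.20654911838791,
    "mean_cartridges": 7.50020483408439
  },
  "victor_manual": {
    "name": "Victor Medical manual",
    "stapler_unit_price": 3800,
    "cartridge_unit_price": 2987,
    "mean_staplers": 1.20654911838791,
    "mean_cartridges": 7.50020483408439,
    "acquisition_override": { "stapler": 4882, "cartridge": 20974 }
  }
}
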