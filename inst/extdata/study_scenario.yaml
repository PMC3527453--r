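# Default study scenario: smoking-stratum case/control quotas matching the
# motivating bladder-cancer case-control series (1,494 cases / 1,723
# controls with known smoking habits), control genotype frequencies from
# the package panel, no planted genetic effects.
strata:
  non:
    cases: 321
    controls: 752
  former:
    cases: 742
    controls: 656
  current:
    cases: 431
    controls: 315
baseline: 0.05
age:
  case:
    mean: 66
    sd: 10
  control:
    mean: 63
    sd: 11
gender:
  male: 0.8
  female: 0.2
sites:
  A: 0.35
  B: 0.15
  C: 0.20
  D: 0.30
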