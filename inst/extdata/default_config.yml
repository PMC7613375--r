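# Default simulator input distributions (units as in the package docs).
# kind: uniform | truncated-gaussian | fixed
distributions:
  N:          {kind: truncated-gaussian, min: 1.0,   max: 2.7,   mean: 1.5,    sd: 0.5}
  Cab:        {kind: truncated-gaussian, min: 0,     max: 80,    mean: 45,     sd: 35}
  Cm:         {kind: truncated-gaussian, min: 0.002, max: 0.02,  mean: 0.0075, sd: 0.005}
  Cw:         {kind: truncated-gaussian, min: 0.005, max: 0.035, mean: 0.015,  sd: 0.0075}
  Cxc:        {kind: uniform, min: 0,   max: 20}
  LAI:        {kind: uniform, min: 0.1, max: 8}
  LIDF:       {kind: uniform, min: -1,  max: 1}
  alpha_soil: {kind: uniform, min: 0,   max: 1}
  SZA:        {kind: uniform, min: 0,   max: 80}
  OZA:        {kind: uniform, min: 0,   max: 25}
  RAA:        {kind: uniform, min: 0,   max: 180}
  SMC:        {kind: truncated-gaussian, min: 5,  max: 55,  mean: 25,  sd: 12.5}
  B_soil:     {kind: truncated-gaussian, min: 0,  max: 0.9, mean: 0.5, sd: 0.25}
  BSM_lat:    {kind: truncated-gaussian, min: 20, max: 40,  mean: 25,  sd: 12.5}
  BSM_lon:    {kind: truncated-gaussian, min: 45, max: 65,  mean: 50,  sd: 10}
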