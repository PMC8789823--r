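K: 4
D:
- 0.005
- 0.03
- 0.12
- 0.45
A:
- - 0.94
  - 0.02
  - 0.02
  - 0.02
- - 0.02
  - 0.94
  - 0.02
  - 0.02
- - 0.02
  - 0.02
  - 0.94
  - 0.02
- - 0.02
  - 0.02
  - 0.02
  - 0.94
pi:
- 0.25
- 0.25
- 0.25
- 0.25
confinement:
- 0.12
- 0.2
- .na.real
- .na.real
sigma_loc: 0.02
dt: 0.0305
n_frames: 300
n_tracks: 200
field: 25.0
binding:
  k_on: 0.3
  tau: 0.3
  offset_sd: 0.015
intensity:
  mu1: 100.0
  cv1: 0.25
  oligomer_weights:
  - - 0.1
    - 0.5
    - 0.3
    - 0.1
  - - 0.4
    - 0.5
    - 0.08
    - 0.02
  - - 0.55
    - 0.35
    - 0.08
    - 0.02
  - - 1.0
    - 0.0
    - 0.0
    - 0.0
bleach_rate: 0.995
seed: 1
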