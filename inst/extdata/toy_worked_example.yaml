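horizon: 480.0
mode: space
areas:
- id: main
  spaces:
  - id: s1
    availability: 480.0
    service_level: 0.95
  - id: s2
    availability: 480.0
    service_level: 0.95
patient_types:
- type: g1
  mix: 0.588235294117647
  pathways:
  - path: p1
    mix: 1.0
    activities:
    - id: a1
      activity_type: generic
      duration:
        kind: point-mass
        value: 60.0
      spaces:
      - s1
      - s2
- type: g2
  mix: 0.411764705882353
  pathways:
  - path: p1
    mix: 1.0
    activities:
    - id: a2
      activity_type: generic
      duration:
        kind: point-mass
        value: 45.0
      spaces: s1
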