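{
  "horizon": 480,
  "mode": "space",
  "areas": [
    {
      "id": "main",
      "spaces": [
        {
          "id": "s1",
          "availability": 480,
          "service_level": 0.95
        },
        {
          "id": "s2",
          "availability": 480,
          "service_level": 0.95
        }
      ]
    }
  ],
  "patient_types": [
    {
      "type": "g1",
      "mix": 1,
      "pathways": [
        {
          "path": "p1",
          "mix": 1,
          "activities": [
            {
              "id": "a1",
              "activity_type": "generic",
              "duration": {
                "kind": "point-mass",
                "value": 60
              },
              "spaces": ["s1", "s2"]
            },
            {
              "id": "a2",
              "activity_type": "generic",
              "duration": {
                "kind": "point-mass",
                "value": 45
              },
              "spaces": "s1"
            }
          ]
        }
      ]
    }
  ]
}
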