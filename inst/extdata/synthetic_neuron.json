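{
  "comment": "synthetic single-neuron fixture in the MouseLight-style JSON layout; coordinates in micrometers, allenId carries the parcel annotation",
  "neuron": {
    "idString": "SYN0001",
    "soma": { "x": 9000, "y": 2500, "z": 4600, "radius": 6, "allenId": 1037 },
    "axon": [
      { "sampleNumber": 1, "structureIdentifier": 2, "x": 9000, "y": 2500, "z": 4600, "radius": 0.5, "parentNumber": -1, "allenId": 1037 },
      { "sampleNumber": 2, "structureIdentifier": 2, "x": 9050, "y": 2480, "z": 4620, "radius": 0.5, "parentNumber": 1, "allenId": 1037 },
      { "sampleNumber": 3, "structureIdentifier": 2, "x": 9150, "y": 2450, "z": 4700, "radius": 0.5, "parentNumber": 2, "allenId": 918 },
      { "sampleNumber": 4, "structureIdentifier": 2, "x": 9260, "y": 2430, "z": 4790, "radius": 0.5, "parentNumber": 3, "allenId": 918 },
      { "sampleNumber": 5, "structureIdentifier": 2, "x": 9370, "y": 2410, "z": 4885, "radius": 0.5, "parentNumber": 4, "allenId": 918 },
      { "sampleNumber": 6, "structureIdentifier": 2, "x": 9200, "y": 2500, "z": 4760, "radius": 0.5, "parentNumber": 3, "allenId": 502 },
      { "sampleNumber": 7, "structureIdentifier": 2, "x": 9250, "y": 2570, "z": 4820, "radius": 0.5, "parentNumber": 6, "allenId": 502 }
    ],
    "dendrite": [
      { "sampleNumber": 1, "structureIdentifier": 3, "x": 9000, "y": 2500, "z": 4600, "radius": 1, "parentNumber": -1, "allenId": 1037 },
      { "sampleNumber": 2, "structureIdentifier": 3, "x": 8980, "y": 2530, "z": 4580, "radius": 1, "parentNumber": 1, "allenId": 1037 }
    ]
  }
}
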