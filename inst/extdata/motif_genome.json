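{
  "nodes": [
    {
      "id": -1,
      "role": "input",
      "activation": "sigmoid",
      "aggregation": "sum",
      "bias": 0,
      "response": 1
    },
    {
      "id": -2,
      "role": "input",
      "activation": "sigmoid",
      "aggregation": "sum",
      "bias": 0,
      "response": 1
    },
    {
      "id": -3,
      "role": "input",
      "activation": "sigmoid",
      "aggregation": "sum",
      "bias": 0,
      "response": 1
    },
    {
      "id": -4,
      "role": "input",
      "activation": "sigmoid",
      "aggregation": "sum",
      "bias": 0,
      "response": 1
    },
    {
      "id": 0,
      "role": "output",
      "activation": "sigmoid",
      "aggregation": "sum",
      "bias": -0.9,
      "response": 1
    },
    {
      "id": 1,
      "role": "output",
      "activation": "sigmoid",
      "aggregation": "sum",
      "bias": -4,
      "response": 1
    },
    {
      "id": 2,
      "role": "output",
      "activation": "sigmoid",
      "aggregation": "sum",
      "bias": -3.2,
      "response": 1
    },
    {
      "id": 3,
      "role": "output",
      "activation": "sigmoid",
      "aggregation": "sum",
      "bias": -4,
      "response": 1
    },
    {
      "id": 4,
      "role": "output",
      "activation": "sigmoid",
      "aggregation": "sum",
      "bias": 0.3,
      "response": 1
    },
    {
      "id": 5,
      "role": "output",
      "activation": "sigmoid",
      "aggregation": "sum",
      "bias": -4,
      "response": 1
    },
    {
      "id": 6,
      "role": "hidden",
      "activation": "sigmoid",
      "aggregation": "sum",
      "bias": -19.8,
      "response": 1
    },
    {
      "id": 7,
      "role": "hidden",
      "activation": "sigmoid",
      "aggregation": "sum",
      "bias": 13.2,
      "response": 1
    },
    {
      "id": 9,
      "role": "hidden",
      "activation": "sigmoid",
      "aggregation": "sum",
      "bias": -16.8,
      "response": 1
    }
  ],
  "connections": [
    {
      "source": -4,
      "target": 0,
      "weight": 2,
      "enabled": true
    },
    {
      "source": 0,
      "target": 0,
      "weight": -4,
      "enabled": true
    },
    {
      "source": -1,
      "target": 4,
      "weight": 2,
      "enabled": true
    },
    {
      "source": -2,
      "target": 2,
      "weight": 4,
      "enabled": true
    },
    {
      "source": 0,
      "target": 6,
      "weight": 60,
      "enabled": true
    },
    {
      "source": 6,
      "target": 4,
      "weight": 0.4,
      "enabled": true
    },
    {
      "source": 0,
      "target": 7,
      "weight": -60,
      "enabled": true
    },
    {
      "source": 7,
      "target": 4,
      "weight": 0.2,
      "enabled": true
    },
    {
      "source": -1,
      "target": 9,
      "weight": 12,
      "enabled": true
    },
    {
      "source": -4,
      "target": 9,
      "weight": 12,
      "enabled": true
    },
    {
      "source": 9,
      "target": 4,
      "weight": -4,
      "enabled": true
    },
    {
      "source": -3,
      "target": 3,
      "weight": 0.1,
      "enabled": false
    },
    {
      "source": -2,
      "target": 5,
      "weight": -0.2,
      "enabled": false
    }
  ],
  "metadata": {
    "name": "sprague_motif",
    "description": "Synthetic ground-truth network with an inhibitory self-loop motif producing a paradoxical lesion effect between (0->0) and (-4->0).",
    "sigmoid": "plain logistic 1/(1+exp(-z)), z clamped to [-60, 60]",
    "target_action": 4
  }
}
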