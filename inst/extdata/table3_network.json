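{
  "variables": [
    {
      "name": "exposure",
      "states": ["low", "moderate", "high"]
    },
    {
      "name": "sensitivity",
      "states": ["low", "moderate", "high"]
    },
    {
      "name": "annoyance",
      "states": ["low", "moderate", "high"]
    },
    {
      "name": "quality",
      "states": ["undesirable", "partly_desirable", "desirable"]
    }
  ],
  "cpts": [
    {
      "child": "exposure",
      "parents": [],
      "rows": [
        {
          "config": [],
          "p": [0.22488038277512, 0.602870813397129, 0.172248803827751]
        }
      ]
    },
    {
      "child": "sensitivity",
      "parents": [],
      "rows": [
        {
          "config": [],
          "p": [0.282296650717703, 0.444976076555024, 0.272727272727273]
        }
      ]
    },
    {
      "child": "annoyance",
      "parents": [],
      "rows": [
        {
          "config": [],
          "p": [0.291866028708134, 0.497607655502392, 0.210526315789474]
        }
      ]
    },
    {
      "child": "quality",
      "parents": ["exposure", "sensitivity", "annoyance"],
      "rows": [
        {
          "config": ["low", "low", "low"],
          "p": [0.037, 0.333, 0.63]
        },
        {
          "config": ["moderate", "low", "low"],
          "p": [0, 0.231, 0.769]
        },
        {
          "config": ["high", "low", "low"],
          "p": [0.333, 0.333, 0.334]
        },
        {
          "config": ["low", "moderate", "low"],
          "p": [0.167, 0.083, 0.75]
        },
        {
          "config": ["moderate", "moderate", "low"],
          "p": [0, 0.2, 0.8]
        },
        {
          "config": ["high", "moderate", "low"],
          "p": [0, 1, 0]
        },
        {
          "config": ["low", "high", "low"],
          "p": [1, 0, 0]
        },
        {
          "config": ["moderate", "high", "low"],
          "p": [0.5, 0.5, 0]
        },
        {
          "config": ["high", "high", "low"],
          "p": [0.333, 0.333, 0.334]
        },
        {
          "config": ["low", "low", "moderate"],
          "p": [0.333, 0.333, 0.334]
        },
        {
          "config": ["moderate", "low", "moderate"],
          "p": [0.118, 0.353, 0.529]
        },
        {
          "config": ["high", "low", "moderate"],
          "p": [0, 1, 0]
        },
        {
          "config": ["low", "moderate", "moderate"],
          "p": [0.5, 0.333, 0.167]
        },
        {
          "config": ["moderate", "moderate", "moderate"],
          "p": [0.038, 0.481, 0.481]
        },
        {
          "config": ["high", "moderate", "moderate"],
          "p": [0, 1, 0]
        },
        {
          "config": ["low", "high", "moderate"],
          "p": [0, 1, 0]
        },
        {
          "config": ["moderate", "high", "moderate"],
          "p": [0.136, 0.409, 0.455]
        },
        {
          "config": ["high", "high", "moderate"],
          "p": [0, 0, 1]
        },
        {
          "config": ["low", "low", "high"],
          "p": [0.333, 0.333, 0.334]
        },
        {
          "config": ["moderate", "low", "high"],
          "p": [0.333, 0.333, 0.334]
        },
        {
          "config": ["high", "low", "high"],
          "p": [0.333, 0.333, 0.334]
        },
        {
          "config": ["low", "moderate", "high"],
          "p": [0.333, 0.333, 0.334]
        },
        {
          "config": ["moderate", "moderate", "high"],
          "p": [0.333, 0.333, 0.334]
        },
        {
          "config": ["high", "moderate", "high"],
          "p": [0.272727272727273, 0.454545454545455, 0.272727272727273]
        },
        {
          "config": ["low", "high", "high"],
          "p": [0.333, 0.333, 0.334]
        },
        {
          "config": ["moderate", "high", "high"],
          "p": [0, 0.833, 0.167]
        },
        {
          "config": ["high", "high", "high"],
          "p": [0.111, 0.889, 0]
        }
      ]
    }
  ]
}
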