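[
  {
    "name": "Diapausin",
    "n_cys": 6,
    "spacers": [
      [
        10,
        14
      ],
      [
        5,
        8
      ],
      [
        2,
        3
      ],
      [
        6,
        10
      ],
      [
        3,
        6
      ]
    ],
    "connectivity": [
      [
        1,
        4
      ],
      [
        2,
        5
      ],
      [
        3,
        6
      ]
    ]
  },
  {
    "name": "SaposinB",
    "n_cys": 6,
    "spacers": [
      [
        6,
        10
      ],
      [
        24,
        30
      ],
      [
        8,
        12
      ],
      [
        22,
        28
      ],
      [
        4,
        8
      ]
    ],
    "connectivity": [
      [
        1,
        6
      ],
      [
        2,
        5
      ],
      [
        3,
        4
      ]
    ]
  },
  {
    "name": "MND",
    "n_cys": 8,
    "spacers": [
      [
        5,
        9
      ],
      [
        3,
        6
      ],
      [
        3,
        5
      ],
      [
        9,
        12
      ],
      [
        4,
        6
      ],
      [
        2,
        3
      ],
      [
        4,
        7
      ]
    ],
    "connectivity": [
      [
        1,
        5
      ],
      [
        2,
        6
      ],
      [
        3,
        7
      ],
      [
        4,
        8
      ]
    ]
  },
  {
    "name": "TID",
    "n_cys": 6,
    "spacers": [
      [
        5,
        7
      ],
      [
        3,
        4
      ],
      [
        9,
        11
      ],
      [
        4,
        6
      ],
      [
        1,
        1
      ]
    ],
    "connectivity": [
      [
        1,
        4
      ],
      [
        2,
        5
      ],
      [
        3,
        6
      ]
    ]
  },
  {
    "name": "Macin",
    "n_cys": 10,
    "spacers": [
      [
        2,
        4
      ],
      [
        6,
        9
      ],
      [
        2,
        4
      ],
      [
        10,
        14
      ],
      [
        2,
        4
      ],
      [
        4,
        6
      ],
      [
        2,
        3
      ],
      [
        3,
        5
      ],
      [
        6,
        9
      ]
    ],
    "connectivity": [
      [
        1,
        5
      ],
      [
        2,
        6
      ],
      [
        3,
        7
      ],
      [
        4,
        9
      ],
      [
        8,
        10
      ]
    ]
  },
  {
    "name": "Drosomycin",
    "n_cys": 8,
    "spacers": [
      [
        4,
        6
      ],
      [
        12,
        15
      ],
      [
        5,
        7
      ],
      [
        6,
        8
      ],
      [
        8,
        10
      ],
      [
        1,
        1
      ],
      [
        2,
        4
      ]
    ],
    "connectivity": [
      [
        1,
        8
      ],
      [
        2,
        5
      ],
      [
        3,
        6
      ],
      [
        4,
        7
      ]
    ]
  },
  {
    "name": "MND_6Cys",
    "n_cys": 6,
    "spacers": [
      [
        2,
        4
      ],
      [
        10,
        13
      ],
      [
        2,
        4
      ],
      [
        14,
        18
      ],
      [
        2,
        4
      ]
    ],
    "connectivity": [
      [
        1,
        2
      ],
      [
        3,
        5
      ],
      [
        4,
        6
      ]
    ]
  }
]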