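{
  "rounds": [
    {
      "round": 1,
      "actions": [
        {
          "action": "delete",
          "id": "3.4.1",
          "note": "excluded after round 1"
        },
        {
          "action": "delete",
          "id": "3.4.2",
          "note": "excluded after round 1"
        },
        {
          "action": "delete",
          "id": "3.4.3",
          "note": "excluded after round 1"
        },
        {
          "action": "rename",
          "id": "1",
          "name": "Health literacy",
          "note": "revised from 'Health problem solving'"
        },
        {
          "action": "rename",
          "id": "3",
          "name": "Digital competency",
          "note": "merge: 'Emotion and communication' and 'Digital protection' combined"
        }
      ]
    },
    {
      "round": 2,
      "actions": [
        {
          "action": "delete",
          "id": "3.4",
          "note": "digital security deleted after round 2"
        },
        {
          "action": "rename",
          "id": "3.2.2",
          "name": "Digital ethics and identity",
          "note": "revised from 'Internet etiquette'"
        }
      ]
    }
  ]
}
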