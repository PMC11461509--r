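{
  "version": "1.0",
  "comment": "Declarative token-pattern rules for PK parameter mentions. Each pattern element matches one token, by exact form (`form`) or regular expression on the token text (`re`); `opt` elements may be skipped. Long forms match case-insensitively, acronym rules case-sensitively. `context` gates a rule on lexical neighbours within `window` tokens of the match.",
  "rules": [
    {
      "id": "clearance-long",
      "label": "PK",
      "case_sensitive": false,
      "pattern": [
        {"re": "^(total|apparent|oral|systemic)$", "opt": true},
        {"re": "^(body|oral|plasma)$", "opt": true},
        {"form": "clearance"}
      ]
    },
    {
      "id": "volume-of-distribution",
      "label": "PK",
      "case_sensitive": false,
      "pattern": [
        {"form": "apparent", "opt": true},
        {"form": "steady-state", "opt": true},
        {"form": "volume"},
        {"form": "of"},
        {"form": "distribution"}
      ]
    },
    {
      "id": "half-life-long",
      "label": "PK",
      "case_sensitive": false,
      "pattern": [
        {"re": "^(elimination|terminal|absorption|plasma)$", "opt": true},
        {"form": "half-life"}
      ]
    },
    {
      "id": "auc-long",
      "label": "PK",
      "case_sensitive": false,
      "pattern": [
        {"form": "area"},
        {"form": "under"},
        {"form": "the"},
        {"re": "^(concentration-time|plasma)$", "opt": true},
        {"form": "curve"}
      ]
    },
    {
      "id": "rate-constant-long",
      "label": "PK",
      "case_sensitive": false,
      "pattern": [
        {"re": "^(elimination|absorption)$"},
        {"form": "rate"},
        {"form": "constant"}
      ]
    },
    {
      "id": "bioavailability-long",
      "label": "PK",
      "case_sensitive": false,
      "pattern": [
        {"re": "^(absolute|oral)$", "opt": true},
        {"form": "bioavailability"}
      ]
    },
    {
      "id": "cl-acronyms",
      "label": "PK",
      "case_sensitive": true,
      "pattern": [{"re": "^(CL|CLr|CL/F)$"}]
    },
    {
      "id": "auc-acronyms",
      "label": "PK",
      "case_sensitive": true,
      "pattern": [{"re": "^AUC(0-([0-9]+|t|tau|inf|∞))?$"}]
    },
    {
      "id": "concentration-acronyms",
      "label": "PK",
      "case_sensitive": true,
      "pattern": [{"re": "^(Cmax|Tmax|Cmin|Ctrough)$"}]
    },
    {
      "id": "half-life-acronym",
      "label": "PK",
      "case_sensitive": true,
      "pattern": [{"form": "t1/2"}]
    },
    {
      "id": "volume-acronyms",
      "label": "PK",
      "case_sensitive": true,
      "pattern": [{"re": "^(Vd|Vss|Vz/F|Vc)$"}]
    },
    {
      "id": "k-acronyms",
      "label": "PK",
      "case_sensitive": true,
      "pattern": [{"re": "^(ke|ka|kel)$"}]
    },
    {
      "id": "mrt-acronym",
      "label": "PK",
      "case_sensitive": true,
      "pattern": [{"form": "MRT"}]
    },
    {
      "id": "f-bioavailability",
      "label": "PK",
      "case_sensitive": true,
      "pattern": [{"form": "F"}],
      "context": {
        "required": ["bioavailability", "oral", "dose", "dosing", "dosed", "%", "percent", "absolute"],
        "forbidden": ["statistic", "test", "ratio"],
        "window": 5
      }
    }
  ]
}
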