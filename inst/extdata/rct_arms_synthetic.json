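[
  {
    "trial": "SYNTH-NTZ (synthetic example)",
    "dmt": "natalizumab",
    "outcome": "relapse",
    "duration_months": 24,
    "published_event_free": 0.67,
    "filters": {"edss_max": 5.0, "age_min": 18, "age_max": 50,
                 "min_relapses_12m": 1}
  },
  {
    "trial": "SYNTH-FTY (synthetic example)",
    "dmt": "fingolimod",
    "outcome": "relapse",
    "duration_months": 12,
    "published_event_free": 0.75,
    "published_ci90": [0.71, 0.79],
    "filters": {"edss_max": 5.5, "min_relapses_12m": 1}
  },
  {
    "trial": "SYNTH-OCR (synthetic example)",
    "dmt": "ocrelizumab",
    "outcome": "cdp",
    "duration_months": 24,
    "published_event_free": 0.90,
    "filters": {"edss_min": 0, "edss_max": 5.5, "age_min": 18, "age_max": 55}
  }
]
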