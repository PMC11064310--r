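{
  "name": "MY-MINDD",
  "max_total": 11,
  "comment": "Band thresholds are expressed in servings/week after unit normalization (day x7, month /4.348). 'null' upper bound means +Inf. display_unit records the unit the band was originally stated in.",
  "components": [
    {
      "id": "whole_grains", "display_name": "Whole grains",
      "polarity": "healthy", "input_kind": "frequency", "display_unit": "per_day",
      "bands": [
        {"lower": 0,  "upper": 7,    "lower_closed": true, "upper_closed": false, "points": 0},
        {"lower": 7,  "upper": 21,   "lower_closed": true, "upper_closed": false, "points": 0.5},
        {"lower": 21, "upper": null, "lower_closed": true, "upper_closed": false, "points": 1}
      ]
    },
    {
      "id": "green_leafy", "display_name": "Green leafy vegetables",
      "polarity": "healthy", "input_kind": "frequency", "display_unit": "per_day",
      "bands": [
        {"lower": 0,   "upper": 3.5,  "lower_closed": true, "upper_closed": false, "points": 0},
        {"lower": 3.5, "upper": 7,    "lower_closed": true, "upper_closed": false, "points": 0.5},
        {"lower": 7,   "upper": null, "lower_closed": true, "upper_closed": false, "points": 1}
      ]
    },
    {
      "id": "other_vegetables", "display_name": "Other vegetables",
      "polarity": "healthy", "input_kind": "frequency", "display_unit": "per_day",
      "bands": [
        {"lower": 0,  "upper": 7,    "lower_closed": true, "upper_closed": false, "points": 0},
        {"lower": 7,  "upper": 21,   "lower_closed": true, "upper_closed": false, "points": 0.5},
        {"lower": 21, "upper": null, "lower_closed": true, "upper_closed": false, "points": 1}
      ]
    },
    {
      "id": "flavonoid_fruits", "display_name": "Flavonoid-rich fruits",
      "polarity": "healthy", "input_kind": "frequency", "display_unit": "per_week",
      "bands": [
        {"lower": 0, "upper": 1,    "lower_closed": true, "upper_closed": false, "points": 0},
        {"lower": 1, "upper": 2,    "lower_closed": true, "upper_closed": false, "points": 0.5},
        {"lower": 2, "upper": null, "lower_closed": true, "upper_closed": false, "points": 1}
      ]
    },
    {
      "id": "deep_sea_fish", "display_name": "Deep-sea fish (not fried)",
      "polarity": "healthy", "input_kind": "frequency", "display_unit": "per_week",
      "bands": [
        {"lower": 0,   "upper": 0.5,  "lower_closed": true, "upper_closed": false, "points": 0},
        {"lower": 0.5, "upper": 1,    "lower_closed": true, "upper_closed": false, "points": 0.5},
        {"lower": 1,   "upper": null, "lower_closed": true, "upper_closed": false, "points": 1}
      ]
    },
    {
      "id": "legumes_soy", "display_name": "Legumes and soy products",
      "polarity": "healthy", "input_kind": "frequency", "display_unit": "per_week",
      "bands": [
        {"lower": 0, "upper": 1,    "lower_closed": true, "upper_closed": false, "points": 0},
        {"lower": 1, "upper": 3,    "lower_closed": true, "upper_closed": false, "points": 0.5},
        {"lower": 3, "upper": null, "lower_closed": true, "upper_closed": false, "points": 1}
      ]
    },
    {
      "id": "poultry", "display_name": "Poultry (not fried)",
      "polarity": "healthy", "input_kind": "frequency", "display_unit": "per_week",
      "bands": [
        {"lower": 0, "upper": 1,    "lower_closed": true, "upper_closed": false, "points": 0},
        {"lower": 1, "upper": 2,    "lower_closed": true, "upper_closed": false, "points": 0.5},
        {"lower": 2, "upper": null, "lower_closed": true, "upper_closed": false, "points": 1}
      ]
    },
    {
      "id": "desserts_kuih", "display_name": "Desserts, sweetened kuih and beverages",
      "polarity": "unhealthy", "input_kind": "frequency", "display_unit": "per_week",
      "bands": [
        {"lower": 0, "upper": 5,    "lower_closed": true, "upper_closed": false, "points": 1},
        {"lower": 5, "upper": 7,    "lower_closed": true, "upper_closed": false, "points": 0.5},
        {"lower": 7, "upper": null, "lower_closed": true, "upper_closed": false, "points": 0}
      ]
    },
    {
      "id": "butter_margarine", "display_name": "Butter, margarine (Tbsp)",
      "polarity": "unhealthy", "input_kind": "frequency", "display_unit": "per_day",
      "bands": [
        {"lower": 0,  "upper": 7,    "lower_closed": true,  "upper_closed": false, "points": 1},
        {"lower": 7,  "upper": 14,   "lower_closed": true,  "upper_closed": true,  "points": 0.5},
        {"lower": 14, "upper": null, "lower_closed": false, "upper_closed": false, "points": 0}
      ]
    },
    {
      "id": "red_meat", "display_name": "Red meat and products",
      "polarity": "unhealthy", "input_kind": "frequency", "display_unit": "per_week",
      "bands": [
        {"lower": 0, "upper": 4,    "lower_closed": true, "upper_closed": false, "points": 1},
        {"lower": 4, "upper": 7,    "lower_closed": true, "upper_closed": false, "points": 0.5},
        {"lower": 7, "upper": null, "lower_closed": true, "upper_closed": false, "points": 0}
      ]
    },
    {
      "id": "fried_fast_foods", "display_name": "Fried/fast foods",
      "polarity": "unhealthy", "input_kind": "frequency", "display_unit": "per_week",
      "bands": [
        {"lower": 0, "upper": 1,    "lower_closed": true, "upper_closed": false, "points": 1},
        {"lower": 1, "upper": 4,    "lower_closed": true, "upper_closed": false, "points": 0.5},
        {"lower": 4, "upper": null, "lower_closed": true, "upper_closed": false, "points": 0}
      ]
    }
  ]
}
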