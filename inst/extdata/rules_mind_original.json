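{
  "name": "MIND-original",
  "max_total": 15,
  "comment": "Band thresholds in servings/week (day x7, month /4.348; 0.22999080036798528 = 1 serving/month). Wine is deliberately non-monotone: zero intake ('never') and > 1 glass/day both score 0; monotone=false exempts it from the polarity check.",
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
      "polarity": "healthy", "input_kind": "frequency", "display_unit": "per_week",
      "bands": [
        {"lower": 0, "upper": 2,    "lower_closed": true,  "upper_closed": true,  "points": 0},
        {"lower": 2, "upper": 6,    "lower_closed": false, "upper_closed": false, "points": 0.5},
        {"lower": 6, "upper": null, "lower_closed": true,  "upper_closed": false, "points": 1}
      ]
    },
    {
      "id": "other_vegetables", "display_name": "Other vegetables",
      "polarity": "healthy", "input_kind": "frequency", "display_unit": "per_week",
      "bands": [
        {"lower": 0, "upper": 5,    "lower_closed": true, "upper_closed": false, "points": 0},
        {"lower": 5, "upper": 7,    "lower_closed": true, "upper_closed": false, "points": 0.5},
        {"lower": 7, "upper": null, "lower_closed": true, "upper_closed": false, "points": 1}
      ]
    },
    {
      "id": "berries", "display_name": "Berries",
      "polarity": "healthy", "input_kind": "frequency", "display_unit": "per_week",
      "bands": [
        {"lower": 0, "upper": 1,    "lower_closed": true, "upper_closed": false, "points": 0},
        {"lower": 1, "upper": 2,    "lower_closed": true, "upper_closed": false, "points": 0.5},
        {"lower": 2, "upper": null, "lower_closed": true, "upper_closed": false, "points": 1}
      ]
    },
    {
      "id": "fish", "display_name": "Fish (not fried)",
      "polarity": "healthy", "input_kind": "frequency", "display_unit": "per_month",
      "bands": [
        {"lower": 0, "upper": 0.22999080036798528, "lower_closed": true, "upper_closed": false, "points": 0},
        {"lower": 0.22999080036798528, "upper": 1, "lower_closed": true, "upper_closed": false, "points": 0.5},
        {"lower": 1, "upper": null, "lower_closed": true, "upper_closed": false, "points": 1}
      ]
    },
    {
      "id": "beans", "display_name": "Beans",
      "polarity": "healthy", "input_kind": "frequency", "display_unit": "per_week",
      "bands": [
        {"lower": 0, "upper": 1,    "lower_closed": true,  "upper_closed": false, "points": 0},
        {"lower": 1, "upper": 3,    "lower_closed": true,  "upper_closed": true,  "points": 0.5},
        {"lower": 3, "upper": null, "lower_closed": false, "upper_closed": false, "points": 1}
      ]
    },
    {
      "id": "nuts", "display_name": "Nuts",
      "polarity": "healthy", "input_kind": "frequency", "display_unit": "per_month",
      "bands": [
        {"lower": 0, "upper": 0.22999080036798528, "lower_closed": true, "upper_closed": false, "points": 0},
        {"lower": 0.22999080036798528, "upper": 5, "lower_closed": true, "upper_closed": false, "points": 0.5},
        {"lower": 5, "upper": null, "lower_closed": true, "upper_closed": false, "points": 1}
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
      "id": "olive_oil", "display_name": "Olive oil",
      "polarity": "healthy", "input_kind": "categorical",
      "categories": {"primary": 1, "not_primary": 0}
    },
    {
      "id": "wine", "display_name": "Wine",
      "polarity": "healthy", "input_kind": "frequency", "display_unit": "per_day",
      "monotone": false,
      "bands": [
        {"lower": 0, "upper": 0,    "lower_closed": true,  "upper_closed": true,  "points": 0},
        {"lower": 0, "upper": 6,    "lower_closed": false, "upper_closed": true,  "points": 0.5},
        {"lower": 6, "upper": 7,    "lower_closed": false, "upper_closed": true,  "points": 1},
        {"lower": 7, "upper": null, "lower_closed": false, "upper_closed": false, "points": 0}
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
      "id": "butter_margarine", "display_name": "Butter, stick margarine",
      "polarity": "unhealthy", "input_kind": "frequency", "display_unit": "per_day",
      "bands": [
        {"lower": 0,  "upper": 7,    "lower_closed": true,  "upper_closed": false, "points": 1},
        {"lower": 7,  "upper": 14,   "lower_closed": true,  "upper_closed": true,  "points": 0.5},
        {"lower": 14, "upper": null, "lower_closed": false, "upper_closed": false, "points": 0}
      ]
    },
    {
      "id": "cheese", "display_name": "Cheese",
      "polarity": "unhealthy", "input_kind": "frequency", "display_unit": "per_week",
      "bands": [
        {"lower": 0, "upper": 1,    "lower_closed": true, "upper_closed": false, "points": 1},
        {"lower": 1, "upper": 7,    "lower_closed": true, "upper_closed": false, "points": 0.5},
        {"lower": 7, "upper": null, "lower_closed": true, "upper_closed": false, "points": 0}
      ]
    },
    {
      "id": "pastries_sweets", "display_name": "Pastries and sweets",
      "polarity": "unhealthy", "input_kind": "frequency", "display_unit": "per_week",
      "bands": [
        {"lower": 0, "upper": 5,    "lower_closed": true, "upper_closed": false, "points": 1},
        {"lower": 5, "upper": 7,    "lower_closed": true, "upper_closed": false, "points": 0.5},
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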