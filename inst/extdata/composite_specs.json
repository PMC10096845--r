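{
  "usda_meat": {
    "name": "usda_meat",
    "display_name": "USDA meat",
    "categories": [
      {
        "category_name": "usda_meat_composite",
        "proportion": 1.0,
        "foods": [
          {"food_id": "usda_beef", "label": "Beef", "proportion": 0.2371},
          {"food_id": "usda_beef_ground", "label": "Beef, ground", "proportion": 0.2712},
          {"food_id": "usda_pork_fresh", "label": "Pork, fresh", "proportion": 0.1276},
          {"food_id": "usda_pork_cured", "label": "Pork, cured", "proportion": 0.0635},
          {"food_id": "usda_sausage", "label": "Sausage", "proportion": 0.0662},
          {"food_id": "usda_lunch_beef", "label": "Luncheon meats and bacon, beef", "proportion": 0.0875},
          {"food_id": "usda_lunch_pork", "label": "Luncheon meats and bacon, pork", "proportion": 0.1234},
          {"food_id": "usda_other", "label": "Others (game meat, lamb and liver)", "proportion": 0.0235}
        ]
      }
    ]
  },
  "min_meat": {
    "name": "min_meat",
    "display_name": "Minimally processed meat",
    "categories": [
      {
        "category_name": "beef",
        "proportion": 0.6930,
        "foods": [
          {"food_id": "21101130", "label": "Beef steak, broiled or baked, lean only eaten", "proportion": 0.8385},
          {"food_id": "21102130", "label": "Beef steak, fried, lean only eaten", "proportion": 0.1615}
        ]
      },
      {
        "category_name": "pork",
        "proportion": 0.3070,
        "foods": [
          {"food_id": "22101120", "label": "Pork chop, broiled or baked, lean only eaten", "proportion": 1.0}
        ]
      }
    ]
  },
  "min_poultry": {
    "name": "min_poultry",
    "display_name": "Minimally processed poultry",
    "categories": [
      {
        "category_name": "chicken",
        "proportion": 0.8773,
        "foods": [
          {"food_id": "24123301", "label": "Chicken breast, grilled without sauce, skin not eaten", "proportion": 0.5325},
          {"food_id": "24122131", "label": "Chicken breast, baked, broiled, or roasted, skin not eaten, from raw", "proportion": 0.3906},
          {"food_id": "24144301", "label": "Chicken drumstick, sauteed, skin not eaten", "proportion": 0.0769}
        ]
      },
      {
        "category_name": "turkey",
        "proportion": 0.1227,
        "foods": [
          {"food_id": "24201120", "label": "Turkey, light meat, roasted, skin not eaten", "proportion": 1.0}
        ]
      }
    ]
  },
  "fp_meat": {
    "name": "fp_meat",
    "display_name": "Further processed meat",
    "categories": [
      {
        "category_name": "beef",
        "proportion": 0.1327,
        "foods": [
          {"food_id": "21104110", "label": "Beef steak, battered, fried, NS as to fat eaten", "proportion": 0.2090},
          {"food_id": "fdc_173113", "label": "Ground beef patty, cooked (synthetic id for FDC 173113)", "proportion": 0.7910}
        ]
      },
      {
        "category_name": "pork",
        "proportion": 0.0509,
        "foods": [
          {"food_id": "22101150", "label": "Pork chop, breaded or floured, broiled or baked, lean only eaten", "proportion": 0.7505},
          {"food_id": "22701050", "label": "Pork, spareribs, barbecued, with sauce, lean only eaten", "proportion": 0.2495}
        ]
      },
      {
        "category_name": "cold_cuts_bacon_franks_sausages",
        "proportion": 0.8164,
        "foods": [
          {"food_id": "25230220", "label": "Ham, prepackaged or deli, luncheon meat, reduced sodium", "proportion": 0.4629},
          {"food_id": "22600210", "label": "Pork bacon, NS as to fresh, smoked or cured, reduced sodium, cooked", "proportion": 0.1805},
          {"food_id": "25210620", "label": "Frankfurter or hot dog, beef, reduced fat or light", "proportion": 0.2727},
          {"food_id": "25221408", "label": "Pork sausage, reduced sodium", "proportion": 0.0839}
        ]
      }
    ]
  },
  "fp_poultry": {
    "name": "fp_poultry",
    "display_name": "Further processed poultry",
    "categories": [
      {
        "category_name": "chicken_turkey",
        "proportion": 0.8249,
        "foods": [
          {"food_id": "24123311", "label": "Chicken breast, grilled with sauce, skin not eaten", "proportion": 0.3454},
          {"food_id": "24122171", "label": "Chicken breast, rotisserie, skin not eaten", "proportion": 0.1527},
          {"food_id": "24198731", "label": "Chicken nuggets, from fast food", "proportion": 0.5018}
        ]
      },
      {
        "category_name": "cold_cuts_bacon_franks_sausages",
        "proportion": 0.1751,
        "foods": [
          {"food_id": "25230785", "label": "Turkey, prepackaged or deli, luncheon meat, reduced sodium", "proportion": 0.8011},
          {"food_id": "24208510", "label": "Turkey bacon, reduced sodium, cooked", "proportion": 0.0830},
          {"food_id": "25210310", "label": "Frankfurter or hot dog, chicken", "proportion": 0.0494},
          {"food_id": "25221855", "label": "Turkey or chicken sausage, reduced sodium", "proportion": 0.0665}
        ]
      }
    ]
  }
}
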