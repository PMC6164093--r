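# Cro-VIDEO-FFQ instrument key: 22 question-level items in 7 product groups.
# Vitamin D content is stored per serving (micrograms), as the instrument's
# calculation key defines it, not per 100 g.
#
# Item partition: the three fresh/smoked-fish questions each list several
# candidate products sharing one serving line; they are encoded as single
# choose-from-list items (the respondent names 1-2 most-consumed products and
# the key resolves to their mean content). The "other fish" and "fortified
# dairy" questions are free-text items whose content is supplied per
# respondent at scoring time.
name: cro_video_ffq
groups:
  - group_id: fish_fresh
    label: Fresh and smoked fish
  - group_id: fish_products
    label: Fish products
  - group_id: dairy
    label: Dairy products
  - group_id: eggs
    label: Eggs
  - group_id: meat
    label: Meat and meat products
  - group_id: cereals
    label: Cereals
  - group_id: fats
    label: Fats
items:
  - item_id: fish_high_vitd
    group_id: fish_fresh
    description: Salmon, rainbow trout, herring, eel
    serving_grams: 50
    household_measure: deck of cards
    period: MONTHLY
    selection_mode: CHOOSE_FROM_LIST
    candidates:
      - {product_id: salmon, name: Salmon, content_per_serving_ug: 7.50}
      - {product_id: rainbow_trout, name: Rainbow trout, content_per_serving_ug: 7.80}
      - {product_id: herring, name: Herring, content_per_serving_ug: 9.50}
      - {product_id: eel, name: Eel, content_per_serving_ug: 15.00}
  - item_id: fish_mid_vitd
    group_id: fish_fresh
    description: Halibut, mackerel, brook trout, sole, tuna
    serving_grams: 50
    household_measure: deck of cards
    period: MONTHLY
    selection_mode: CHOOSE_FROM_LIST
    candidates:
      - {product_id: halibut, name: Halibut, content_per_serving_ug: 2.50}
      - {product_id: mackerel, name: Mackerel, content_per_serving_ug: 2.50}
      - {product_id: brook_trout, name: Brook trout, content_per_serving_ug: 1.05}
      - {product_id: sole, name: Sole, content_per_serving_ug: 4.00}
      - {product_id: tuna, name: Tuna, content_per_serving_ug: 3.60}
  - item_id: fish_low_vitd
    group_id: fish_fresh
    description: Cod, flounder, plaice, pollock, hake, bass, zander, pike
    serving_grams: 50
    household_measure: deck of cards
    period: MONTHLY
    selection_mode: CHOOSE_FROM_LIST
    candidates:
      - {product_id: cod, name: Cod, content_per_serving_ug: 0.50}
      - {product_id: flounder, name: Flounder, content_per_serving_ug: 0.40}
      - {product_id: plaice, name: Plaice, content_per_serving_ug: 0.40}
      - {product_id: pollock, name: Pollock, content_per_serving_ug: 0.50}
      - {product_id: hake, name: Hake, content_per_serving_ug: 0.50}
      - {product_id: bass, name: Bass, content_per_serving_ug: 0.40}
      - {product_id: zander, name: Zander, content_per_serving_ug: 0.35}
      - {product_id: pike, name: Pike, content_per_serving_ug: 0.45}
  - item_id: fish_other
    group_id: fish_fresh
    description: Other fish (to be specified)
    serving_grams: 50
    household_measure: deck of cards
    period: MONTHLY
    selection_mode: FREE_TEXT
  - item_id: fish_prod_herring_sardine_tuna
    group_id: fish_products
    description: Herrings, sardines, and tuna products
    serving_grams: 100
    household_measure: e.g., 2 rollmops, small can of tuna, 2/3 of can of herrings
    period: MONTHLY
    selection_mode: FIXED
    content_per_serving_ug: 12.36
  - item_id: fish_prod_other
    group_id: fish_products
    description: Other fish products
    serving_grams: 100
    household_measure: e.g., 1/3 of can of fish stew
    period: MONTHLY
    selection_mode: FIXED
    content_per_serving_ug: 0.93
  - item_id: milk_beverages
    group_id: dairy
    description: Milk and milk beverages (yoghurt, kefir, buttermilk, cream)
    serving_grams: 250
    household_measure: 1 glass
    period: WEEKLY
    selection_mode: FIXED
    content_per_serving_ug: 0.28
  - item_id: fortified_dairy
    group_id: dairy
    description: Vitamin D fortified products (to be specified)
    serving_grams: 250
    household_measure: 1 glass
    period: WEEKLY
    selection_mode: FREE_TEXT
  - item_id: rennet_blue_soft_cheese
    group_id: dairy
    description: Rennet, blue and soft penicillium cheese
    serving_grams: 20
    household_measure: 1 slice
    period: WEEKLY
    selection_mode: FIXED
    content_per_serving_ug: 0.09
  - item_id: feta_cheese
    group_id: dairy
    description: Feta cheese
    serving_grams: 15
    household_measure: 1 slice
    period: WEEKLY
    selection_mode: FIXED
    content_per_serving_ug: 0.08
  - item_id: cottage_cheese
    group_id: dairy
    description: Cottage cheese
    serving_grams: 50
    household_measure: 1 thick slice, 2 tablespoons
    period: WEEKLY
    selection_mode: FIXED
    content_per_serving_ug: 0.08
  - item_id: processed_cheese
    group_id: dairy
    description: Processed cheese
    serving_grams: 25
    household_measure: 1 slice, 1 spoon, 1 triangle serving
    period: WEEKLY
    selection_mode: FIXED
    content_per_serving_ug: 0.07
  - item_id: homogenized_cheese
    group_id: dairy
    description: Homogenized cheese
    serving_grams: 150
    household_measure: 1 package
    period: WEEKLY
    selection_mode: FIXED
    content_per_serving_ug: 0.23
  - item_id: dairy_ice_cream
    group_id: dairy
    description: Dairy ice cream
    serving_grams: 40
    household_measure: 1 scoop
    period: MONTHLY
    selection_mode: FIXED
    content_per_serving_ug: 0.30
  - item_id: egg
    group_id: eggs
    description: Egg
    serving_grams: 50
    household_measure: 1 medium egg
    period: WEEKLY
    selection_mode: FIXED
    content_per_serving_ug: 0.85
  - item_id: egg_yolk
    group_id: eggs
    description: Egg yolk
    serving_grams: 20
    household_measure: 1 yolk
    period: WEEKLY
    selection_mode: FIXED
    content_per_serving_ug: 0.90
  - item_id: meat
    group_id: meat
    description: Meat
    serving_grams: 100
    household_measure: palm of small hand
    period: WEEKLY
    selection_mode: FIXED
    content_per_serving_ug: 0.75
  - item_id: meat_products
    group_id: meat
    description: Meat products
    serving_grams: 15
    household_measure: thin slice of ham, 3 slices of sausage
    period: WEEKLY
    selection_mode: FIXED
    content_per_serving_ug: 0.09
  - item_id: white_bread
    group_id: cereals
    description: White wheat and confectionery bread
    serving_grams: 35
    household_measure: 1 slice, small roll
    period: WEEKLY
    selection_mode: FIXED
    content_per_serving_ug: 0.06
  - item_id: egg_pasta
    group_id: cereals
    description: Cooked egg pasta
    serving_grams: 100
    household_measure: 1 glass of cooked
    period: WEEKLY
    selection_mode: FIXED
    content_per_serving_ug: 0.25
  - item_id: butter_pork_fat
    group_id: fats
    description: Butter, butter products, pork fat
    serving_grams: 5
    household_measure: 1 teaspoon
    period: DAILY
    selection_mode: FIXED
    content_per_serving_ug: 0.03
  - item_id: fortified_margarine
    group_id: fats
    description: Fortified margarine
    serving_grams: 5
    household_measure: 1 teaspoon
    period: DAILY
    selection_mode: FIXED
    content_per_serving_ug: 0.31
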