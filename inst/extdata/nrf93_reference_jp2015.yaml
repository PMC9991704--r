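# NRF9.3 reference daily values per sex and age band, transcribed from the
# Dietary Reference Intakes for Japanese, 2015 edition (RDA where available,
# otherwise AI or tentative dietary goal), plus the Estimated Energy
# Requirement (EER) for a moderate physical activity level.
# Disqualifying-nutrient limits: added sugars as 5 % of EER energy (WHO
# conditional recommendation, 4 kcal/g), saturated fats as 7 % of EER energy
# (9 kcal/g), and sodium from the salt-equivalent goal (<8 g men, <7 g women).
added_sugar_pct_energy: 5
sfa_pct_energy: 7
bands:
  - sex: male
    age_min: 18
    age_max: 29
    protein_g: 60
    fibre_g: 20
    vit_a_ug_rae: 850
    vit_c_mg: 100
    vit_d_ug: 5.5
    calcium_mg: 800
    iron_mg: 7.0
    potassium_mg: 3000
    magnesium_mg: 340
    sodium_mg: 3150
    eer_kcal: 2650
  - sex: male
    age_min: 30
    age_max: 49
    protein_g: 60
    fibre_g: 20
    vit_a_ug_rae: 900
    vit_c_mg: 100
    vit_d_ug: 5.5
    calcium_mg: 650
    iron_mg: 7.5
    potassium_mg: 3000
    magnesium_mg: 370
    sodium_mg: 3150
    eer_kcal: 2650
  - sex: male
    age_min: 50
    age_max: 69
    protein_g: 60
    fibre_g: 20
    vit_a_ug_rae: 850
    vit_c_mg: 100
    vit_d_ug: 5.5
    calcium_mg: 700
    iron_mg: 7.5
    potassium_mg: 3000
    magnesium_mg: 350
    sodium_mg: 3150
    eer_kcal: 2450
  - sex: male
    age_min: 70
    age_max: 120
    protein_g: 60
    fibre_g: 19
    vit_a_ug_rae: 800
    vit_c_mg: 100
    vit_d_ug: 5.5
    calcium_mg: 700
    iron_mg: 7.0
    potassium_mg: 3000
    magnesium_mg: 320
    sodium_mg: 3150
    eer_kcal: 2200
  - sex: female
    age_min: 18
    age_max: 29
    protein_g: 50
    fibre_g: 18
    vit_a_ug_rae: 650
    vit_c_mg: 100
    vit_d_ug: 5.5
    calcium_mg: 650
    iron_mg: 10.5
    potassium_mg: 2600
    magnesium_mg: 270
    sodium_mg: 2750
    eer_kcal: 1950
  - sex: female
    age_min: 30
    age_max: 49
    protein_g: 50
    fibre_g: 18
    vit_a_ug_rae: 700
    vit_c_mg: 100
    vit_d_ug: 5.5
    calcium_mg: 650
    iron_mg: 10.5
    potassium_mg: 2600
    magnesium_mg: 290
    sodium_mg: 2750
    eer_kcal: 2000
  - sex: female
    age_min: 50
    age_max: 69
    protein_g: 50
    fibre_g: 18
    vit_a_ug_rae: 700
    vit_c_mg: 100
    vit_d_ug: 5.5
    calcium_mg: 650
    iron_mg: 6.5
    potassium_mg: 2600
    magnesium_mg: 290
    sodium_mg: 2750
    eer_kcal: 1900
  - sex: female
    age_min: 70
    age_max: 120
    protein_g: 50
    fibre_g: 17
    vit_a_ug_rae: 650
    vit_c_mg: 100
    vit_d_ug: 5.5
    calcium_mg: 650
    iron_mg: 6.0
    potassium_mg: 2600
    magnesium_mg: 270
    sodium_mg: 2750
    eer_kcal: 1750
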