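# HEI-2015 component scoring standards.
# basis: density      -> amount per 1000 kcal (column `source` of the intake)
#        percent_energy -> % of energy (added sugars x4 kcal/g, SFA x9 kcal/g)
#        ratio        -> (MUFA + PUFA) / SFA, unadjusted
# Adequacy components score max_points at/above max_threshold, 0 at/below
# zero_threshold; moderation components score max_points at/below
# max_threshold, 0 at/above zero_threshold; linear in between.
components:
  - name: total_fruits
    direction: adequacy
    basis: density
    source: heq_total_fruit_cup
    unit: cup-eq/1000 kcal
    max_points: 5
    max_threshold: 0.8
    zero_threshold: 0.0
  - name: whole_fruits
    direction: adequacy
    basis: density
    source: heq_whole_fruit_cup
    unit: cup-eq/1000 kcal
    max_points: 5
    max_threshold: 0.4
    zero_threshold: 0.0
  - name: total_vegetables
    direction: adequacy
    basis: density
    source: heq_total_veg_cup
    unit: cup-eq/1000 kcal
    max_points: 5
    max_threshold: 1.1
    zero_threshold: 0.0
  - name: greens_and_beans
    direction: adequacy
    basis: density
    source: heq_greens_beans_cup
    unit: cup-eq/1000 kcal
    max_points: 5
    max_threshold: 0.2
    zero_threshold: 0.0
  - name: whole_grains
    direction: adequacy
    basis: density
    source: heq_whole_grains_oz
    unit: oz-eq/1000 kcal
    max_points: 10
    max_threshold: 1.5
    zero_threshold: 0.0
  - name: dairy
    direction: adequacy
    basis: density
    source: heq_dairy_cup
    unit: cup-eq/1000 kcal
    max_points: 10
    max_threshold: 1.3
    zero_threshold: 0.0
  - name: total_protein_foods
    direction: adequacy
    basis: density
    source: heq_total_protein_oz
    unit: oz-eq/1000 kcal
    max_points: 5
    max_threshold: 2.5
    zero_threshold: 0.0
  - name: seafood_plant_proteins
    direction: adequacy
    basis: density
    source: heq_seafood_plant_oz
    unit: oz-eq/1000 kcal
    max_points: 5
    max_threshold: 0.8
    zero_threshold: 0.0
  - name: fatty_acids
    direction: adequacy
    basis: ratio
    source: fatty_acid_ratio
    unit: (MUFA+PUFA)/SFA
    max_points: 10
    max_threshold: 2.5
    zero_threshold: 1.2
  - name: refined_grains
    direction: moderation
    basis: density
    source: heq_refined_grains_oz
    unit: oz-eq/1000 kcal
    max_points: 10
    max_threshold: 1.8
    zero_threshold: 4.3
  - name: sodium
    direction: moderation
    basis: density
    source: sodium_g
    unit: g/1000 kcal
    max_points: 10
    max_threshold: 1.1
    zero_threshold: 2.0
  - name: added_sugars
    direction: moderation
    basis: percent_energy
    source: added_sugar_g
    unit: "% of energy"
    max_points: 10
    max_threshold: 6.5
    zero_threshold: 26.0
  - name: saturated_fats
    direction: moderation
    basis: percent_energy
    source: sfa_g
    unit: "% of energy"
    max_points: 10
    max_threshold: 8.0
    zero_threshold: 16.0
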