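dimension,level,anchor
nutrition_hydration,1,Eats and drinks independently
nutrition_hydration,2,Needs help with eating or drinking
nutrition_hydration,3,Is fed by staff
nutrition_hydration,4,Total parenteral nutrition
elimination,1,Independent
elimination,2,Bladder or condom catheter
elimination,3,Occasional urinary or fecal incontinence
elimination,4,Permanent urinary and fecal incontinence
hygiene_comfort,1,Independent
hygiene_comfort,2,Intimate hygiene in bed; otherwise independent in bathroom use
hygiene_comfort,3,Hygiene in bed with the patient's help
hygiene_comfort,4,Hygiene in bed without the patient's help
mobilization,1,Independent
mobilization,2,Walks with help
mobilization,3,Mobilized to armchair
mobilization,4,Bedridden
diagnostic_procedures,1,Monitoring once a day
diagnostic_procedures,2,Vital-sign monitoring once per shift
diagnostic_procedures,3,Vital-sign monitoring more than once per shift
diagnostic_procedures,4,Continuous vital-sign monitoring
therapeutic_procedures,1,Oral therapy only or none
therapeutic_procedures,2,Oral or intramuscular or intravenous therapy
therapeutic_procedures,3,Central venous catheter with intermittent infusion
therapeutic_procedures,4,Central venous catheter with continuous 24-h infusion
sensory_perception,1,Alert and oriented; no sedatives
sensory_perception,2,Occasional temporal-spatial disorientation; day and night sedatives
sensory_perception,3,Constant temporal-spatial disorientation; sedatives day and night
sensory_perception,4,Sleepy state or coma or severe agitation (delirium)
skin_integrity,1,Low pressure-ulcer risk (Braden > 16); no ulcers
skin_integrity,2,At risk (Braden <= 16); not bedridden; mobilization program
skin_integrity,3,Bedridden with mobilization program and/or ulcers up to grade 2
skin_integrity,4,Bedridden with mobilization program and/or ulcers above grade 2
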