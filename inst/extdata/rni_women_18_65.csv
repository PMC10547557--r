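nutrient,intake,unit
calcium,1000,mg
iron,29.4,mg
zinc,4.9,mg
selenium,26,ug
vitamin_a,500,ug
omega3,1.1,g
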