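nutrient,sex,age_lo,age_hi,ear,tul
vitamin_a,female,15,49,390,3000
vitamin_c,female,15,49,55,2000
thiamin,female,15,49,1.4,
riboflavin,female,15,49,2,
niacin,female,15,49,12,35
vitamin_b6,female,15,49,1.6,100
folate,female,15,49,180,1000
vitamin_b12,female,15,49,2,
calcium,female,15,49,800,2000
iron,female,15,49,15,45
zinc,female,15,49,11,40
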