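analyte,units,normal_low,normal_high,category
creatinine,mg/dL,0.5,1.5,blood
BUN,mg/dL,7,27,blood
phosphorus,mg/dL,2.5,6,blood
calcium,mg/dL,9,11.5,blood
albumin,g/dL,2.5,3.8,blood
total_protein,g/dL,5.4,7.5,blood
globulin,g/dL,2.4,4,blood
ALT,U/L,10,100,blood
ALP,U/L,20,150,blood
AST,U/L,15,55,blood
GGT,U/L,0,10,blood
total_bilirubin,mg/dL,0.1,0.4,blood
cholesterol,mg/dL,130,300,blood
triglycerides,mg/dL,20,150,blood
glucose,mg/dL,70,120,blood
sodium,mmol/L,140,155,blood
potassium,mmol/L,3.6,5.6,blood
chloride,mmol/L,105,120,blood
bicarbonate,mmol/L,18,26,blood
amylase,U/L,400,1200,blood
lipase,U/L,100,750,blood
hematocrit,%,37,55,blood
hemoglobin,g/dL,12,19,blood
rbc,10^6/uL,5.5,8.5,blood
wbc,10^3/uL,6,17,blood
neutrophils,10^3/uL,3,11.5,blood
lymphocytes,10^3/uL,1,4.8,blood
monocytes,10^3/uL,0.15,1.35,blood
eosinophils,10^3/uL,0.1,1.25,blood
platelets,10^3/uL,200,500,blood
USG,,1.015,1.045,urine
urine_protein,mg/dL,0,30,urine
urine_ph,,5.5,7.5,urine
urine_glucose,mg/dL,0,15,urine
urine_ketones,mg/dL,0,5,urine
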