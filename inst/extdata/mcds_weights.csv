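condition,coefficient,weight
cancer,1.039,10
chronic_renal_disease,0.689,7
psychosis,0.677,7
haemorrhagic_diathesis,0.446,4
depression_anxiety_ocd,0.440,4
epilepsy,0.422,4
anaemias,0.422,4
parkinson,0.325,3
diabetes,0.293,3
hyperuricemia_gout,0.286,3
irritable_colon,0.282,3
transplantation,0.256,3
dementia,0.244,2
cardio_cerebrovascular,0.177,2
acid_disorders_peptic_ulcer,0.139,1
respiratory_illness,0.108,1
exocrine_pancreas_failure,0.087,1
liver_disease,0.082,1
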