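condition,atc_pattern,min_rx_per_year,exception_codes,flag
cardio_cerebrovascular,C01,2,,
cardio_cerebrovascular,C02,2,,
cardio_cerebrovascular,C03,2,,
cardio_cerebrovascular,C07,2,,
cardio_cerebrovascular,C08,2,,
cardio_cerebrovascular,C09,2,,
respiratory_illness,R03,2,,
exocrine_pancreas_failure,A09AA02,1,,
cystic_fibrosis,R05CB13,1,,
tuberculosis,J04A,1,,
cancer,L01,1,,
cancer,L02,1,,
cancer,R05,1,R05CB13,wrong
acid_disorders_peptic_ulcer,A02B,3,,nonspecific
irritable_colon,A03AA,3,,nonspecific
liver_disease,A05A,2,,
chronic_hepatitis,J05AP,1,,
diabetes,A10,2,,
glaucoma,S01E,2,,
chronic_renal_disease,V03AE,2,,
chronic_renal_disease,B03XA,2,,
anaemias,B03A,2,,nonspecific
anaemias,B03B,2,,
bone_diseases,M05B,2,,
ibd_rheumatologic,A07EC,2,,
ibd_rheumatologic,L04AB,2,,
pain_inflammation,M01A,3,,nonspecific
pain_inflammation,N02A,3,,nonspecific
hyperuricemia_gout,M04A,2,,
dermatological_severe,D05,2,,
transplantation,L04AD,1,,
hyperlipidaemia,C10,2,,
hiv,J05AR,1,,
hypothyroidism,H03A,2,,
epilepsy,N03A,2,,
epilepsy,N05CD08,2,,
dementia,N06D,2,,
parkinson,N04,2,,
depression_anxiety_ocd,N06A,2,,
depression_anxiety_ocd,N05BA,2,,
depression_anxiety_ocd,N05CD,2,N05CD08,
bipolar_disorders,N05AN01,1,,
psychosis,N05A,2,N05AN01,
multiple_sclerosis,L03AB07,1,,
multiple_sclerosis,L03AB08,1,,
multiple_sclerosis,L04AA27,1,,
haemorrhagic_diathesis,B02B,1,,
allergic_disorders,R06A,3,,nonspecific
addictive_disorders,N07BB,1,,
addictive_disorders,N07BC,1,,
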