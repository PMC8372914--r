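name,value,units,description
total_societal_cost_condom,380023259,INR,Published total societal cost for the condom-UBT strategy
total_societal_cost_esm,375629967,INR,Published total societal cost for the ESM-UBT strategy
total_societal_cost_bakri,993068492,INR,Published total societal cost for the Bakri-UBT strategy
total_health_system_cost_condom,192277700,INR,Published total health-system cost for the condom-UBT strategy
total_health_system_cost_esm,187880533,INR,Published total health-system cost for the ESM-UBT strategy
total_health_system_cost_bakri,805236204,INR,Published total health-system cost for the Bakri-UBT strategy
per_patient_societal_cost_condom,6338,INR,Published per-patient societal cost for condom-UBT
per_patient_societal_cost_esm,6264,INR,Published per-patient societal cost for ESM-UBT
per_patient_societal_cost_bakri,16561,INR,Published per-patient societal cost for Bakri-UBT
delta_cost_societal_esm,-73,INR,Published incremental per-patient societal cost ESM-UBT vs condom-UBT
delta_cost_societal_bakri,10224,INR,Published incremental per-patient societal cost Bakri-UBT vs condom-UBT
delta_cost_health_system_esm,-73,INR,Published incremental per-patient health-system cost ESM-UBT vs condom-UBT
delta_cost_health_system_bakri,10222,INR,Published incremental per-patient health-system cost Bakri-UBT vs condom-UBT
dalys_averted_esm,0.030,DALY,Published per-patient DALYs averted ESM-UBT vs condom-UBT
dalys_averted_bakri,-0.081,DALY,Published per-patient DALYs averted Bakri-UBT vs condom-UBT
icer_esm,-2412,INR/DALY,Published ICER ESM-UBT vs condom-UBT (societal)
icer_bakri,-126219,INR/DALY,Published ICER Bakri-UBT vs condom-UBT (societal)
nmb_esm,809,INR,Published incremental NMB per patient ESM-UBT vs condom-UBT
nmb_bakri,-12185,INR,Published incremental NMB per patient Bakri-UBT vs condom-UBT
surgeries_condom,4615,patients,Published total surgeries in the annual cohort with condom-UBT
surgeries_esm,2817,patients,Published total surgeries in the annual cohort with ESM-UBT
surgeries_bakri,9411,patients,Published total surgeries in the annual cohort with Bakri-UBT
icu_admissions_condom,4932,admissions,Published total ICU admissions with condom-UBT
icu_admissions_esm,3594,admissions,Published total ICU admissions with ESM-UBT
icu_admissions_bakri,8500,admissions,Published total ICU admissions with Bakri-UBT
p_ce_esm_base_wtp,0.635,probability,Published probability ESM-UBT cost-effective at base WTP (10000-draw PSA)
p_ce_bakri_base_wtp,0.001,probability,Published probability Bakri-UBT cost-effective at base WTP (10000-draw PSA)
evpi_population_esm,14323056,INR,Published population EVPI for ESM-UBT vs condom-UBT (annual cohort)
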