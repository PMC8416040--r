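subject_id,age,sex,education,marital,income,family_history_htn,antihypertensive_med,baseline_sbp,baseline_dbp,followup_sbp,followup_dbp,hypertension,ff_whole_grains,ff_fish,ff_eggs,ff_dairy,ff_vegetables,ff_fruits,ff_bean_products,ff_nuts,ff_red_meat,bmi,smoking,years_since_quit,ipaq_level,drinks_per_year,rs11191548,rs1275988,rs16849225,rs7136259,rs17249754,rs2107595,rs9810888,rs10745332,rs1378942,rs16998073,rs1902859,rs2021783,rs7577262
S000001,55,male,senior_or_above,married_cohabit,lt1000,TRUE,FALSE,134.1,64.7,127.8,68.3,FALSE,never,never,monthly,annually,monthly,monthly,monthly,monthly,weekly,27,current,NA,moderate,11,het,hom,het,ref,het,ref,hom,ref,het,ref,het,het,ref
S000002,36.6,female,junior,married_cohabit,lt1000,TRUE,FALSE,109.7,76,122.5,72.6,FALSE,daily,annually,annually,annually,monthly,monthly,monthly,weekly,never,29.5,never,NA,low,0,ref,ref,het,ref,ref,ref,ref,ref,het,ref,ref,het,het
S000003,50.6,female,junior,married_cohabit,ge3000,FALSE,FALSE,114.5,60.6,118.3,49.2,FALSE,weekly,annually,annually,never,monthly,never,monthly,monthly,annually,24.9,never,NA,high,193,ref,hom,het,ref,ref,het,het,het,ref,ref,het,ref,ref
S000004,48.1,female,primary_or_below,married_cohabit,lt1000,FALSE,FALSE,113.3,84,127.3,70.2,FALSE,daily,annually,annually,monthly,weekly,daily,monthly,weekly,weekly,18.5,current,NA,low,0,ref,het,het,het,hom,ref,het,ref,het,ref,ref,het,ref
S000005,41.4,female,primary_or_below,married_cohabit,lt1000,FALSE,FALSE,133.2,57.2,137.6,64,FALSE,annually,weekly,daily,never,monthly,monthly,monthly,never,weekly,30.6,current,NA,moderate,235,hom,het,ref,ref,het,ref,het,ref,ref,het,hom,ref,ref
S000006,20.1,male,primary_or_below,married_cohabit,lt1000,TRUE,FALSE,131.1,83.2,130.4,75.9,FALSE,monthly,monthly,annually,annually,never,annually,annually,annually,monthly,23.3,never,NA,high,0,het,ref,ref,het,ref,ref,ref,ref,ref,het,het,ref,ref
S000007,40.6,female,junior,married_cohabit,lt1000,FALSE,FALSE,107.3,79.5,128,88,FALSE,monthly,monthly,daily,daily,monthly,never,weekly,monthly,annually,20.1,current,NA,high,235,ref,het,ref,ref,het,het,het,ref,het,het,het,het,het
S000008,37.3,female,primary_or_below,married_cohabit,lt1000,TRUE,FALSE,114,79.8,112.9,79.6,FALSE,weekly,daily,monthly,monthly,annually,annually,weekly,monthly,monthly,19.7,never,NA,low,0,ref,ref,ref,het,ref,het,ref,ref,het,ref,ref,ref,ref
S000009,50.3,female,junior,married_cohabit,lt1000,TRUE,FALSE,129.1,65.6,131.7,65.3,FALSE,annually,never,annually,weekly,monthly,annually,monthly,never,annually,21,current,NA,high,0,ref,ref,ref,ref,het,ref,ref,ref,het,ref,het,het,ref
S000010,43.6,female,primary_or_below,married_cohabit,lt1000,FALSE,FALSE,125.6,83.4,125.4,80.8,FALSE,annually,monthly,weekly,monthly,weekly,weekly,monthly,weekly,weekly,20.7,never,NA,low,0,ref,ref,het,ref,ref,het,het,het,het,het,ref,ref,het
S000011,44.3,female,primary_or_below,married_cohabit,lt1000,FALSE,FALSE,106.6,81.2,110.9,75.1,FALSE,never,monthly,monthly,monthly,monthly,never,annually,monthly,daily,21.1,never,NA,moderate,2,ref,het,ref,ref,het,het,het,het,ref,ref,ref,het,het
S000012,40.6,female,junior,married_cohabit,lt1000,TRUE,FALSE,126.7,68.7,132.2,75.2,FALSE,never,annually,never,weekly,never,monthly,monthly,annually,annually,23.3,never,NA,low,0,het,ref,ref,ref,ref,ref,het,ref,het,ref,hom,ref,het
S000013,46.5,female,primary_or_below,married_cohabit,1000to2999,TRUE,FALSE,106.5,72.2,101.2,77.1,FALSE,monthly,never,annually,weekly,monthly,never,monthly,weekly,daily,19.9,never,NA,low,0,ref,ref,ref,het,het,het,ref,het,het,ref,ref,het,ref
S000014,46.4,female,primary_or_below,married_cohabit,lt1000,FALSE,FALSE,103.9,67.3,115.4,70.9,FALSE,weekly,weekly,monthly,daily,annually,annually,annually,monthly,monthly,28.4,never,NA,low,159,het,het,ref,ref,het,ref,het,ref,ref,het,ref,ref,ref
S000015,19.7,male,primary_or_below,married_cohabit,lt1000,FALSE,FALSE,119.6,63.7,119.9,66.8,FALSE,weekly,monthly,daily,weekly,monthly,weekly,annually,weekly,monthly,24,current,NA,moderate,0,ref,ref,ref,het,ref,het,het,het,het,ref,het,ref,het
S000016,64.6,female,primary_or_below,married_cohabit,lt1000,FALSE,FALSE,114.9,76.6,105.9,73.9,FALSE,weekly,never,weekly,weekly,annually,daily,daily,never,annually,19.7,never,NA,low,0,het,ref,ref,ref,het,ref,het,het,ref,ref,ref,ref,ref
S000017,56.1,female,junior,married_cohabit,lt1000,TRUE,FALSE,113.3,67.2,114.2,67.7,FALSE,never,annually,monthly,weekly,monthly,daily,weekly,annually,annually,22.3,never,NA,low,0,het,het,het,ref,het,het,het,het,het,het,het,ref,het
S000018,51.5,female,junior,married_cohabit,lt1000,FALSE,FALSE,125.9,66.1,135.1,72.2,FALSE,annually,annually,monthly,annually,annually,never,monthly,annually,weekly,24.6,never,NA,moderate,105,ref,het,het,het,het,ref,het,ref,ref,het,het,hom,het
S000019,39.8,male,primary_or_below,married_cohabit,lt1000,FALSE,FALSE,103.8,74.1,109.7,74.3,FALSE,annually,daily,monthly,daily,daily,never,never,monthly,weekly,23.9,never,NA,low,0,ref,het,hom,ref,ref,ref,het,hom,ref,ref,het,ref,ref
S000020,57,female,junior,married_cohabit,lt1000,TRUE,TRUE,106.6,79.4,121.1,78.8,TRUE,monthly,never,weekly,monthly,weekly,annually,annually,annually,weekly,26,never,NA,low,0,ref,het,ref,ref,het,ref,ref,ref,het,het,het,ref,ref
S000021,45.3,male,primary_or_below,married_cohabit,lt1000,FALSE,FALSE,103.8,87.3,121.9,81.4,FALSE,monthly,annually,annually,never,annually,monthly,weekly,annually,daily,19,never,NA,low,0,ref,ref,het,hom,ref,het,hom,het,het,ref,het,het,het
S000022,47.1,female,junior,married_cohabit,lt1000,FALSE,TRUE,103.2,66.7,117.5,69,TRUE,annually,annually,annually,never,weekly,annually,weekly,weekly,weekly,21.7,current,NA,moderate,0,ref,het,hom,het,hom,het,het,ref,ref,het,het,het,ref
S000023,33,female,primary_or_below,married_cohabit,lt1000,FALSE,FALSE,119.8,76.6,125.1,78.9,FALSE,annually,monthly,monthly,weekly,weekly,annually,monthly,never,weekly,23.9,never,NA,high,0,ref,hom,ref,het,het,ref,het,ref,ref,het,ref,hom,ref
S000024,65.9,female,primary_or_below,married_cohabit,lt1000,FALSE,FALSE,123.4,78,129.2,76.4,FALSE,annually,monthly,weekly,monthly,annually,daily,weekly,annually,annually,26.6,never,NA,low,0,het,ref,hom,hom,het,ref,ref,ref,ref,ref,het,ref,ref
S000025,49.6,male,primary_or_below,married_cohabit,lt1000,FALSE,FALSE,104.1,61.7,110.7,68.8,FALSE,weekly,annually,annually,monthly,monthly,annually,weekly,weekly,never,16.3,never,NA,low,6,het,het,ref,het,ref,hom,het,ref,het,ref,hom,ref,ref
S000026,71,female,primary_or_below,married_cohabit,lt1000,FALSE,FALSE,109.4,82.9,115,83.8,FALSE,monthly,monthly,annually,annually,annually,never,never,annually,weekly,24.7,never,NA,high,0,het,ref,ref,ref,hom,het,het,het,het,ref,het,ref,ref
S000027,69,female,junior,married_cohabit,lt1000,TRUE,FALSE,127.5,70,152.5,58.8,TRUE,weekly,monthly,monthly,monthly,monthly,daily,monthly,monthly,monthly,20.5,current,NA,low,60,hom,ref,ref,ref,hom,het,het,ref,het,ref,ref,het,ref
S000028,49.7,female,primary_or_below,married_cohabit,1000to2999,FALSE,FALSE,135.5,68.4,132.8,65.2,FALSE,never,monthly,annually,monthly,daily,weekly,annually,weekly,weekly,22.2,former,45,low,0,ref,het,ref,ref,het,ref,het,het,ref,het,het,het,hom
S000029,56.5,male,primary_or_below,married_cohabit,ge3000,FALSE,FALSE,130.3,64.8,121.1,67.2,FALSE,annually,monthly,monthly,never,weekly,never,monthly,monthly,weekly,21.1,never,NA,low,7,ref,het,het,het,ref,ref,hom,ref,hom,het,het,het,ref
S000030,68.9,male,junior,married_cohabit,lt1000,FALSE,FALSE,80.5,78.6,93.6,78.7,FALSE,annually,monthly,monthly,monthly,weekly,weekly,weekly,weekly,monthly,22.4,current,NA,moderate,0,het,het,het,ref,ref,ref,het,ref,het,ref,het,ref,hom
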