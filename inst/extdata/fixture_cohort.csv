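"species_id","scientific_name","common_name","lead_region","listing_status","taxonomic_group","populations_remaining","age_at_maturity_years","lifespan_years","recovery_priority_number","translocation_status","genetic_rescue_mentioned","marker_types","evaluator_id","q1","q2","q3","q4","q5","q6","q7","q8","q9","island_species","marine_species","likely_extinct","in_us_range"
"FIX-01","Fictus primus","Fixture species 1",1,"Endangered","Birds","6 to 20",2,12,6,"implemented","mentioned","microsatellite;snp","EV1",2,1,1,1,0,0,0,0,NA,FALSE,FALSE,FALSE,TRUE
"FIX-02","Fictus secundus","Fixture species 2",2,"Threatened","Fishes","1 to 5",3.9,8,7,"considered","absent","microsatellite","EV2",1,1,1,1,0,NA,-1,-1,NA,FALSE,FALSE,FALSE,TRUE
"FIX-03","Fictus tertius","Fixture species 3",3,"Endangered","Mammals","21 to 80",4,20,12,"not_mentioned","absent",NA,"EV3",NA,NA,NA,0,0,NA,0,NA,NA,FALSE,FALSE,FALSE,TRUE
"FIX-04","Fictus quartus","Fixture species 4",4,"Threatened","Birds","1 to 5",1,6,13,"implemented","mentioned","snp","EV1",2,1,1,1,0,NA,0,NA,-1,FALSE,FALSE,FALSE,TRUE
"FIX-05","Fictus quintus","Fixture species 5",5,"Endangered","Amphibians","6 to 20",0.5,4,1,"implemented","considered_concept","mtdna_nuclear","EV2",0,1,1,1,0,0,0,0,NA,FALSE,FALSE,FALSE,TRUE
"FIX-06","Fictus sextus","Fixture species 6",6,"Endangered","Fishes","81 to 300",6,30,18,"considered","absent","microsatellite","EV3",1,NA,1,1,0,0,0,0,NA,FALSE,FALSE,FALSE,TRUE
"FIX-07","Fictus septimus","Fixture species 7",7,"Threatened","Fishes","1 to 5",4,15,3,"not_mentioned","absent",NA,"EV1",NA,NA,NA,0,-1,-1,0,NA,NA,FALSE,FALSE,FALSE,TRUE
"FIX-08","Fictus octavus","Fixture species 8",8,"Endangered","Mammals",">300",2.5,10,9,"not_mentioned","absent",NA,"EV2",0,0,1,0,0,NA,0,-1,NA,FALSE,FALSE,FALSE,TRUE
"FIX-09","Fictus nonus","Fixture species 9",4,"Threatened","Reptiles","6 to 20",8,40,15,"considered","absent",NA,"EV3",NA,1,1,0,0,NA,-1,NA,-1,FALSE,FALSE,FALSE,TRUE
"FIX-10","Fictus decimus","Fixture species 10",2,"Endangered","Fishes",NA,3,7,NA,"not_mentioned","absent",NA,"EV1",NA,NA,1,0,0,NA,-1,-1,NA,FALSE,FALSE,FALSE,TRUE
"FIX-11","Fictus undecimus","Fixture species 11",6,"Threatened","Amphibians","21 to 80",NA,NA,5,"implemented","absent",NA,"EV2",NA,1,1,0,0,NA,0,NA,NA,FALSE,FALSE,FALSE,TRUE
"FIX-12","Fictus duodecimus","Fixture species 12",1,"Endangered","Reptiles","1 to 5",5,25,11,"not_mentioned","absent",NA,"EV3",NA,NA,1,0,0,NA,0,NA,NA,FALSE,FALSE,FALSE,TRUE
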