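compound_id,name,k_M_per_s,barrier_kJ_mol,k_source,barrier_source
1,"1,3-cyclopentanedione",2.8e2,72.53,text,text
2,"2-methyl-1,3-cyclopentanedione",3.2e3,57.92,text,text
3,"2-acetyl-1,3-cyclopentanedione",NA,90.93,table-only: transcribe from source table,text
4,"1,3-cyclohexanedione",2.2e3,59.28,text,text
5,"2-methyl-1,3-cyclohexanedione",1.1e4,50.03,text,text
6,"dimedone (5,5-dimethyl-1,3-cyclohexanedione)",2.5e3,NA,text,table-only: transcribe from source table
7,"1,3-cycloheptanedione",6.8e3,57.52,text,text
8,"2,4-piperidinedione",2.0e4,45.65,text,text
9,"1-(4-methoxybenzyl)-2,4-piperidinedione",1.4e4,41.34,text,text
10,"1,3-dimethylbarbituric acid",NA,50.93,table-only: transcribe from source table,text
11,"barbituric acid",NA,64.65,table-only: transcribe from source table,text
12,"2-thiobarbituric acid",8.2e2,76.28,text,text
13,"Meldrum's acid",8.7e2,70.15,text,text
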