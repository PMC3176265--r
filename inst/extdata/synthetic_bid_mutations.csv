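"pdb_id","chain","resseq","icode","wt_aa","bid_category","is_antibody_complex"
"BID01","B",19,"","M","Strong",FALSE
"BID01","B",21,"","E","Weak",FALSE
"BID01","B",363,"","S","Insignificant",FALSE
"BID01","B",354,"","I","Strong",FALSE
"BID01","A",372,"","L","Insignificant",FALSE
"BID01","A",391,"","Y","Weak",FALSE
"BID01","A",177,"","G","Insignificant",FALSE
"BID02","B",324,"","P","Strong",FALSE
"BID02","B",115,"","M","Weak",FALSE
"BID02","A",321,"","V","Intermediate",FALSE
"BID02","A",92,"","L","Intermediate",FALSE
"BID02","A",337,"","Q","Strong",FALSE
"BID02","A",185,"","N","Weak",FALSE
"BID02","B",155,"","D","Insignificant",FALSE
"BID03","B",154,"","N","Insignificant",FALSE
"BID03","B",57,"","P","Intermediate",FALSE
"BID03","A",213,"","T","Strong",FALSE
"BID03","A",232,"","C","Negative-strong",FALSE
"BID03","A",291,"","E","Strong",FALSE
"BID03","B",186,"","K","Weak",FALSE
"BID03","B",13,"","R","Negative-strong",FALSE
"BID04","B",98,"","P","Strong",FALSE
"BID04","B",228,"","R","Strong",FALSE
"BID04","A",297,"","C","Weak",FALSE
"BID04","A",348,"","F","Insignificant",FALSE
"BID04","A",394,"","E","Strong",FALSE
"BID04","A",352,"","M","Strong",FALSE
"BID04","B",110,"","G","Insignificant",FALSE
"BID05","A",27,"","M","Strong",FALSE
"BID05","A",353,"","Q","Insignificant",FALSE
"BID05","B",256,"","Y","Intermediate",FALSE
"BID05","B",65,"","G","Insignificant",FALSE
"BID05","A",78,"","F","Insignificant",FALSE
"BID05","A",383,"","N","Strong",FALSE
"BID05","A",244,"","D","Negative-strong",FALSE
"BID06","B",58,"","R","Insignificant",FALSE
"BID06","A",245,"","S","Insignificant",FALSE
"BID06","A",28,"","K","Intermediate",FALSE
"BID06","A",288,"","I","Weak",FALSE
"BID06","B",361,"","L","Strong",FALSE
"BID06","B",158,"","G","Weak",FALSE
"BID06","A",371,"","V","Weak",FALSE
"BID07","B",165,"","Y","Negative-strong",FALSE
"BID07","A",245,"","M","Intermediate",FALSE
"BID07","B",354,"","L","Intermediate",FALSE
"BID07","A",152,"","I","Weak",FALSE
"BID07","A",172,"","V","Insignificant",FALSE
"BID07","A",34,"","S","Insignificant",FALSE
"BID07","B",125,"","P","Weak",FALSE
"BID08","A",284,"","D","Strong",FALSE
"BID08","B",304,"","L","Intermediate",FALSE
"BID08","A",18,"","N","Negative-weak",FALSE
"BID08","B",150,"","W","Insignificant",FALSE
"BID08","A",154,"","Y","Insignificant",FALSE
"BID08","A",49,"","V","Weak",FALSE
"BID08","A",212,"","P","Insignificant",FALSE
"BID09","B",351,"","W","Weak",FALSE
"BID09","B",360,"","L","Intermediate",FALSE
"BID09","A",30,"","Q","Intermediate",FALSE
"BID09","B",72,"","F","Negative-strong",FALSE
"BID09","B",58,"","Y","Strong",FALSE
"BID09","A",166,"","V","Weak",FALSE
"BID09","A",99,"","V","Insignificant",FALSE
"BID10","A",321,"","L","Strong",FALSE
"BID10","A",175,"","T","Strong",FALSE
"BID10","A",4,"","N","Strong",FALSE
"BID10","A",41,"","C","Strong",FALSE
"BID10","B",353,"","G","Intermediate",FALSE
"BID10","A",198,"","R","Strong",FALSE
"BID10","A",276,"","P","Intermediate",FALSE
"BID11","B",398,"","V","Weak",FALSE
"BID11","B",137,"","M","Strong",FALSE
"BID11","A",92,"","V","Weak",FALSE
"BID11","A",152,"","E","Intermediate",FALSE
"BID11","A",150,"","M","Strong",FALSE
"BID11","B",267,"","L","Insignificant",FALSE
"BID12","A",210,"","G","Negative-weak",FALSE
"BID12","B",363,"","V","Strong",FALSE
"BID12","B",147,"","N","Weak",FALSE
"BID12","B",399,"","E","Intermediate",FALSE
"BID12","A",369,"","I","Strong",FALSE
"BID12","A",296,"","K","Strong",FALSE
"BID13","B",242,"","E","Strong",FALSE
"BID13","A",225,"","Q","Strong",FALSE
"BID13","A",311,"","P","Insignificant",FALSE
"BID13","B",166,"","L","Intermediate",FALSE
"BID13","B",34,"","S","Insignificant",FALSE
"BID13","B",238,"","R","Negative-weak",FALSE
"BID14","B",229,"","I","Weak",FALSE
"BID14","B",1,"","L","Intermediate",FALSE
"BID14","A",350,"","W","Insignificant",FALSE
"BID14","B",57,"","M","Intermediate",FALSE
"BID14","A",311,"","R","Negative-weak",FALSE
"BID14","B",316,"","K","Intermediate",FALSE
"BID15","A",196,"","C","Insignificant",FALSE
"BID15","A",71,"","D","Weak",FALSE
"BID15","A",142,"","E","Strong",FALSE
"BID15","A",10,"","Q","Intermediate",FALSE
"BID15","A",69,"","L","Strong",FALSE
"BID15","B",344,"","N","Negative-weak",FALSE
"BID16","A",166,"","C","Intermediate",FALSE
"BID16","B",133,"","I","Intermediate",FALSE
"BID16","A",277,"","P","Strong",FALSE
"BID16","B",63,"","P","Intermediate",FALSE
"BID16","B",242,"","D","Insignificant",FALSE
"BID16","A",35,"","Y","Weak",FALSE
"BID17","A",259,"","L","Strong",FALSE
"BID17","B",201,"","R","Intermediate",FALSE
"BID17","B",301,"","H","Strong",FALSE
"BID17","A",91,"","Q","Intermediate",FALSE
"BID17","B",285,"","E","Weak",FALSE
"BID17","B",219,"","P","Strong",FALSE
"BID18","B",298,"","C","Insignificant",FALSE
"BID18","B",17,"","I","Weak",FALSE
"BID18","B",20,"","H","Intermediate",FALSE
"BID18","A",76,"","T","Weak",FALSE
"BID18","A",88,"","M","Strong",FALSE
"BID18","A",158,"","L","Negative-weak",FALSE
"BID19","A",214,"","P","Weak",FALSE
"BID19","A",179,"","K","Intermediate",FALSE
"BID19","B",112,"","N","Negative-weak",FALSE
"BID19","A",161,"","T","Intermediate",FALSE
"BID19","B",106,"","P","Strong",FALSE
"BID19","B",135,"","S","Intermediate",FALSE
"BID20","B",25,"","W","Intermediate",FALSE
"BID20","B",24,"","E","Strong",FALSE
"BID20","A",255,"","V","Negative-weak",FALSE
"BID20","A",322,"","L","Insignificant",FALSE
"BID20","B",292,"","F","Insignificant",FALSE
"BID20","B",264,"","E","Strong",FALSE
"BID21","B",206,"","R","Intermediate",FALSE
"BID21","A",145,"","K","Intermediate",FALSE
"BID21","A",186,"","F","Intermediate",FALSE
"BID21","A",241,"","L","Strong",FALSE
"BID21","B",399,"","F","Insignificant",FALSE
"BID21","A",80,"","S","Intermediate",FALSE
"BID22","A",352,"","W","Insignificant",FALSE
"BID22","A",180,"","S","Strong",FALSE
"BID22","A",25,"","H","Strong",FALSE
"BID22","B",195,"","C","Intermediate",FALSE
"BID22","A",142,"","E","Strong",FALSE
"BID22","B",56,"","L","Intermediate",FALSE
"BID23","B",172,"","T","Strong",FALSE
"BID23","B",183,"","M","Strong",FALSE
"BID23","A",238,"","T","Weak",FALSE
"BID23","B",67,"","V","Insignificant",FALSE
"BID23","A",164,"","D","Strong",FALSE
"BID23","A",291,"","G","Strong",FALSE
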