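taxon_id,rank,label,parent_id,status,accepted_id,authors,year,parenthesized,combination_authors,vernacular,language,external_ids,timestamp
t1,genus,Leptura,,valid,,Linnaeus,1758,false,,,,,
t2,genus,Pedostrangalia,,valid,,Sokolow,1758,false,,,,,
t3,species,pubescens,t2,valid,,Fabricius,1787,true,,,,,
t4,species,revestita,t2,valid,,Linnaeus,1767,true,,,,,
t5,species,aethiops,t1,valid,,Poda,1761,false,,,,,
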