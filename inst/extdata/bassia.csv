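taxon_id,rank,label,parent_id,status,accepted_id,authors,year,parenthesized,combination_authors,vernacular,language,external_ids,timestamp
t1,genus,Bassia,,valid,,,,,,,,,
t2,species,scoparia,t1,valid,,L.,,true,A.J. Scot,,,,
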