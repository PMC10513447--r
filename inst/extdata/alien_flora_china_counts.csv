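group,category,count
checklist,naturalized_checklist,861
checklist,invasive_checklist,464
checklist,griis_checklist,459
consensus,introduced,193
consensus,naturalized,275
consensus,invasive,343
analyzed,introduced,165
analyzed,naturalized,222
analyzed,invasive,319
occurrence_source,gbif,17924
occurrence_source,nsii,69736
taxa,genera,397
taxa,families,94
family_total,Asteraceae,114
family_total,Fabaceae,90
family_total,Poaceae,75
family_stage,Asteraceae_introduced,17
family_stage,Asteraceae_naturalized,32
family_stage,Asteraceae_invasive,65
family_stage,Fabaceae_introduced,28
family_stage,Fabaceae_naturalized,27
family_stage,Fabaceae_invasive,35
family_stage,Poaceae_introduced,23
family_stage,Poaceae_naturalized,20
family_stage,Poaceae_invasive,32
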