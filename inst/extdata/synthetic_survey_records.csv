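"taxon","rank","classic_label","pgtcp_label","categories","motif_count_at_least_3","based_on_preexisting_periodicity"
"taxon_1","order","Y","N","",FALSE,FALSE
"taxon_2","order","Y","Y","rosettes",TRUE,FALSE
"taxon_3","order","N","Y","rosettes",TRUE,FALSE
"taxon_4","order","N","N","",FALSE,FALSE
"taxon_5","order","N","M","",FALSE,FALSE
"taxon_6","order","N","Y","rosettes",TRUE,FALSE
"taxon_7","order","N","N","",FALSE,FALSE
"taxon_8","order","N","N","",FALSE,FALSE
"taxon_9","order","N","N?","",FALSE,FALSE
"taxon_10","order","Y","M","",FALSE,FALSE
"taxon_11","order","N","N","",FALSE,FALSE
"taxon_12","order","Y","N","",FALSE,FALSE
"taxon_13","order","N","N?","",FALSE,FALSE
"taxon_14","order","N","N","",FALSE,FALSE
"taxon_15","order","N","Y","rosettes",TRUE,FALSE
"taxon_16","order","N","M","",FALSE,FALSE
"taxon_17","order","Y","N","",FALSE,FALSE
"taxon_18","order","N","N?","",FALSE,FALSE
"taxon_19","order","Y","N","",FALSE,FALSE
"taxon_20","order","Y","N","",FALSE,FALSE
"taxon_21","order","Y","N?","",FALSE,FALSE
"taxon_22","order","N","N?","",FALSE,FALSE
"taxon_23","order","N","Y","rosettes",TRUE,FALSE
"taxon_24","order","N","N","",FALSE,FALSE
"taxon_25","order","N","N","",FALSE,FALSE
"taxon_26","order","N","M","",FALSE,FALSE
"taxon_27","order","N","N","",FALSE,FALSE
"taxon_28","order","Y","N","",FALSE,FALSE
"taxon_29","order","N","Y","rosettes",TRUE,FALSE
"taxon_30","order","Y","N","",FALSE,FALSE
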